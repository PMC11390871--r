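# Small cohort configurations reused across tests. Feature counts are kept
# modest so a full simulate + WPPS cycle stays in the tens of milliseconds.

small_config <- function(n_pairs = 40, seed = 1, a2 = 0.5, c2 = 0.2,
                         e2 = 0.3, n_features = 20, n_latent = 5,
                         lifestyle = list(), ...) {
  sim_config(
    n_pairs = n_pairs,
    domains = list(domain_spec("omics", n_features, n_latent = n_latent,
                               a2 = a2, c2 = c2, e2 = e2)),
    lifestyle = lifestyle,
    seed = seed,
    ...
  )
}

# One omics + one exposome-style domain with co-residence duplication.
two_domain_config <- function(n_pairs = 50, seed = 1, co_residence_prob = 0.3) {
  sim_config(
    n_pairs = n_pairs,
    domains = list(
      domain_spec("omics", 16, n_latent = 4),
      domain_spec("exposome", 12, n_latent = 3, a2 = 0, c2 = 0.6, e2 = 0.4,
                  coresident_identical = TRUE)
    ),
    lifestyle = list(lifestyle_spec("smoking", 0.3, missing_prob = 0),
                     lifestyle_spec("going_out", 0.25, missing_prob = 0),
                     lifestyle_spec("reading", 0.2, missing_prob = 0)),
    co_residence_prob = co_residence_prob,
    seed = seed
  )
}

# Domain tibble from a bare matrix with generated twin ids.
as_domain <- function(m, ids = sprintf("t%02d", seq_len(nrow(m)))) {
  colnames(m) <- colnames(m) %||% sprintf("f%02d", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(twin_id = ids),
                   tibble::as_tibble(as.data.frame(m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Twin-1 and twin-2 feature matrices for a cohort domain (default: first).
split_pairs_matrix <- function(cohort, domain = names(cohort$domains)[1]) {
  d <- cohort$domains[[domain]]
  m <- as.matrix(d[-1])
  rownames(m) <- d$twin_id
  list(x1 = m[cohort$pairs$twin1_id, , drop = FALSE],
       x2 = m[cohort$pairs$twin2_id, , drop = FALSE])
}

# Minimal pair table for a matrix whose rows 1,2 / 3,4 / ... are co-twins.
pairs_for <- function(ids) {
  n <- length(ids) %/% 2
  tibble::tibble(
    pair_id = sprintf("p%02d", seq_len(n)),
    twin1_id = ids[seq(1, 2 * n, by = 2)],
    twin2_id = ids[seq(2, 2 * n, by = 2)],
    zygosity = rep(c("MZ", "DZ"), length.out = n),
    sex = "F",
    age_blood_twin1 = 22, age_blood_twin2 = 22,
    age_left_home = 18, co_resident = FALSE
  )
}
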
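#' Full-rank principal component analysis for proximity scoring
#'
#' Decomposes a complete, standardized domain matrix into all principal
#' components with non-negligible variance, covering 100% of the realized
#' inertia (total variance). With more features than individuals at most
#' `n - 1` components carry variance; inertia fractions are renormalized
#' over the retained components so they always sum to one.
#'
#' @param x Numeric matrix (individuals x features), complete; or a domain
#'   tibble with a `twin_id` column.
#' @param tol Components with variance below `tol` times total inertia are
#'   dropped before scaling.
#' @return Object of class `"wpps_pca"`: list with `scores` (n x r raw
#'   component scores), `omega` (inertia fractions, non-increasing, sum 1),
#'   `component_sds`, `total_inertia` and `ids`.
#' @export
pca_full <- function(x, tol = 1e-12) {
  if (is.data.frame(x)) {
    d <- split_domain(x)
    x <- d$values
  }
  if (!is.matrix(x) || !is.numeric(x)) abort("`x` must be a numeric matrix")
  if (nrow(x) < 3L) abort("need at least three individuals for PCA")
  if (anyNA(x)) abort("PCA requires a complete matrix")
  pr <- prcomp(x, center = TRUE, scale. = FALSE)
  vars <- pr$sdev^2
  total <- sum(vars)
  keep <- vars > tol * total
  scores <- pr$x[, keep, drop = FALSE]
  vars <- vars[keep]
  structure(list(scores = scores,
                 omega = vars / sum(vars),
                 component_sds = sqrt(vars),
                 total_inertia = sum(vars),
                 ids = rownames(x)),
            class = "wpps_pca")
}

#' Scale principal components to unit variance
#'
#' Divides each retained component by its standard deviation so every
#' component has mean zero and variance one.
#'
#' @param decomp A [pca_full()] decomposition.
#' @return Matrix of scaled scores (columns have sd 1).
#' @export
scale_components <- function(decomp) {
  if (!inherits(decomp, "wpps_pca")) abort("`decomp` must be a wpps_pca")
  if (any(decomp$component_sds <= 0)) abort("zero-variance component cannot be scaled")
  sweep(decomp$scores, 2, decomp$component_sds, "/")
}

#' Inertia-weighted distance between two individuals
#'
#' On scaled component scores, computes
#' `D = sum_k omega_k * delta_k^2` (weighted squared Euclidean, the
#' default) or `D = sum_k omega_k * |delta_k|` (weighted Manhattan), where
#' `delta_k` is the difference between the two individuals on scaled
#' component `k` and `omega_k` the component's inertia fraction.
#'
#' @param scaled_scores Matrix from [scale_components()].
#' @param omega Inertia-fraction weights (same length as columns).
#' @param i,j Row indices (or rowname ids) of the two individuals.
#' @param metric `"euclidean"` (squared, weighted) or `"manhattan"`.
#' @return Non-negative scalar distance; 0 iff identical score rows.
#' @export
pair_distance <- function(scaled_scores, omega, i, j,
                          metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  if (length(omega) != ncol(scaled_scores)) {
    abort("length(omega) must equal the number of score columns")
  }
  delta <- scaled_scores[i, ] - scaled_scores[j, ]
  if (metric == "euclidean") sum(omega * delta^2) else sum(omega * abs(delta))
}

#' Gaussian kernel similarity
#'
#' Projects a distance into (0, 1] via `exp(-D / (2 * sigma^2))`; strictly
#' decreasing in `D`, equal to 1 iff `D = 0`. A pair whose weighted mean
#' squared scaled-component difference equals one scores
#' `exp(-1/2) ~= 0.61`.
#'
#' @param D Non-negative distance(s).
#' @param sigma Kernel width, positive; default 1.
#' @return Similarity in (0, 1].
#' @export
gaussian_similarity <- function(D, sigma = 1) {
  if (any(D < 0)) abort("distance must be non-negative")
  if (!is.numeric(sigma) || sigma <= 0) abort("`sigma` must be positive")
  exp(-D / (2 * sigma^2))
}

#' Reference distance computed without PCA
#'
#' Because PCA is an orthogonal rotation, weighting scaled components by
#' their inertia fractions collapses algebraically to the squared Euclidean
#' distance between the standardized feature rows divided by the total
#' inertia. This direct computation serves as an independent oracle for
#' [pair_distance()] under the euclidean metric.
#'
#' @param x Complete numeric matrix or domain tibble (standardized features).
#' @param i,j Row indices (or ids) of the two individuals.
#' @return Non-negative scalar `||x_i - x_j||^2 / total_inertia`.
#' @export
oracle_distance <- function(x, i, j) {
  if (is.data.frame(x)) {
    d <- split_domain(x)
    x <- d$values
  }
  xc <- scale(x, center = TRUE, scale = FALSE)
  total <- sum(apply(xc, 2, var))
  sum((x[i, ] - x[j, ])^2) / total
}

#' Compute within-pair proximity scores for one domain
#'
#' Runs the four-step procedure on a preprocessed domain: (1) full-rank PCA
#' covering 100% of the realized inertia, (2) scaling of every component to
#' unit variance, (3) inertia-weighted distance between the two co-twins'
#' component scores, (4) Gaussian kernel with width `sigma`. Pairs whose
#' preprocessed feature rows are exactly equal score exactly 1 (identity
#' detection by exact row equality, as for co-resident pairs sharing one
#' exposure record); all scores lie in (0, 1]. Pairs with either co-twin
#' absent from the domain are dropped (complete-case per domain). The
#' result is invariant to feature order and component sign conventions.
#'
#' @param data Preprocessed domain tibble (`twin_id` + numeric features).
#' @param pairs Pair table with `pair_id`, `twin1_id`, `twin2_id`.
#' @param domain Domain label stored in the output; defaults to
#'   `"domain"`.
#' @param sigma Gaussian kernel width (default 1).
#' @param metric `"euclidean"` or `"manhattan"` weighted distance.
#' @param id_col Identifier column name.
#' @return Tibble of class `"wpps_tbl"`: `pair_id`, `domain`, `wpps`,
#'   `n_features`, `metric`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(
#'   n_pairs = 15, domains = list(domain_spec("omics", 10, n_latent = 3)),
#'   lifestyle = list(), seed = 2
#' ))
#' dom <- standardize_features(cohort$domains$omics)
#' compute_wpps(dom, cohort$pairs, domain = "omics")
compute_wpps <- function(data, pairs, domain = "domain", sigma = 1,
                         metric = c("euclidean", "manhattan"),
                         id_col = "twin_id") {
  metric <- match.arg(metric)
  d <- split_domain(data, id_col)
  keep <- pairs$twin1_id %in% d$ids & pairs$twin2_id %in% d$ids
  if (!any(keep)) abort("no pair has both co-twins present in the domain")
  pp <- pairs[keep, , drop = FALSE]

  decomp <- pca_full(d$values)
  scaled <- scale_components(decomp)
  idx <- setNames(seq_along(d$ids), d$ids)

  score_one <- function(t1, t2) {
    i <- idx[[t1]]; j <- idx[[t2]]
    if (identical(unname(d$values[i, ]), unname(d$values[j, ]))) {
      return(1)
    }
    gaussian_similarity(
      pair_distance(scaled, decomp$omega, i, j, metric), sigma)
  }
  out <- tibble(
    pair_id = pp$pair_id,
    domain = domain,
    wpps = purrr::map2_dbl(pp$twin1_id, pp$twin2_id, score_one),
    n_features = length(d$feature_names),
    metric = metric
  )
  class(out) <- c("wpps_tbl", class(out))
  out
}

#' Compute WPPS for every domain of a cohort
#'
#' Preprocesses each simulated domain (standardization; inverse-normal
#' first for a domain named `"metabolome"`) and computes its proximity
#' scores, returning one stacked table.
#'
#' @param cohort A `twin_cohort`, or a named list of domain tibbles.
#' @param pairs Pair table; taken from the cohort when omitted.
#' @param sigma,metric Passed to [compute_wpps()].
#' @param prep Apply [prep_domain()] to each domain first (default TRUE).
#' @return A `wpps_tbl` tibble covering all domains.
#' @export
compute_wpps_all <- function(cohort, pairs = NULL, sigma = 1,
                             metric = c("euclidean", "manhattan"),
                             prep = TRUE) {
  metric <- match.arg(metric)
  if (inherits(cohort, "twin_cohort")) {
    domains <- cohort$domains
    if (is.null(pairs)) pairs <- cohort$pairs
  } else {
    domains <- cohort
    if (is.null(pairs)) abort("`pairs` is required when passing a domain list")
  }
  out <- purrr::imap(domains, function(dat, nm) {
    if (prep) dat <- prep_domain(dat, inverse_normal = identical(nm, "metabolome"))
    compute_wpps(dat, pairs, domain = nm, sigma = sigma, metric = metric)
  })
  out <- bind_rows(out)
  class(out) <- c("wpps_tbl", class(out))
  out
}
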
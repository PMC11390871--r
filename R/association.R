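# Inference layer: covariate models, prioritized cross-domain regressions,
# zygosity-stratified comparison, and the lifestyle-discordance ExWAS.

# Dependent-variable priority for cross-domain model orientation: the
# higher-priority domain is modeled as the dependent variable.
WPPS_PRIORITY <- c("exposome", "eaa", "proteome", "metabolome")

#' Ordinary least squares with tidy per-term output
#'
#' Fits an OLS regression with intercept and returns one row per
#' non-intercept term with the classical standard error, two-sided t-test
#' p-value and model R-squared.
#'
#' @param data Data frame containing the model variables.
#' @param formula Model formula.
#' @return Tibble: `term`, `estimate`, `se`, `statistic`, `p`, `n`,
#'   `r_squared`.
#' @export
fit_linear <- function(data, formula) {
  data <- data[complete.cases(data[all.vars(formula)]), , drop = FALSE]
  fit <- lm(formula, data = data)
  if (fit$df.residual < 1L) abort("too few observations for the model")
  if (anyNA(coef(fit))) abort("rank-deficient design matrix")
  s <- summary(fit)
  ct <- s$coefficients
  keep <- rownames(ct) != "(Intercept)"
  tibble(
    term = rownames(ct)[keep],
    estimate = ct[keep, 1], se = ct[keep, 2],
    statistic = ct[keep, 3], p = ct[keep, 4],
    n = nrow(data), r_squared = unname(s$r.squared)
  )
}

# Formula `dep ~ indep (+ age_diff)`; the age-difference covariate is
# dropped when constant in the analysis subset (e.g. toy data with all
# co-twins sampled the same day), where it carries no information and
# would make the design rank-deficient.
adjusted_formula <- function(dep, indep, dat) {
  rhs <- paste0("`", indep, "`")
  ad <- dat$age_diff[complete.cases(dat[c(dep, indep, "age_diff")])]
  if (length(ad) > 1 && sd(ad) > .Machine$double.eps) {
    rhs <- paste0(rhs, " + age_diff")
  }
  stats::as.formula(paste0("`", dep, "` ~ ", rhs))
}

wpps_wide <- function(wpps) {
  wpps %>%
    as_tibble() %>%
    select("pair_id", "domain", "wpps") %>%
    tidyr::pivot_wider(names_from = "domain", values_from = "wpps")
}

pair_covariates <- function(pairs) {
  pairs %>%
    mutate(
      zygosity_mz = as.integer(.data$zygosity == "MZ"),
      sex_f = as.integer(.data$sex == "F"),
      age_diff = abs(.data$age_blood_twin1 - .data$age_blood_twin2)
    ) %>%
    select("pair_id", "zygosity", "zygosity_mz", "sex_f", "age_diff",
           dplyr::any_of("age_left_home"))
}

#' Pair-covariate models of domain proximity
#'
#' For each domain, models the WPPS as a function of zygosity (MZ = 1,
#' DZ = 0), sex (F = 1, M = 0) and the age at which the pair left the
#' familial home, all entered jointly. Pairs with a missing
#' age-at-separation are dropped from that model.
#'
#' @param wpps A `wpps_tbl` (see [compute_wpps_all()]).
#' @param pairs Pair table.
#' @return Tibble with one row per domain x covariate: `dependent`,
#'   `independent`, `estimate`, `se`, `statistic`, `p`, `n`, `r_squared`,
#'   `subsample`.
#' @export
wpps_covariate_models <- function(wpps, pairs) {
  if (length(unique(pairs$zygosity)) < 2L) {
    abort("covariate models need both MZ and DZ pairs")
  }
  dat <- wpps_wide(wpps) %>% left_join(pair_covariates(pairs), by = "pair_id")
  purrr::map(unique(wpps$domain), function(dm) {
    f <- stats::as.formula(
      paste0("`", dm, "` ~ zygosity_mz + sex_f + age_left_home"))
    fit_linear(dat, f) %>%
      mutate(dependent = dm, subsample = "all", .before = 1) %>%
      rename(independent = "term")
  }) %>%
    bind_rows()
}

#' Prioritized cross-domain WPPS regressions
#'
#' Fits all pairwise regressions between domain WPPS on the pairs with
#' both scores present, orienting each model by the stated priority
#' (external exposome > EAA > proteome > metabolome: the higher-priority
#' domain is the dependent variable) and adjusting for the absolute
#' within-pair difference in age at blood sampling. Models with fewer than
#' `min_pairs` overlapping pairs are skipped with a warning.
#'
#' @param wpps A `wpps_tbl` with at least two domains.
#' @param pairs Pair table.
#' @param subsample `"all"`, `"MZ"` or `"DZ"`.
#' @param standardize Scale both WPPS to mean 0 / sd 1 within the
#'   subsample before fitting (used for cross-zygosity comparison).
#' @param priority Character vector giving the dependent-variable
#'   priority; domains absent from it rank last in input order.
#' @param min_pairs Minimum overlap to fit a model (default 10).
#' @return Tibble: `dependent`, `independent`, `estimate`, `se`,
#'   `statistic`, `p`, `n`, `r_squared`, `subsample` (one row per domain
#'   pair; the reported row is the independent-WPPS coefficient).
#' @export
cross_domain_models <- function(wpps, pairs, subsample = "all",
                                standardize = FALSE,
                                priority = WPPS_PRIORITY, min_pairs = 10L) {
  subsample <- match.arg(subsample, c("all", "MZ", "DZ"))
  domains <- unique(wpps$domain)
  if (length(domains) < 2L) abort("need at least two domains")
  ord <- c(intersect(priority, domains), setdiff(domains, priority))
  dat <- wpps_wide(wpps) %>% left_join(pair_covariates(pairs), by = "pair_id")
  if (subsample != "all") dat <- dat %>% filter(.data$zygosity == subsample)
  if (standardize) {
    for (dm in ord) {
      v <- dat[[dm]]
      s <- sd(v, na.rm = TRUE)
      if (is.na(s) || s < .Machine$double.eps) {
        abort(sprintf("degenerate WPPS variance in domain '%s'", dm))
      }
      dat[[dm]] <- (v - mean(v, na.rm = TRUE)) / s
    }
  }
  combos <- utils::combn(ord, 2, simplify = FALSE)
  purrr::map(combos, function(cb) {
    dep <- cb[1]; indep <- cb[2]
    sub <- dat[complete.cases(dat[c(dep, indep, "age_diff")]), , drop = FALSE]
    if (nrow(sub) < min_pairs) {
      warn(sprintf("skipping %s ~ %s (%s): only %d overlapping pairs",
                   dep, indep, subsample, nrow(sub)))
      return(NULL)
    }
    f <- adjusted_formula(dep, indep, sub)
    fit_linear(sub, f) %>%
      filter(.data$term == paste0("`", indep, "`") | .data$term == indep) %>%
      mutate(dependent = dep, independent = indep, subsample = subsample,
             .before = 1) %>%
      select(-"term")
  }) %>%
    bind_rows()
}

#' Zygosity-stratified coefficient comparison
#'
#' Refits every cross-domain model separately in MZ and DZ pairs with each
#' WPPS standardized to mean zero and unit variance within the subsample,
#' then tests the genetic hypothesis that the MZ coefficient exceeds the
#' DZ coefficient with the one-sided z-statistic
#' `z = (bMZ - bDZ) / sqrt(seMZ^2 + seDZ^2)`, `p = 1 - Phi(z)` (MZ pairs
#' are fully genetically matched, DZ pairs half-matched, so genetic
#' effects inflate the MZ coefficient).
#'
#' @inheritParams cross_domain_models
#' @return Tibble of class `"wpps_zcomp"`: `dependent`, `independent`,
#'   `b_mz`, `se_mz`, `n_mz`, `b_dz`, `se_dz`, `n_dz`, `z`, `p_one_sided`.
#' @export
stratified_z_comparison <- function(wpps, pairs, priority = WPPS_PRIORITY,
                                    min_pairs = 10L) {
  mz <- cross_domain_models(wpps, pairs, "MZ", standardize = TRUE,
                            priority = priority, min_pairs = min_pairs)
  dz <- cross_domain_models(wpps, pairs, "DZ", standardize = TRUE,
                            priority = priority, min_pairs = min_pairs)
  out <- mz %>%
    select("dependent", "independent",
           b_mz = "estimate", se_mz = "se", n_mz = "n") %>%
    dplyr::inner_join(
      dz %>% select("dependent", "independent",
                    b_dz = "estimate", se_dz = "se", n_dz = "n"),
      by = c("dependent", "independent")
    ) %>%
    mutate(
      z = (.data$b_mz - .data$b_dz) / sqrt(.data$se_mz^2 + .data$se_dz^2),
      p_one_sided = pnorm(.data$z, lower.tail = FALSE)
    )
  class(out) <- c("wpps_zcomp", class(out))
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up q-values `q_i = min_{j: p_(j) >= p_(i)} m * p_(j) / j`, clipped
#' at 1 and monotone in p.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Vector of q-values.
#' @export
bh_fdr <- function(p) {
  obs <- p[!is.na(p)]
  if (any(obs < 0 | obs > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Exposome-wide association study of WPPS on lifestyle discordance
#'
#' For every (domain, lifestyle variable) combination, regresses the
#' domain's WPPS on the pair's binary discordance indicator plus the
#' absolute within-pair difference in age at blood sampling. Pairs missing
#' the indicator are dropped per variable; combinations with fewer than
#' two discordant or two concordant pairs are skipped with a warning.
#' q-values are Benjamini-Hochberg, computed within each domain's family
#' of tests by default (`fdr_family = "per_domain"`) or over all tests
#' (`"pooled"`); associations with `q < fdr_threshold` are flagged.
#'
#' @param wpps A `wpps_tbl`.
#' @param discordance Tibble `pair_id`, `variable`, `discordant` (0/1/NA);
#'   see [build_discordance_table()].
#' @param pairs Pair table.
#' @param fdr_family `"per_domain"` or `"pooled"`.
#' @param fdr_threshold Discussion threshold on q (default 0.2).
#' @return Tibble of class `"wpps_exwas"`: `dependent` (domain),
#'   `independent` (lifestyle variable), `estimate`, `se`, `statistic`,
#'   `p`, `q`, `flagged`, `n`, `n_discordant`, `r_squared`.
#' @export
exwas <- function(wpps, discordance, pairs,
                  fdr_family = c("per_domain", "pooled"),
                  fdr_threshold = 0.2) {
  fdr_family <- match.arg(fdr_family)
  dat <- wpps_wide(wpps) %>% left_join(pair_covariates(pairs), by = "pair_id")
  domains <- unique(wpps$domain)
  vars <- unique(discordance$variable)
  res <- purrr::map(domains, function(dm) {
    purrr::map(vars, function(v) {
      dv <- discordance %>% filter(.data$variable == v)
      sub <- dat %>%
        left_join(dv, by = "pair_id") %>%
        filter(!is.na(.data$discordant) & !is.na(.data[[dm]]) &
                 !is.na(.data$age_diff))
      nd <- sum(sub$discordant == 1L)
      nc <- sum(sub$discordant == 0L)
      if (nd < 2L || nc < 2L) {
        warn(sprintf("skipping %s ~ %s: %d discordant / %d concordant pairs",
                     dm, v, nd, nc))
        return(NULL)
      }
      f <- adjusted_formula(dm, "discordant", sub)
      fit_linear(sub, f) %>%
        filter(.data$term == "discordant") %>%
        mutate(dependent = dm, independent = v, n_discordant = nd,
               .before = 1) %>%
        select(-"term")
    }) %>% bind_rows()
  }) %>% bind_rows()
  if (nrow(res) == 0L) abort("no (domain, variable) combination could be tested")
  res <- if (fdr_family == "per_domain") {
    res %>% group_by(.data$dependent) %>%
      mutate(q = bh_fdr(.data$p)) %>% ungroup()
  } else {
    res %>% mutate(q = bh_fdr(.data$p))
  }
  res <- res %>%
    mutate(flagged = .data$q < fdr_threshold) %>%
    select("dependent", "independent", "estimate", "se", "statistic",
           "p", "q", "flagged", "n", "n_discordant", "r_squared")
  class(res) <- c("wpps_exwas", class(res))
  res
}
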
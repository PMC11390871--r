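#' Specify one simulated data domain
#'
#' Describes the ACE structure of a feature block in the synthetic twin
#' cohort. Each pair draws `n_latent` latent factors per twin; a twin's
#' factor value is `sqrt(a2)*A + sqrt(c2)*C + sqrt(e2)*E` where `C` is
#' shared within the pair, `A` correlates 1 between monozygotic (MZ)
#' co-twins and 0.5 between dizygotic (DZ) co-twins, and `E` is
#' twin-specific. Features are fixed linear mixtures of the latent factors
#' plus independent feature-level noise.
#'
#' @param name Domain label (e.g. `"proteome"`).
#' @param n_features Number of observed features `p`.
#' @param n_latent Number of latent factors (must not exceed `n_features`).
#' @param a2,c2,e2 Additive-genetic, common-environment and unique-environment
#'   variance fractions of each latent factor; must sum to 1.
#' @param feature_noise Fraction of each feature's variance that is
#'   independent measurement noise (in `[0, 1)`).
#' @param coresident_identical If `TRUE`, co-resident pairs receive exactly
#'   identical feature rows (used for the geocode-derived external exposome,
#'   where co-twins sharing a household share one exposure record).
#'
#' @return A list of class `"domain_spec"`.
#' @export
domain_spec <- function(name, n_features, n_latent = min(10L, n_features),
                        a2 = 0.5, c2 = 0.2, e2 = 0.3,
                        feature_noise = 0.2, coresident_identical = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  n_features <- as.integer(n_features)
  n_latent <- as.integer(n_latent)
  if (n_features < 1L) abort("`n_features` must be positive")
  if (n_latent < 1L || n_latent > n_features) {
    abort("`n_latent` must be in 1..n_features")
  }
  for (v in c(a2, c2, e2)) {
    if (!is.numeric(v) || v < 0 || v > 1) abort("variance components must lie in [0, 1]")
  }
  if (abs(a2 + c2 + e2 - 1) > 1e-12) {
    abort(sprintf("variance components must satisfy a2 + c2 + e2 = 1 (got %.15g)",
                  a2 + c2 + e2))
  }
  check_fraction(feature_noise, "feature_noise", 0, 1, open_hi = TRUE)
  structure(list(name = name, n_features = n_features, n_latent = n_latent,
                 a2 = a2, c2 = c2, e2 = e2, feature_noise = feature_noise,
                 coresident_identical = isTRUE(coresident_identical)),
            class = "domain_spec")
}

#' Specify one simulated lifestyle variable
#'
#' Lifestyle variables are generated directly at the dichotomized (binary
#' per twin) level. The pair's discordance indicator for the variable is
#' Bernoulli with `logit(prob) = logit(baseline) + sum_d coupling[d] * z_d`,
#' where `z_d` is the pair's standardized within-pair Euclidean distance in
#' domain `d`. Positive coupling therefore makes discordance more likely for
#' pairs that are far apart in that domain, i.e. plants a negative
#' association between the domain's proximity score and discordance.
#'
#' @param name Variable label.
#' @param baseline Baseline discordance probability in (0, 1).
#' @param coupling Named numeric vector of logit-scale couplings per domain
#'   (per SD of within-pair distance); missing domains count as 0.
#' @param missing_prob Probability that a twin's response is missing
#'   (missingness propagates to the pair's indicator).
#'
#' @return A list of class `"lifestyle_spec"`.
#' @export
lifestyle_spec <- function(name, baseline = 0.25, coupling = numeric(0),
                           missing_prob = 0.05) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  check_fraction(baseline, "baseline", 0, 1, open_lo = TRUE, open_hi = TRUE)
  check_fraction(missing_prob, "missing_prob", 0, 1, open_hi = TRUE)
  if (length(coupling) > 0 && is.null(names(coupling))) {
    abort("`coupling` must be a named vector (names = domain names)")
  }
  structure(list(name = name, baseline = baseline,
                 coupling = coupling, missing_prob = missing_prob),
            class = "lifestyle_spec")
}

#' Default domain specifications
#'
#' Four domains matching the study design the simulator emulates: a plasma
#' proteome (439 features), a plasma metabolome (140 features), epigenetic
#' age acceleration (8 clock residuals) and a geocode-derived external
#' exposome (65 exposures). Omics domains use a2 = 0.5, c2 = 0.2, e2 = 0.3;
#' the external exposome carries no genetic component, is identical for
#' co-resident pairs, and its few latent factors and low feature noise
#' reproduce the left-skewed, high-mean proximity distribution geocode
#' exposures produce in practice.
#'
#' @return Named list of [domain_spec()] objects.
#' @export
default_domain_specs <- function() {
  specs <- list(
    domain_spec("proteome", 439, n_latent = 30L, a2 = 0.5, c2 = 0.2, e2 = 0.3,
                feature_noise = 0.2),
    domain_spec("metabolome", 140, n_latent = 20L, a2 = 0.5, c2 = 0.2, e2 = 0.3,
                feature_noise = 0.2),
    domain_spec("eaa", 8, n_latent = 4L, a2 = 0.5, c2 = 0.2, e2 = 0.3,
                feature_noise = 0.3),
    domain_spec("exposome", 65, n_latent = 3L, a2 = 0, c2 = 0.6, e2 = 0.4,
                feature_noise = 0.05, coresident_identical = TRUE)
  )
  setNames(specs, vapply(specs, `[[`, character(1), "name"))
}

#' Default lifestyle variable specifications
#'
#' The 14 binary lifestyle variables of the emulated questionnaire panel
#' (education, leisure, substance use, social behavior). Baseline
#' discordance probabilities span 0.16-0.37, the observed range of
#' discordant-pair counts (42-94 of 257 pairs). By default one variable
#' (drinking to intoxication) is coupled to the proteome, mirroring the
#' kind of single-domain lifestyle signal the analysis is designed to
#' detect; all other couplings are zero.
#'
#' @return Named list of [lifestyle_spec()] objects.
#' @export
default_lifestyle_specs <- function() {
  vars <- c("vocational_degree", "video_games", "watching_videos",
            "playing_instrument", "reading", "going_out", "dancing",
            "club_participation", "fast_food", "bars", "smoking",
            "alcohol_use", "drinking_to_intoxication", "early_sexual_initiation")
  base <- c(0.20, 0.30, 0.28, 0.18, 0.25, 0.33, 0.22, 0.17, 0.27, 0.31,
            0.24, 0.36, 0.26, 0.19)
  specs <- purrr::map2(vars, base, function(v, b) {
    cp <- if (v == "drinking_to_intoxication") c(proteome = 0.3) else numeric(0)
    lifestyle_spec(v, baseline = b, coupling = cp, missing_prob = 0.05)
  })
  setNames(specs, vars)
}

#' Build a simulation configuration
#'
#' Defaults emulate the cohort the analysis was designed for: 257 same-sex
#' twin pairs (140 MZ / 117 DZ, 63% female pairs), blood sampling at mean
#' age 22.3 (sd 0.6) years with co-twins sampled the same day in three
#' fourths of pairs, and 80/257 pairs co-resident (hence sharing an
#' identical external-exposome record).
#'
#' @param n_pairs Number of twin pairs (>= 2).
#' @param prop_mz Fraction of monozygotic pairs.
#' @param domains Named list of [domain_spec()] objects.
#' @param lifestyle Named list of [lifestyle_spec()] objects.
#' @param prop_female Fraction of female pairs (pairs are same-sex).
#' @param co_residence_prob Probability a pair still shares a household.
#' @param age_mean_years,age_sd_years Age at blood sampling distribution.
#' @param age_diff_zero_prob Probability the co-twins are sampled on the
#'   same day.
#' @param age_diff_days_max Maximum sampling-date difference (days) for the
#'   remaining pairs (uniform on 1..max).
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   configuration including the seed.
#'
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_pairs = 257L, prop_mz = 140 / 257,
                       domains = default_domain_specs(),
                       lifestyle = default_lifestyle_specs(),
                       prop_female = 163 / 257,
                       co_residence_prob = 80 / 257,
                       age_mean_years = 22.3, age_sd_years = 0.6,
                       age_diff_zero_prob = 0.75, age_diff_days_max = 160L,
                       seed = 1L) {
  n_pairs <- as.integer(n_pairs)
  if (is.na(n_pairs) || n_pairs < 2L) abort("`n_pairs` must be at least 2")
  check_fraction(prop_mz, "prop_mz")
  check_fraction(prop_female, "prop_female")
  check_fraction(co_residence_prob, "co_residence_prob")
  check_fraction(age_diff_zero_prob, "age_diff_zero_prob")
  if (!length(domains)) abort("at least one domain_spec is required")
  for (d in domains) {
    if (!inherits(d, "domain_spec")) abort("`domains` must contain domain_spec objects")
  }
  for (l in lifestyle) {
    if (!inherits(l, "lifestyle_spec")) abort("`lifestyle` must contain lifestyle_spec objects")
  }
  dn <- vapply(domains, `[[`, character(1), "name")
  if (anyDuplicated(dn) > 0) abort("duplicated domain names")
  domains <- setNames(domains, dn)
  if (length(lifestyle)) {
    ln <- vapply(lifestyle, `[[`, character(1), "name")
    if (anyDuplicated(ln) > 0) abort("duplicated lifestyle variable names")
    lifestyle <- setNames(lifestyle, ln)
    for (l in lifestyle) {
      unknown <- setdiff(names(l$coupling), dn)
      if (length(unknown)) {
        abort(paste0("lifestyle coupling refers to unknown domain(s): ",
                     paste(unknown, collapse = ", ")))
      }
    }
  }
  structure(list(n_pairs = n_pairs, prop_mz = prop_mz, domains = domains,
                 lifestyle = lifestyle, prop_female = prop_female,
                 co_residence_prob = co_residence_prob,
                 age_mean_years = age_mean_years, age_sd_years = age_sd_years,
                 age_diff_zero_prob = age_diff_zero_prob,
                 age_diff_days_max = as.integer(age_diff_days_max),
                 seed = as.integer(seed)),
            class = "sim_config")
}
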
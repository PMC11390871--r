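#' Drop features with excess missingness
#'
#' Retains features whose fraction of missing values is at most
#' `max_fraction` (strictly greater is excluded), mirroring the usual
#' quality-control rule for proteomic and metabolomic panels.
#'
#' @param data Domain tibble: a `twin_id` column plus numeric features.
#' @param max_fraction Maximum tolerated missing fraction; default 0.10.
#' @param id_col Name of the identifier column.
#' @return The domain tibble with failing features removed.
#' @export
filter_missing_features <- function(data, max_fraction = 0.10,
                                    id_col = "twin_id") {
  check_fraction(max_fraction, "max_fraction", 0, 1, open_hi = TRUE)
  d <- split_domain(data, id_col)
  frac <- colMeans(is.na(d$values))
  keep <- frac <= max_fraction
  if (!any(keep)) abort("no features pass the missingness filter")
  rebuild_domain(d$ids, d$values[, keep, drop = FALSE], id_col)
}

#' Impute missing values by the observed feature minimum
#'
#' Replaces each missing cell with the minimum observed value of its
#' feature; observed cells are untouched.
#'
#' @inheritParams filter_missing_features
#' @return The imputed domain tibble (no missing values).
#' @export
impute_minimum <- function(data, id_col = "twin_id") {
  d <- split_domain(data, id_col)
  m <- d$values
  all_missing <- colSums(!is.na(m)) == 0L
  if (any(all_missing)) {
    abort(paste0("feature(s) with no observed values: ",
                 paste(d$feature_names[all_missing], collapse = ", ")))
  }
  for (j in which(colSums(is.na(m)) > 0L)) {
    m[is.na(m[, j]), j] <- min(m[, j], na.rm = TRUE)
  }
  rebuild_domain(d$ids, m, id_col)
}

#' Inverse-normal rank transformation
#'
#' Maps values to normal quantiles of their (Blom-offset) ranks:
#' `qnorm((rank - c) / (n - 2c + 1))` with offset `c = 3/8` and average
#' ranks for ties. Order-preserving; missing values propagate.
#'
#' @param x Numeric vector, at least two observed values, not all tied.
#' @param offset Rank offset; 3/8 (Blom) by default.
#' @return Transformed vector of the same length.
#' @export
inverse_normal_transform <- function(x, offset = 3 / 8) {
  obs <- !is.na(x)
  n <- sum(obs)
  if (n < 2L) abort("need at least two observed values")
  if (length(unique(x[obs])) == 1L) abort("constant vector cannot be rank-transformed")
  r <- rank(x[obs], ties.method = "average")
  out <- rep(NA_real_, length(x))
  out[obs] <- qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

#' Standardize features to mean zero, unit variance
#'
#' Scales every feature so one unit corresponds to one sample standard
#' deviation (divisor n - 1) with zero mean. Input must be complete.
#'
#' @inheritParams filter_missing_features
#' @return The standardized domain tibble.
#' @export
standardize_features <- function(data, id_col = "twin_id") {
  d <- split_domain(data, id_col)
  if (anyNA(d$values)) abort("standardization requires a complete matrix; impute first")
  s <- col_sds(d$values)
  if (any(s < .Machine$double.eps)) {
    abort(paste0("constant feature(s): ",
                 paste(d$feature_names[s < .Machine$double.eps], collapse = ", ")))
  }
  m <- scale(d$values, center = TRUE, scale = s)
  attr(m, "scaled:center") <- NULL
  attr(m, "scaled:scale") <- NULL
  rebuild_domain(d$ids, m, id_col)
}

#' Flag multivariate outliers on leading principal components
#'
#' Flags an individual when any of the first `n_components` standardized
#' principal-component scores exceeds `sd_threshold` standard deviations in
#' absolute value (the usual +/- 5 SD screen on the first three PCs).
#'
#' @inheritParams filter_missing_features
#' @param n_components Number of leading components screened (default 3).
#' @param sd_threshold Flagging threshold in component SDs (default 5).
#' @return Named logical vector (one flag per individual).
#' @export
pca_outlier_flags <- function(data, n_components = 3L, sd_threshold = 5,
                              id_col = "twin_id") {
  d <- split_domain(data, id_col)
  if (anyNA(d$values)) abort("PCA screen requires a complete matrix")
  pr <- prcomp(d$values, center = TRUE, scale. = FALSE)
  rank_ <- sum(pr$sdev > 1e-12 * max(pr$sdev))
  if (n_components > rank_) {
    abort(sprintf("n_components (%d) exceeds matrix rank (%d)", n_components, rank_))
  }
  z <- sweep(pr$x[, seq_len(n_components), drop = FALSE], 2,
             pr$sdev[seq_len(n_components)], "/")
  flags <- apply(abs(z) > sd_threshold, 1, any)
  setNames(flags, d$ids)
}

#' Epigenetic age acceleration as regression residuals
#'
#' EAA is the residual of epigenetic age after removing its linear
#' dependence on chronological age (OLS with intercept); a constant offset
#' between the two ages is absorbed and residuals have mean zero.
#'
#' @param epigenetic_age Numeric vector of clock-predicted ages (years).
#' @param chronological_age Numeric vector of chronological ages (years).
#' @return Residual vector (years).
#' @export
eaa_residuals <- function(epigenetic_age, chronological_age) {
  if (length(epigenetic_age) != length(chronological_age)) {
    abort("age vectors must have equal length")
  }
  if (length(epigenetic_age) < 3L) abort("need at least three individuals")
  if (sd(chronological_age) < .Machine$double.eps) {
    abort("chronological age is constant; residuals undefined")
  }
  unname(resid(lm(epigenetic_age ~ chronological_age)))
}

#' Default frequency-category dichotomization map
#'
#' Maps ordinal frequency labels to the binary contrast "at most once a
#' month" (0) versus "at least once a week" (1). Categories falling
#' strictly between the two modalities (e.g. 2-3 times a month) are mapped
#' according to `gap`: to missing (default), or forced low/high for
#' sensitivity reruns.
#'
#' @param gap One of `"missing"`, `"low"`, `"high"`.
#' @return Named integer vector (`NA` for the gap when `gap = "missing"`).
#' @export
frequency_map <- function(gap = c("missing", "low", "high")) {
  gap <- match.arg(gap)
  gap_value <- switch(gap, missing = NA_integer_, low = 0L, high = 1L)
  c("never" = 0L, "less than once a month" = 0L, "once a month" = 0L,
    "2-3 times a month" = gap_value,
    "once a week" = 1L, "2-3 times a week" = 1L,
    "daily" = 1L, "several times a day" = 1L)
}

#' Dichotomize an ordinal frequency response
#'
#' @param response Character vector of category labels.
#' @param map Named vector mapping each label to 0, 1 or `NA`; see
#'   [frequency_map()].
#' @return Integer vector in 0/1/NA.
#' @export
dichotomize_frequency <- function(response, map = frequency_map()) {
  obs <- !is.na(response)
  unknown <- setdiff(unique(response[obs]), names(map))
  if (length(unknown)) {
    abort(paste0("unknown frequency categories: ", paste(unknown, collapse = ", ")))
  }
  out <- rep(NA_integer_, length(response))
  out[obs] <- unname(map[response[obs]])
  out
}

#' Within-pair discordance indicator
#'
#' XOR of the two co-twins' binary responses: 1 when exactly one co-twin
#' expresses the feature, 0 when both or neither do. A pair is missing
#' whenever at least one co-twin's response is missing.
#'
#' @param twin1_value,twin2_value Integer vectors in 0/1/NA.
#' @return Integer vector in 0/1/NA.
#' @export
discordance_indicator <- function(twin1_value, twin2_value) {
  chk <- function(v) {
    if (!all(v %in% c(0L, 1L, NA))) abort("values must be 0, 1 or NA")
  }
  chk(twin1_value); chk(twin2_value)
  as.integer(xor(twin1_value == 1L, twin2_value == 1L))
}

#' Build the pair-level discordance table
#'
#' Joins a per-twin binary lifestyle table onto the pair table and applies
#' [discordance_indicator()] per variable.
#'
#' @param lifestyle Tibble with columns `twin_id`, `variable`, `value`
#'   (0/1/NA).
#' @param pairs Pair table (`pair_id`, `twin1_id`, `twin2_id`, ...).
#' @return Tibble `pair_id`, `variable`, `discordant` (0/1/NA).
#' @export
build_discordance_table <- function(lifestyle, pairs) {
  lifestyle <- as_tibble(lifestyle)
  v1 <- lifestyle %>% rename(twin1_id = "twin_id", value1 = "value")
  v2 <- lifestyle %>% rename(twin2_id = "twin_id", value2 = "value")
  pairs %>%
    select("pair_id", "twin1_id", "twin2_id") %>%
    tidyr::crossing(variable = unique(lifestyle$variable)) %>%
    left_join(v1, by = c("twin1_id", "variable")) %>%
    left_join(v2, by = c("twin2_id", "variable")) %>%
    mutate(discordant = discordance_indicator(.data$value1, .data$value2)) %>%
    select("pair_id", "variable", "discordant")
}

#' Run a domain's preprocessing pipeline
#'
#' Applies, in order, the missingness filter, minimum-value imputation,
#' optionally the inverse-normal rank transformation (used for NMR
#' metabolomics), and feature standardization.
#'
#' @inheritParams filter_missing_features
#' @param inverse_normal Apply [inverse_normal_transform()] per feature
#'   before standardizing.
#' @return The preprocessed domain tibble (complete, mean 0 / sd 1 columns).
#' @export
prep_domain <- function(data, max_fraction = 0.10, inverse_normal = FALSE,
                        id_col = "twin_id") {
  out <- data %>%
    filter_missing_features(max_fraction, id_col) %>%
    impute_minimum(id_col)
  if (inverse_normal) {
    out <- out %>%
      mutate(across(-all_of(id_col), inverse_normal_transform))
  }
  standardize_features(out, id_col)
}
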
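#' Remap proximity scores and apply the logit
#'
#' Sensitivity transform for skewed, bounded proximity scores: the
#' feasible range `[0, 1]` is linearly remapped onto `[lower, upper]`
#' (`x -> lower + (upper - lower) * x`, default `[0.025, 0.975]`) so the
#' boundary value 1 — outside the logit's valid range — maps to `upper`,
#' then the logit spreads values over the whole real axis. Strictly
#' increasing; the remap is defined from the theoretical range, not the
#' observed one, so the transform is dataset-independent (set
#' `from_observed = TRUE` to use the observed min/max instead).
#'
#' @param wpps Numeric vector of scores in `(0, 1]`.
#' @param lower,upper Target interval endpoints, `0 < lower < upper < 1`.
#' @param from_observed Remap from the observed range instead of `[0, 1]`.
#' @return Transformed vector on the real axis.
#' @export
remap_and_logit <- function(wpps, lower = 0.025, upper = 0.975,
                            from_observed = FALSE) {
  if (!length(wpps)) abort("empty score vector")
  if (!(is.numeric(lower) && is.numeric(upper) &&
        0 < lower && lower < upper && upper < 1)) {
    abort("need 0 < lower < upper < 1")
  }
  if (any(wpps < 0 | wpps > 1, na.rm = TRUE)) abort("scores must lie in [0, 1]")
  x <- wpps
  if (from_observed) {
    rng <- range(x, na.rm = TRUE)
    if (diff(rng) < .Machine$double.eps) abort("degenerate observed range")
    x <- (x - rng[1]) / diff(rng)
  }
  qlogis(lower + (upper - lower) * x)
}

#' Exclude pairs with a proximity score of exactly 1
#'
#' Drops, for the given domain, pairs whose score equals 1 exactly (the
#' identity criterion of [compute_wpps()]; in the emulated design these
#' are co-resident pairs sharing one external-exposome record). Scores of
#' other domains are untouched.
#'
#' @param wpps A `wpps_tbl`.
#' @param domain Domain whose unity-score pairs are removed (default
#'   `"exposome"`).
#' @return The filtered `wpps_tbl`.
#' @export
exclude_unity_pairs <- function(wpps, domain = "exposome") {
  out <- wpps %>%
    as_tibble() %>%
    filter(!(.data$domain == .env$domain & .data$wpps == 1))
  class(out) <- c("wpps_tbl", class(out))
  out
}

# Sample skewness (moment estimator), used by diagnostics and tests.
skewness <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2)^1.5)
}
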
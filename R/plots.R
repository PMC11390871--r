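#' @importFrom ggplot2 ggplot aes autoplot geom_histogram geom_point
#'   geom_errorbar geom_errorbarh geom_abline geom_hline geom_vline
#'   facet_wrap labs theme_minimal scale_color_manual coord_flip
NULL

#' @export
ggplot2::autoplot

#' Plot the distribution of proximity scores per domain
#'
#' Histograms of WPPS faceted by domain; when a pair table is supplied
#' bars are colored by zygosity, which makes the MZ > DZ proximity shift
#' of heritable domains directly visible.
#'
#' @param object A `wpps_tbl`.
#' @param pairs Optional pair table for zygosity coloring.
#' @param bins Histogram bins (default 30).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wpps_tbl
#' @export
autoplot.wpps_tbl <- function(object, pairs = NULL, bins = 30, ...) {
  dat <- as_tibble(object)
  if (!is.null(pairs)) {
    dat <- dat %>% left_join(pairs %>% select("pair_id", "zygosity"),
                             by = "pair_id")
    p <- ggplot(dat, aes(x = .data$wpps, fill = .data$zygosity))
  } else {
    p <- ggplot(dat, aes(x = .data$wpps))
  }
  p +
    geom_histogram(bins = bins, position = "identity", alpha = 0.6) +
    facet_wrap(~domain, scales = "free_y") +
    labs(x = "within-pair proximity score", y = "pairs") +
    theme_minimal()
}

#' Plot MZ vs DZ standardized cross-domain estimates
#'
#' Scatter of standardized MZ against DZ coefficients with 95% confidence
#' bars on both axes; points above the diagonal are domain pairs whose
#' association is stronger among the genetically fully matched MZ pairs.
#'
#' @param object A `wpps_zcomp` from [stratified_z_comparison()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wpps_zcomp
#' @export
autoplot.wpps_zcomp <- function(object, ...) {
  dat <- as_tibble(object) %>%
    mutate(pair = paste(.data$dependent, "~", .data$independent))
  ggplot(dat, aes(x = .data$b_dz, y = .data$b_mz, color = .data$pair)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    geom_errorbar(aes(ymin = .data$b_mz - 1.96 * .data$se_mz,
                      ymax = .data$b_mz + 1.96 * .data$se_mz), width = 0) +
    geom_errorbarh(aes(xmin = .data$b_dz - 1.96 * .data$se_dz,
                       xmax = .data$b_dz + 1.96 * .data$se_dz), height = 0) +
    geom_point(size = 2) +
    labs(x = "standardized estimate (DZ pairs)",
         y = "standardized estimate (MZ pairs)", color = NULL) +
    theme_minimal()
}

#' Plot ExWAS results
#'
#' -log10 nominal p-values of every WPPS-discordance test, faceted by
#' domain, with the nominal 0.05 line dashed and FDR-flagged associations
#' highlighted.
#'
#' @param object A `wpps_exwas` from [exwas()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wpps_exwas
#' @export
autoplot.wpps_exwas <- function(object, ...) {
  dat <- as_tibble(object)
  ggplot(dat, aes(x = .data$independent, y = -log10(.data$p),
                  color = .data$flagged)) +
    geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    geom_point(size = 2) +
    facet_wrap(~dependent) +
    scale_color_manual(values = c(`FALSE` = "grey40", `TRUE` = "goldenrod2"),
                       name = "FDR q < threshold") +
    coord_flip() +
    labs(x = NULL, y = expression(-log[10](italic(p)))) +
    theme_minimal()
}
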
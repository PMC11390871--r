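#' Cohort and score summary table
#'
#' One row per descriptor: pair counts by zygosity, sex of the pairs, age
#' at blood sampling, and per-domain WPPS mean/sd/range — the shape of a
#' standard cohort-description table.
#'
#' @param wpps A `wpps_tbl`.
#' @param pairs Pair table.
#' @return Tibble: `quantity`, `mean_or_n`, `sd`, `min`, `max`.
#' @export
cohort_summary <- function(wpps, pairs) {
  ages <- c(pairs$age_blood_twin1, pairs$age_blood_twin2)
  base <- tibble(
    quantity = c("n_pairs", "n_pairs_mz", "n_pairs_dz",
                 "n_pairs_male", "n_pairs_female", "age_blood"),
    mean_or_n = c(nrow(pairs), sum(pairs$zygosity == "MZ"),
                  sum(pairs$zygosity == "DZ"), sum(pairs$sex == "M"),
                  sum(pairs$sex == "F"), mean(ages)),
    sd = c(rep(NA_real_, 5), sd(ages)),
    min = c(rep(NA_real_, 5), min(ages)),
    max = c(rep(NA_real_, 5), max(ages))
  )
  per_domain <- wpps %>%
    as_tibble() %>%
    group_by(.data$domain) %>%
    summarise(mean_or_n = mean(.data$wpps), sd = sd(.data$wpps),
              min = min(.data$wpps), max = max(.data$wpps),
              .groups = "drop") %>%
    mutate(quantity = paste0("wpps_", .data$domain), .before = 1) %>%
    select(-"domain")
  bind_rows(base, per_domain)
}

#' Run the full within-pair proximity analysis
#'
#' End-to-end driver: preprocesses each domain, computes WPPS, fits the
#' pair-covariate models, the prioritized cross-domain regressions (all
#' pairs plus MZ/DZ subsamples with the one-sided z-comparison), runs the
#' lifestyle-discordance ExWAS, and optionally reruns every analysis
#' involving the skew-prone domain under the two sensitivity schemes
#' (logit-remapped scores; exclusion of unity-score pairs). When `outdir`
#' is given all result tables are written as CSV together with a JSON run
#' log (seed, parameters, per-stage pair counts).
#'
#' @param cohort A `twin_cohort` (from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param sigma,metric Kernel parameters, see [compute_wpps()].
#' @param fdr_family,fdr_threshold ExWAS FDR settings, see [exwas()].
#' @param sensitivity Run the sensitivity reruns (default TRUE).
#' @param sensitivity_domain Domain targeted by the sensitivity analyses
#'   (default `"exposome"`; skipped when absent).
#' @param outdir Optional output directory for CSVs and the run log.
#' @return Object of class `"wpps_pipeline"`: list with `wpps`, `summary`,
#'   `covariate_models`, `cross_domain` (all/MZ/DZ stacked),
#'   `z_comparison`, `exwas`, `sensitivity` (named list or NULL) and
#'   `params`.
#' @export
run_pipeline <- function(cohort, sigma = 1,
                         metric = c("euclidean", "manhattan"),
                         fdr_family = c("per_domain", "pooled"),
                         fdr_threshold = 0.2, sensitivity = TRUE,
                         sensitivity_domain = "exposome", outdir = NULL) {
  stopifnot(inherits(cohort, "twin_cohort"))
  metric <- match.arg(metric)
  fdr_family <- match.arg(fdr_family)
  pairs <- cohort$pairs

  wpps <- compute_wpps_all(cohort, sigma = sigma, metric = metric)
  discord <- build_discordance_table(cohort$lifestyle, pairs)

  covariate_models <- wpps_covariate_models(wpps, pairs)
  cross_domain <- bind_rows(
    cross_domain_models(wpps, pairs, "all"),
    cross_domain_models(wpps, pairs, "MZ", standardize = TRUE),
    cross_domain_models(wpps, pairs, "DZ", standardize = TRUE)
  )
  z_comparison <- stratified_z_comparison(wpps, pairs)
  exwas_res <- exwas(wpps, discord, pairs, fdr_family = fdr_family,
                     fdr_threshold = fdr_threshold)

  sens <- NULL
  if (isTRUE(sensitivity) && sensitivity_domain %in% wpps$domain) {
    logit_wpps <- wpps %>%
      mutate(wpps = ifelse(.data$domain == sensitivity_domain,
                           remap_and_logit(.data$wpps), .data$wpps))
    excl_wpps <- exclude_unity_pairs(wpps, sensitivity_domain)
    run_variant <- function(w) {
      list(
        cross_domain = cross_domain_models(w, pairs, "all") %>%
          filter(.data$dependent == sensitivity_domain |
                   .data$independent == sensitivity_domain),
        exwas = exwas(w, discord, pairs, fdr_family = fdr_family,
                      fdr_threshold = fdr_threshold) %>%
          filter(.data$dependent == sensitivity_domain)
      )
    }
    sens <- list(logit_remap = run_variant(logit_wpps),
                 exclude_unity = run_variant(excl_wpps))
    sens$n_excluded <- sum(wpps$domain == sensitivity_domain & wpps$wpps == 1)
  }

  out <- structure(list(
    wpps = wpps,
    summary = cohort_summary(wpps, pairs),
    covariate_models = covariate_models,
    cross_domain = cross_domain,
    z_comparison = z_comparison,
    exwas = exwas_res,
    sensitivity = sens,
    params = list(sigma = sigma, metric = metric, fdr_family = fdr_family,
                  fdr_threshold = fdr_threshold,
                  seed = tryCatch(cohort$config$seed, error = function(e) NULL),
                  coding = c(zygosity_mz = "MZ=1/DZ=0", sex_f = "F=1/M=0"),
                  n_pairs = nrow(pairs),
                  pairs_per_domain = wpps %>% count(.data$domain) %>%
                    tibble::deframe())
  ), class = "wpps_pipeline")

  if (!is.null(outdir)) write_pipeline(out, outdir)
  out
}

write_pipeline <- function(x, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(as_tibble(x$wpps), file.path(outdir, "wpps.csv"))
  readr::write_csv(x$summary, file.path(outdir, "summary.csv"))
  readr::write_csv(x$covariate_models, file.path(outdir, "covariate_models.csv"))
  readr::write_csv(x$cross_domain, file.path(outdir, "cross_domain.csv"))
  readr::write_csv(as_tibble(x$z_comparison), file.path(outdir, "z_comparison.csv"))
  readr::write_csv(as_tibble(x$exwas), file.path(outdir, "exwas.csv"))
  if (!is.null(x$sensitivity)) {
    for (v in c("logit_remap", "exclude_unity")) {
      readr::write_csv(x$sensitivity[[v]]$cross_domain,
                       file.path(outdir, paste0("sensitivity_", v, "_cross_domain.csv")))
      readr::write_csv(as_tibble(x$sensitivity[[v]]$exwas),
                       file.path(outdir, paste0("sensitivity_", v, "_exwas.csv")))
    }
  }
  log <- x$params
  log$pairs_per_domain <- as.list(log$pairs_per_domain)
  log$coding <- as.list(log$coding)
  log$n_unity_excluded <- x$sensitivity$n_excluded
  jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.wpps_pipeline <- function(x, ...) {
  cat(sprintf("<wpps_pipeline> %d pairs, domains: %s\n", x$params$n_pairs,
              paste(names(x$params$pairs_per_domain), collapse = ", ")))
  cat(sprintf("  kernel: %s distance, sigma = %g\n", x$params$metric,
              x$params$sigma))
  cat(sprintf("  cross-domain models: %d | ExWAS tests: %d (%d flagged at q < %g)\n",
              nrow(x$cross_domain), nrow(x$exwas), sum(x$exwas$flagged),
              x$params$fdr_threshold))
  if (!is.null(x$sensitivity)) {
    cat(sprintf("  sensitivity reruns: logit remap + exclusion of %d unity-score pair(s)\n",
                x$sensitivity$n_excluded))
  }
  invisible(x)
}

#' Tidy the results of a pipeline run
#'
#' Stacks the requested association tables into one tibble with a `layer`
#' column (`covariate`, `cross_domain`, `exwas`).
#'
#' @param x A `wpps_pipeline`.
#' @param layer Which layers to include; default all three.
#' @param ... Unused.
#' @return A tibble of association results.
#' @method tidy wpps_pipeline
#' @export
tidy.wpps_pipeline <- function(x, layer = c("covariate", "cross_domain", "exwas"),
                               ...) {
  layer <- match.arg(layer, several.ok = TRUE)
  parts <- list()
  if ("covariate" %in% layer) {
    parts$covariate <- x$covariate_models %>% mutate(layer = "covariate")
  }
  if ("cross_domain" %in% layer) {
    parts$cross_domain <- x$cross_domain %>% mutate(layer = "cross_domain")
  }
  if ("exwas" %in% layer) {
    parts$exwas <- as_tibble(x$exwas) %>% mutate(layer = "exwas")
  }
  bind_rows(parts) %>% select("layer", dplyr::everything())
}

#' One-row summary of a pipeline run
#'
#' @param x A `wpps_pipeline`.
#' @param ... Unused.
#' @return One-row tibble: pair counts, domain count, kernel parameters,
#'   number of ExWAS tests and flagged associations.
#' @method glance wpps_pipeline
#' @export
glance.wpps_pipeline <- function(x, ...) {
  tibble(
    n_pairs = x$params$n_pairs,
    n_domains = length(x$params$pairs_per_domain),
    sigma = x$params$sigma,
    metric = x$params$metric,
    n_cross_domain = nrow(x$cross_domain),
    n_exwas = nrow(x$exwas),
    n_exwas_flagged = sum(x$exwas$flagged),
    fdr_threshold = x$params$fdr_threshold
  )
}
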
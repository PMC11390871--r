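#' Simulate a twin cohort with ACE structure
#'
#' Generates a synthetic cohort of same-sex MZ/DZ twin pairs with
#' per-domain feature matrices, pair metadata and binary lifestyle
#' variables, following the classical twin (ACE) decomposition: each latent
#' factor value is `sqrt(a2)*A + sqrt(c2)*C + sqrt(e2)*E`, with the
#' additive-genetic part `A` correlating 1 within MZ pairs and exactly 0.5
#' within DZ pairs (`A2 = 0.5*A1 + sqrt(0.75)*A'`), the common environment
#' `C` shared within a pair and the unique environment `E` twin-specific.
#' Observed features are fixed linear mixtures of the pair's latent factors
#' plus independent feature noise. Co-resident pairs receive byte-identical
#' rows in domains flagged `coresident_identical` (the external exposome).
#' Lifestyle discordance is Bernoulli on the logit scale with optional
#' coupling to standardized within-pair domain distances.
#'
#' The closed-form within-pair correlation of a latent factor is
#' `a2 + c2` for MZ pairs and `0.5*a2 + c2` for DZ pairs; the planted
#' latent factors are kept in `truth` so recovery tests need no side
#' channel.
#'
#' @param config A [sim_config()] object.
#'
#' @return An object of class `"twin_cohort"`: a list with elements
#'   `pairs` (tibble: `pair_id`, `twin1_id`, `twin2_id`, `zygosity`, `sex`,
#'   `age_blood_twin1`, `age_blood_twin2`, `age_left_home`, `co_resident`),
#'   `domains` (named list of tibbles, `twin_id` + feature columns),
#'   `lifestyle` (tibble: `twin_id`, `variable`, `value` in 0/1/NA),
#'   `truth` (planted latent factors, distances and parameters) and
#'   `config`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(
#'   n_pairs = 20,
#'   domains = list(domain_spec("omics", 12, n_latent = 4)),
#'   lifestyle = list(lifestyle_spec("smoking")),
#'   seed = 7
#' ))
#' cohort$pairs
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config")
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  n <- config$n_pairs
  pair_id <- sprintf("p%04d", seq_len(n))
  twin1_id <- paste0(pair_id, "_1")
  twin2_id <- paste0(pair_id, "_2")
  n_mz <- as.integer(round(n * config$prop_mz))
  zygosity <- c(rep("MZ", n_mz), rep("DZ", n - n_mz))
  sex <- ifelse(runif(n) < config$prop_female, "F", "M")

  age_base <- rnorm(n, config$age_mean_years, config$age_sd_years)
  same_day <- runif(n) < config$age_diff_zero_prob
  diff_days <- ifelse(same_day, 0,
                      sample.int(max(config$age_diff_days_max, 1L), n,
                                 replace = TRUE))
  diff_sign <- sample(c(-1, 1), n, replace = TRUE)
  age1 <- age_base
  age2 <- age_base + diff_sign * diff_days / 365.25

  co_resident <- runif(n) < config$co_residence_prob
  age_left_home <- pmax(rnorm(n, 18.3, 1.2), 15)
  age_left_home <- pmin(age_left_home, pmin(age1, age2))
  age_left_home[co_resident] <- NA_real_

  pairs <- tibble(
    pair_id = pair_id, twin1_id = twin1_id, twin2_id = twin2_id,
    zygosity = zygosity, sex = sex,
    age_blood_twin1 = age1, age_blood_twin2 = age2,
    age_left_home = age_left_home, co_resident = co_resident
  )

  mz <- zygosity == "MZ"
  domains <- list()
  truth_latent <- list()
  pair_dist <- list()
  for (spec in config$domains) {
    g <- simulate_domain(spec, n, mz, co_resident, twin1_id, twin2_id)
    domains[[spec$name]] <- g$data
    truth_latent[[spec$name]] <- g$latent
    pair_dist[[spec$name]] <- g$dist
  }

  lifestyle <- simulate_lifestyle(config$lifestyle, pair_dist, n,
                                  twin1_id, twin2_id)

  truth <- list(
    latent = truth_latent,
    pair_distance = as_tibble(c(list(pair_id = pair_id), pair_dist)),
    domain_params = purrr::map(config$domains, function(d) {
      d[c("a2", "c2", "e2", "feature_noise", "n_latent", "n_features",
          "coresident_identical")]
    }),
    lifestyle_params = purrr::map(config$lifestyle, function(l) {
      list(baseline = l$baseline, coupling = as.list(l$coupling),
           missing_prob = l$missing_prob)
    })
  )

  structure(list(pairs = pairs, domains = domains,
                 lifestyle = lifestyle$table, truth = truth,
                 config = config),
            class = "twin_cohort")
}

simulate_domain <- function(spec, n, mz, co_resident, twin1_id, twin2_id) {
  L <- spec$n_latent
  p <- spec$n_features
  a <- sqrt(spec$a2); cc <- sqrt(spec$c2); e <- sqrt(spec$e2)

  A1 <- matrix(rnorm(n * L), n, L)
  A2 <- A1
  if (any(!mz)) {
    A2[!mz, ] <- 0.5 * A1[!mz, , drop = FALSE] +
      sqrt(0.75) * matrix(rnorm(sum(!mz) * L), sum(!mz), L)
  }
  C <- matrix(rnorm(n * L), n, L)
  F1 <- a * A1 + cc * C + e * matrix(rnorm(n * L), n, L)
  F2 <- a * A2 + cc * C + e * matrix(rnorm(n * L), n, L)

  W <- matrix(rnorm(L * p), L, p)
  wnorm <- sqrt(colSums(W^2))
  tau <- spec$feature_noise
  mix <- function(F_) {
    S <- sweep(F_ %*% W, 2, wnorm, "/") * sqrt(1 - tau)
    S + sqrt(tau) * matrix(rnorm(n * p), n, p)
  }
  X1 <- mix(F1)
  X2 <- mix(F2)
  if (spec$coresident_identical && any(co_resident)) {
    X2[co_resident, ] <- X1[co_resident, , drop = FALSE]
  }

  X <- matrix(0, 2 * n, p)
  X[seq(1, 2 * n, by = 2), ] <- X1
  X[seq(2, 2 * n, by = 2), ] <- X2
  ids <- character(2 * n)
  ids[seq(1, 2 * n, by = 2)] <- twin1_id
  ids[seq(2, 2 * n, by = 2)] <- twin2_id
  colnames(X) <- sprintf("%s_f%03d", spec$name, seq_len(p))

  list(
    data = rebuild_domain(ids, X),
    latent = list(twin1 = F1, twin2 = F2),
    dist = sqrt(rowSums((X1 - X2)^2))
  )
}

simulate_lifestyle <- function(specs, pair_dist, n, twin1_id, twin2_id) {
  if (!length(specs)) {
    return(list(table = tibble(twin_id = character(), variable = character(),
                               value = integer())))
  }
  z <- purrr::map(pair_dist, function(d) {
    s <- sd(d)
    if (s < .Machine$double.eps) rep(0, length(d)) else (d - mean(d)) / s
  })
  rows <- purrr::map(specs, function(l) {
    lp <- rep(qlogis(l$baseline), n)
    for (d in names(l$coupling)) lp <- lp + l$coupling[[d]] * z[[d]]
    disc <- rbinom(n, 1L, plogis(lp))
    t1 <- rbinom(n, 1L, 0.5)
    t2 <- as.integer(xor(t1 == 1L, disc == 1L))
    miss1 <- runif(n) < l$missing_prob
    miss2 <- runif(n) < l$missing_prob
    t1[miss1] <- NA_integer_
    t2[miss2] <- NA_integer_
    tibble(twin_id = c(twin1_id, twin2_id),
           variable = l$name,
           value = c(t1, t2))
  })
  list(table = bind_rows(rows))
}

#' @export
print.twin_cohort <- function(x, ...) {
  n <- nrow(x$pairs)
  nm <- sum(x$pairs$zygosity == "MZ")
  cat(sprintf("<twin_cohort> %d pairs (%d MZ / %d DZ), %d domain(s), %d lifestyle variable(s)\n",
              n, nm, n - nm, length(x$domains),
              length(unique(x$lifestyle$variable))))
  cat("domains:",
      paste(sprintf("%s[%d]", names(x$domains),
                    vapply(x$domains, function(d) ncol(d) - 1L, integer(1))),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write a simulated cohort as delimited text
#'
#' Writes one CSV per domain (`<domain>.csv`, rows = twins), `pairs.csv`,
#' `lifestyle.csv`, and a `cohort.json` sidecar echoing the configuration
#' and the planted (scalar) truth parameters. Latent factor matrices are
#' not serialized; they live only in the in-memory `truth` record.
#'
#' @param cohort A `twin_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "twin_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$pairs, file.path(dir, "pairs.csv"))
  readr::write_csv(cohort$lifestyle, file.path(dir, "lifestyle.csv"))
  for (d in names(cohort$domains)) {
    readr::write_csv(cohort$domains[[d]], file.path(dir, paste0(d, ".csv")))
  }
  cfg <- cohort$config
  sidecar <- list(
    n_pairs = cfg$n_pairs, prop_mz = cfg$prop_mz, seed = cfg$seed,
    co_residence_prob = cfg$co_residence_prob,
    age_mean_years = cfg$age_mean_years, age_sd_years = cfg$age_sd_years,
    domains = cohort$truth$domain_params,
    lifestyle = cohort$truth$lifestyle_params
  )
  jsonlite::write_json(sidecar, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `pairs.csv`, `lifestyle.csv` and one CSV
#'   per domain.
#' @return A `twin_cohort` (without latent-factor truth matrices).
#' @export
read_cohort <- function(dir) {
  pairs <- readr::read_csv(file.path(dir, "pairs.csv"),
                           show_col_types = FALSE)
  lifestyle <- readr::read_csv(file.path(dir, "lifestyle.csv"),
                               show_col_types = FALSE)
  sidecar_path <- file.path(dir, "cohort.json")
  sidecar <- if (file.exists(sidecar_path)) {
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  }
  files <- setdiff(list.files(dir, pattern = "\\.csv$"),
                   c("pairs.csv", "lifestyle.csv"))
  domains <- purrr::map(files, function(f) {
    readr::read_csv(file.path(dir, f), show_col_types = FALSE)
  })
  names(domains) <- sub("\\.csv$", "", files)
  structure(list(pairs = pairs, domains = domains, lifestyle = lifestyle,
                 truth = sidecar, config = sidecar),
            class = "twin_cohort")
}
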
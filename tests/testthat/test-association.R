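test_that("fit_linear matches hand-solved normal equations", {
  # printed 5-point toy dataset
  toy <- tibble::tibble(x = c(1, 2, 3, 4, 5), y = c(2.1, 3.9, 6.2, 8.1, 9.8))
  X <- cbind(1, toy$x)
  beta <- solve(t(X) %*% X, t(X) %*% toy$y)
  res <- fit_linear(toy, y ~ x)
  expect_equal(res$estimate, beta[2], tolerance = 1e-10)
  rss <- sum((toy$y - X %*% beta)^2)
  tss <- sum((toy$y - mean(toy$y))^2)
  expect_equal(res$r_squared, 1 - rss / tss, tolerance = 1e-10)
  se_hand <- sqrt((rss / 3) * solve(t(X) %*% X)[2, 2])
  expect_equal(res$se, se_hand, tolerance = 1e-10)
  # p consistent with the t reference distribution
  expect_equal(res$p, 2 * pt(abs(res$statistic), df = 3, lower.tail = FALSE),
               tolerance = 1e-6)

  # noiseless and orthogonal cases
  exact <- tibble::tibble(x = 1:10, y = 2 * (1:10))
  noiseless <- suppressWarnings(fit_linear(exact, y ~ x)) # perfect-fit note
  expect_equal(noiseless$estimate, 2, tolerance = 1e-12)
  expect_equal(noiseless$r_squared, 1, tolerance = 1e-12)
  orth <- tibble::tibble(x = c(-1, -1, 1, 1), y = c(-1, 1, -1, 1))
  expect_equal(fit_linear(orth, y ~ x)$estimate, 0, tolerance = 1e-10)
  expect_error(fit_linear(tibble::tibble(x = 1:4, z = 2 * (1:4) + 1, y = rnorm(4)),
                          y ~ x + z), "rank-deficient")
})

test_that("covariate models recover a planted zygosity effect", {
  hits <- vapply(1:20, function(s) {
    co <- simulate_cohort(small_config(n_pairs = 250, seed = 200 + s))
    wpps <- compute_wpps_all(co)
    res <- wpps_covariate_models(wpps, co$pairs)
    zyg <- res[res$independent == "zygosity_mz", ]
    zyg$estimate > 0 && zyg$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("covariate models are null when no genetic effect is planted", {
  est <- vapply(1:20, function(s) {
    co <- simulate_cohort(small_config(n_pairs = 120, seed = 300 + s,
                                       a2 = 0, c2 = 0.5, e2 = 0.5))
    wpps <- compute_wpps_all(co)
    res <- wpps_covariate_models(wpps, co$pairs)
    res$estimate[res$independent == "zygosity_mz"]
  }, numeric(1))
  expect_lt(abs(mean(est)), 3 * sd(est) / sqrt(length(est)))
  expect_error(
    wpps_covariate_models(
      compute_wpps_all(simulate_cohort(small_config(n_pairs = 10, seed = 1,
                                                    prop_mz = 1)))
      , simulate_cohort(small_config(n_pairs = 10, seed = 1, prop_mz = 1))$pairs),
    "both MZ and DZ")
})

test_that("cross-domain orientation follows the stated priority", {
  co <- simulate_cohort(two_domain_config(n_pairs = 40, seed = 33))
  wpps <- compute_wpps_all(co)
  res <- cross_domain_models(wpps, co$pairs)
  row <- res[res$independent == "omics" | res$dependent == "omics", ][1, ]
  expect_equal(row$dependent, "exposome")
  expect_equal(row$independent, "omics")
})

test_that("cross-domain regression recovers a planted slope and respects overlap", {
  set.seed(34)
  reps <- vapply(1:20, function(s) {
    set.seed(400 + s)
    n <- 250
    w1 <- runif(n, 0.2, 0.9)
    w2 <- 0.5 * w1 + rnorm(n, sd = 0.05)
    pid <- sprintf("p%03d", 1:n)
    wpps <- tibble::tibble(
      pair_id = rep(pid, 2),
      domain = rep(c("metabolome", "proteome"), each = n),
      wpps = c(w1, w2), n_features = 10L, metric = "euclidean"
    )
    pairs <- tibble::tibble(
      pair_id = pid, twin1_id = paste0(pid, "_1"), twin2_id = paste0(pid, "_2"),
      zygosity = rep(c("MZ", "DZ"), length.out = n), sex = "F",
      age_blood_twin1 = 22, age_blood_twin2 = 22, age_left_home = 18,
      co_resident = FALSE
    )
    res <- cross_domain_models(wpps, pairs)
    # priority: proteome is dependent, metabolome independent
    expect_equal(res$dependent, "proteome")
    (res$estimate - 0.5) / res$se
  }, numeric(1))
  expect_true(all(abs(reps) < 3.5))

  # independent scores -> estimate centered at zero
  set.seed(35)
  n <- 200
  pid <- sprintf("p%03d", 1:n)
  wpps0 <- tibble::tibble(
    pair_id = rep(pid, 2), domain = rep(c("eaa", "proteome"), each = n),
    wpps = runif(2 * n, 0.2, 0.9), n_features = 5L, metric = "euclidean"
  )
  pairs0 <- tibble::tibble(
    pair_id = pid, twin1_id = paste0(pid, "_1"), twin2_id = paste0(pid, "_2"),
    zygosity = "MZ", sex = "F", age_blood_twin1 = 22, age_blood_twin2 = 22,
    age_left_home = 18, co_resident = FALSE
  )
  res0 <- cross_domain_models(wpps0, pairs0)
  expect_lt(abs(res0$estimate / res0$se), 3.5)

  expect_warning(
    out <- cross_domain_models(wpps0[c(1:5, n + (1:5)), ], pairs0),
    "overlapping pairs")
  expect_equal(nrow(out), 0L)
})

test_that("z-comparison matches the hand-computed normal evaluation", {
  # bMZ = 0.40 (se 0.10) vs bDZ = 0.10 (se 0.10)
  z <- (0.40 - 0.10) / sqrt(0.10^2 + 0.10^2)
  expect_equal(z, 0.30 / sqrt(0.02), tolerance = 1e-12)
  expect_equal(1 - pnorm(z), 0.01694743, tolerance = 1e-6)
})

test_that("stratified comparison is scale-free and calibrated under the null", {
  co <- simulate_cohort(two_domain_config(n_pairs = 80, seed = 36))
  wpps <- compute_wpps_all(co)
  base <- stratified_z_comparison(wpps, co$pairs)
  expect_equal(base$p_one_sided, 1 - pnorm(base$z), tolerance = 1e-12)

  scaled <- wpps
  scaled$wpps[scaled$domain == "omics"] <-
    scaled$wpps[scaled$domain == "omics"] * 7.3
  rescaled <- stratified_z_comparison(scaled, co$pairs)
  expect_equal(rescaled$z, base$z, tolerance = 1e-10)
  expect_equal(rescaled$b_mz, base$b_mz, tolerance = 1e-10)

  # identical planted slopes in both subsamples -> one-sided p roughly uniform
  set.seed(37)
  ps <- vapply(1:60, function(r) {
    n <- 120
    pid <- sprintf("p%03d", 1:n)
    w1 <- rnorm(n)
    w2 <- 0.4 * w1 + rnorm(n, sd = 0.8)
    wp <- tibble::tibble(pair_id = rep(pid, 2),
                         domain = rep(c("eaa", "proteome"), each = n),
                         wpps = plogis(c(w1, w2)), n_features = 5L,
                         metric = "euclidean")
    pr <- tibble::tibble(pair_id = pid, twin1_id = paste0(pid, "_1"),
                         twin2_id = paste0(pid, "_2"),
                         zygosity = rep(c("MZ", "DZ"), each = n / 2),
                         sex = "F", age_blood_twin1 = 22, age_blood_twin2 = 22,
                         age_left_home = 18, co_resident = FALSE)
    stratified_z_comparison(wp, pr)$p_one_sided
  }, numeric(1))
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("BH step-up matches the hand example and clips at one", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  # step-up definition on an uneven vector, computed by the formula
  p <- c(0.001, 0.02, 0.5, 0.9)
  m <- length(p)
  hand <- vapply(seq_along(p), function(i) {
    min(pmin(1, m * sort(p)[sort(p) >= p[i]] / which(sort(p) >= p[i])))
  }, numeric(1))
  expect_equal(bh_fdr(p), hand)
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("exwas reduces to a mean comparison without the covariate", {
  set.seed(38)
  n <- 60
  pid <- sprintf("p%03d", 1:n)
  w <- runif(n, 0.3, 0.9)
  disc <- rbinom(n, 1, 0.4)
  wpps <- tibble::tibble(pair_id = pid, domain = "proteome", wpps = w,
                         n_features = 10L, metric = "euclidean")
  class(wpps) <- c("wpps_tbl", class(wpps))
  pairs <- tibble::tibble(pair_id = pid, twin1_id = paste0(pid, "_1"),
                          twin2_id = paste0(pid, "_2"),
                          zygosity = rep(c("MZ", "DZ"), length.out = n),
                          sex = "F", age_blood_twin1 = 22,
                          age_blood_twin2 = 22, # zero age differences
                          age_left_home = 18, co_resident = FALSE)
  dtab <- tibble::tibble(pair_id = pid, variable = "v", discordant = disc)
  res <- suppressWarnings(exwas(wpps, dtab, pairs))
  # with a constant age difference the covariate is dropped by lm only if
  # collinear; here age_diff is constant 0 so the discordance term equals
  # the two-group mean difference
  expect_equal(res$estimate,
               mean(w[disc == 1]) - mean(w[disc == 0]), tolerance = 1e-10)
  expect_equal(res$n_discordant, sum(disc))

  # degenerate indicator -> skipped with warning
  dtab0 <- tibble::tibble(pair_id = pid, variable = "v",
                          discordant = rep(1L, n))
  expect_warning(expect_error(exwas(wpps, dtab0, pairs), "no .*combination"),
                 "skipping")
})

test_that("exwas recovers planted couplings and controls FDR under the null", {
  # planted coupling: discordance more likely for distant pairs
  hits <- vapply(1:15, function(s) {
    co <- simulate_cohort(small_config(
      n_pairs = 200, seed = 500 + s,
      lifestyle = list(lifestyle_spec("coupled", 0.35,
                                      coupling = c(omics = 1), missing_prob = 0),
                       lifestyle_spec("null", 0.35, missing_prob = 0))
    ))
    wpps <- compute_wpps_all(co)
    disc <- build_discordance_table(co$lifestyle, co$pairs)
    res <- exwas(wpps, disc, co$pairs)
    res$estimate[res$independent == "coupled"] < 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # full null: families with any q < 0.2 in at most ~20% of replicates
  disc_rate <- vapply(1:25, function(s) {
    co <- simulate_cohort(small_config(
      n_pairs = 100, seed = 600 + s, n_features = 10, n_latent = 3,
      lifestyle = purrr::map(1:8, function(i) {
        lifestyle_spec(paste0("v", i), 0.3, missing_prob = 0)
      })
    ))
    wpps <- compute_wpps_all(co)
    disc <- build_discordance_table(co$lifestyle, co$pairs)
    any(exwas(wpps, disc, co$pairs)$q < 0.2)
  }, logical(1))
  expect_lte(mean(disc_rate), 0.4)
})
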
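test_that("missingness filter keeps features at or below the threshold", {
  set.seed(1)
  m <- matrix(rnorm(50), 10, 5)
  # per-feature missing counts 0, 1, 1, 2, 0 out of 10
  m[1, 2] <- NA; m[4, 3] <- NA; m[c(2, 7), 4] <- NA
  d <- as_domain(m)
  out <- filter_missing_features(d, 0.10)
  expect_equal(setdiff(names(out), "twin_id"), c("f01", "f02", "f03", "f05"))

  # strictly-greater exclusion: 11/100 missing is out at 0.10, 10/100 stays
  m2 <- matrix(rnorm(200), 100, 2)
  m2[1:11, 1] <- NA
  m2[1:10, 2] <- NA
  out2 <- filter_missing_features(as_domain(m2), 0.10)
  expect_equal(setdiff(names(out2), "twin_id"), "f02")

  expect_identical(filter_missing_features(d[c("twin_id", "f01")], 0.1),
                   d[c("twin_id", "f01")])
  m3 <- matrix(NA_real_, 4, 2)
  expect_error(filter_missing_features(as_domain(m3), 0.1), "no features")
})

test_that("minimum imputation fills exactly the missing cells", {
  m <- matrix(c(2, NA, 5, 1,
                NA, 4, 3, 8,
                7, 6, NA, 2), 4, 3)
  hand <- m
  hand[2, 1] <- 1; hand[1, 2] <- 3; hand[3, 3] <- 2
  out <- impute_minimum(as_domain(m))
  expect_equal(unname(as.matrix(out[-1])), hand)
  # observed cells untouched, identity on complete input
  complete <- as_domain(matrix(rnorm(12), 4, 3))
  expect_identical(impute_minimum(complete), complete)
  all_na <- as_domain(cbind(c(1, 2, 3), NA_real_))
  expect_error(impute_minimum(all_na), "no observed values")
})

test_that("inverse-normal transform matches the Blom quantile formula", {
  x <- c(10, 20, 30, 40, 50)
  expected <- qnorm(((1:5) - 3 / 8) / (5 - 2 * (3 / 8) + 1))
  expect_equal(inverse_normal_transform(x), expected, tolerance = 1e-12)

  # order preservation: Spearman correlation 1 on noisy input with ties
  set.seed(4)
  y <- sample(rep(rnorm(20), 2))
  expect_equal(cor(y, inverse_normal_transform(y), method = "spearman"), 1)

  # middle of 3 distinct values maps to 0 by symmetry
  expect_equal(inverse_normal_transform(c(7, -2, 11))[1], 0)
  expect_error(inverse_normal_transform(rep(1, 5)), "constant")
  # ties share the average-rank quantile
  z <- inverse_normal_transform(c(1, 1, 5))
  expect_equal(z[1], z[2])
})

test_that("standardization yields exact z-scores and is idempotent", {
  d <- as_domain(cbind(a = c(1, 2, 3), b = c(5, 1, 0)))
  out <- standardize_features(d)
  expect_equal(out$a, c(-1, 0, 1))
  expect_equal(mean(out$b), 0, tolerance = 1e-12)
  expect_equal(sd(out$b), 1, tolerance = 1e-12)
  again <- standardize_features(out)
  expect_equal(as.matrix(again[-1]), as.matrix(out[-1]), tolerance = 1e-12)
  expect_error(standardize_features(as_domain(cbind(k = rep(2, 3), j = 1:3))),
               "k")
})

test_that("PCA outlier screen flags constructed outliers only", {
  set.seed(7)
  m <- matrix(rnorm(200 * 5), 200, 5)
  d <- as_domain(m)
  expect_false(any(pca_outlier_flags(d, 3, 5)))
  expect_false(any(pca_outlier_flags(d, 3, Inf)))

  # displace one individual far along the leading component
  pr <- prcomp(m)
  m_out <- m
  m_out[17, ] <- m_out[17, ] + 10 * pr$sdev[1] * pr$rotation[, 1]
  flags <- pca_outlier_flags(as_domain(m_out), 3, 5)
  expect_true(flags[[17]])
  expect_lt(sum(flags), 3)
  expect_error(pca_outlier_flags(as_domain(m[, 1:2]), n_components = 5), "rank")
})

test_that("EAA residuals follow closed-form OLS and absorb offsets", {
  chrono <- c(20, 21, 22, 23, 25)
  expect_equal(eaa_residuals(chrono, chrono), rep(0, 5))
  expect_equal(eaa_residuals(chrono + 2, chrono), rep(0, 5))

  epi <- c(21.5, 20.2, 24.1, 22.8, 26.0)
  X <- cbind(1, chrono)
  beta <- solve(t(X) %*% X, t(X) %*% epi)
  expect_equal(eaa_residuals(epi, chrono), drop(epi - X %*% beta),
               tolerance = 1e-10)
  expect_equal(mean(eaa_residuals(epi, chrono)), 0, tolerance = 1e-12)
  expect_error(eaa_residuals(epi, rep(22, 5)), "constant")
})

test_that("frequency dichotomization respects the modality gap", {
  expect_equal(dichotomize_frequency(c("never", "daily")), c(0L, 1L))
  expect_true(is.na(dichotomize_frequency("2-3 times a month")))
  expect_equal(dichotomize_frequency("2-3 times a month",
                                     frequency_map(gap = "low")), 0L)
  expect_equal(dichotomize_frequency("2-3 times a month",
                                     frequency_map(gap = "high")), 1L)
  expect_equal(dichotomize_frequency(c("once a month", "once a week")),
               c(0L, 1L))
  expect_error(dichotomize_frequency("sometimes"), "unknown")
})

test_that("discordance is a missing-propagating XOR", {
  expect_equal(discordance_indicator(1L, 0L), 1L)
  expect_equal(discordance_indicator(0L, 1L), 1L)
  expect_equal(discordance_indicator(1L, 1L), 0L)
  expect_equal(discordance_indicator(0L, 0L), 0L)
  expect_true(is.na(discordance_indicator(NA_integer_, 0L)))
  expect_true(is.na(discordance_indicator(1L, NA_integer_)))
  expect_error(discordance_indicator(2L, 0L), "0, 1 or NA")
})

test_that("discordance table equals brute-force per-pair XOR", {
  co <- simulate_cohort(small_config(
    n_pairs = 60, seed = 8,
    lifestyle = list(lifestyle_spec("a", 0.3, missing_prob = 0.1),
                     lifestyle_spec("b", 0.2, missing_prob = 0))
  ))
  disc <- build_discordance_table(co$lifestyle, co$pairs)
  for (v in c("a", "b")) {
    lv <- co$lifestyle[co$lifestyle$variable == v, ]
    val <- setNames(lv$value, lv$twin_id)
    brute <- mapply(function(t1, t2) {
      a <- val[[t1]]; b <- val[[t2]]
      if (is.na(a) || is.na(b)) NA_integer_ else as.integer(a != b)
    }, co$pairs$twin1_id, co$pairs$twin2_id)
    got <- disc$discordant[disc$variable == v][
      match(co$pairs$pair_id, disc$pair_id[disc$variable == v])]
    expect_identical(unname(got), unname(brute))
  }
})

test_that("prep pipeline output is complete and standardized", {
  set.seed(10)
  m <- matrix(rnorm(30 * 8), 30, 8)
  m[sample(length(m), 12)] <- NA
  m[, 8] <- ifelse(is.na(m[, 8]), NA, m[, 8]) # keep as-is
  out <- prep_domain(as_domain(m), inverse_normal = TRUE)
  v <- as.matrix(out[-1])
  expect_false(anyNA(v))
  expect_lt(max(abs(colMeans(v))), 1e-10)
  expect_equal(unname(apply(v, 2, sd)), rep(1, ncol(v)), tolerance = 1e-8)
})
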
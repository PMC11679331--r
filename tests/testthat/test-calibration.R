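test_that("an exact line is recovered under every weighting scheme", {
  pts <- calibration_points(c(1, 2, 3), c(1, 2, 3))
  for (w in c("none", "1/x", "1/x^2")) {
    fit <- fit_calibration(pts, weighting = w)
    expect_equal(fit$slope, 1, tolerance = 1e-12)
    expect_equal(fit$intercept, 0, tolerance = 1e-12)
    expect_equal(fit$r_squared, 1, tolerance = 1e-12)
    expect_true(all(abs(fit$residuals) < 1e-12))
  }
})

test_that("weighted fits match the closed-form normal-equations oracle", {
  sc <- assay_scenario(true_slope = 0.65, true_intercept = -0.5,
                       cv_proportional = 0.04, sd_additive = 0.002,
                       n_replicates = 2L, seed = 42L)
  pts <- gen_calibration(sc)
  for (w in c("none", "1/x", "1/x^2")) {
    fit <- fit_calibration(pts, weighting = w)
    orc <- wls_oracle(pts$nominal_conc, pts$response,
                      weights_for(pts$nominal_conc, w))
    expect_equal(fit$slope, orc$slope, tolerance = 1e-10)
    expect_equal(fit$intercept, orc$intercept, tolerance = 1e-10)
    expect_equal(fit$r_squared, orc$r_squared, tolerance = 1e-10)
    expect_equal(fit$sd_intercept, orc$se_intercept, tolerance = 1e-10)
  }
})

test_that("random small instances agree with the oracle under all schemes", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    x <- sort(stats::runif(n, 0.5, 100))
    y <- 0.7 * x + 0.1 + stats::rnorm(n, 0, 0.5)
    pts <- calibration_points(x, y)
    for (w in c("none", "1/x", "1/x^2")) {
      fit <- fit_calibration(pts, weighting = w)
      orc <- wls_oracle(x, y, weights_for(x, w))
      expect_equal(fit$slope, orc$slope, tolerance = 1e-10)
      expect_equal(fit$intercept, orc$intercept, tolerance = 1e-10)
    }
  }
})

test_that("equal weights reproduce ordinary least squares", {
  set.seed(11)
  x <- c(1, 5, 20, 80, 300)
  y <- 0.6 * x - 0.4 + stats::rnorm(5, 0, 0.3)
  ols <- fit_calibration(calibration_points(x, y), weighting = "none")
  orc <- wls_oracle(x, y)
  expect_equal(ols$slope, orc$slope, tolerance = 1e-12)
  expect_equal(ols$intercept, orc$intercept, tolerance = 1e-12)
})

test_that("grid search over slope/intercept agrees with the closed form", {
  set.seed(3)
  x <- c(1, 15, 50, 150, 300)
  y <- 0.65 * x - 0.5 + stats::rnorm(5, 0, 0.02 * x)
  w <- 1 / x
  fit <- fit_calibration(calibration_points(x, y), weighting = "1/x")
  slopes <- seq(fit$slope - 0.01, fit$slope + 0.01, length.out = 401)
  ints <- seq(fit$intercept - 0.5, fit$intercept + 0.5, length.out = 401)
  sse <- outer(slopes, ints, function(a, b) {
    vapply(seq_along(a), function(i) {
      sum(w * (y - a[i] * x - b[i])^2)
    }, numeric(1))
  })
  best <- which(sse == min(sse), arr.ind = TRUE)[1, ]
  expect_equal(slopes[best[1]], fit$slope,
               tolerance = diff(slopes[1:2]) * 1.5)
  expect_equal(ints[best[2]], fit$intercept, tolerance = diff(ints[1:2]) * 1.5)
})

test_that("replicate-curve intercept-SD mode uses per-batch fits", {
  sc <- assay_scenario(n_replicates = 6L, seed = 5L)
  pts <- gen_calibration(sc)
  fit <- fit_calibration(pts, sd_intercept_mode = "replicate_curves")
  ints <- vapply(split(seq_len(nrow(pts)), pts$batch), function(i) {
    wls_oracle(pts$nominal_conc[i], pts$response[i],
               1 / pts$nominal_conc[i])$intercept
  }, numeric(1))
  expect_equal(fit$sd_intercept, stats::sd(ints), tolerance = 1e-10)
  expect_error(
    fit_calibration(calibration_points(c(1, 2, 3), c(1, 2, 3)),
                    sd_intercept_mode = "replicate_curves"),
    class = "hlmstab_invalid_argument")
})

test_that("degenerate designs are rejected", {
  expect_error(
    fit_calibration(calibration_points(c(1, 1, 2), c(1, 1.1, 2))),
    class = "hlmstab_degenerate_design")
  expect_error(calibration_points(c(-1, 2, 3), c(1, 2, 3)),
               class = "hlmstab_invalid_argument")
})

test_that("back-calculation inverts the line and flags rather than clips", {
  fit <- fit_calibration(calibration_points(c(1, 2, 3), c(1, 2, 3)), "none")
  expect_equal(back_calculate(fit, 5), 5)
  # round trip at the printed fit's magnitudes
  f2 <- structure(list(slope = 0.6515, intercept = -0.5459),
                  class = "calibration_fit")
  expect_equal(back_calculate(f2, 0.6515 * 900 - 0.5459), 900,
               tolerance = 1e-12)
  expect_lt(back_calculate(f2, -1), 0)  # sub-blank response, returned as-is
  set.seed(9)
  for (i in 1:100) {
    a <- stats::runif(1, 0.1, 2); b <- stats::runif(1, -1, 1)
    xx <- stats::runif(1, 0.5, 3000)
    f <- structure(list(slope = a, intercept = b), class = "calibration_fit")
    expect_lt(abs(back_calculate(f, a * xx + b) - xx), 1e-9)
  }
  f0 <- structure(list(slope = 0, intercept = 0), class = "calibration_fit")
  expect_error(back_calculate(f0, 1), class = "hlmstab_zero_slope")
})

test_that("LOD/LOQ follow the 3- and 10-sigma intercept rules", {
  expect_equal(lod_loq(0.5, 0), list(lod = 0, loq = 0))
  ll <- lod_loq(0.6515, 0.0625)
  expect_equal(ll$loq, 10 * 0.0625 / 0.6515, tolerance = 1e-12)
  expect_equal(round_half_up(ll$loq), 0.96)
  expect_equal(round_half_up(ll$lod), 0.29)
  set.seed(13)
  for (i in 1:20) {
    s <- stats::runif(1, 0.01, 2); sd <- stats::runif(1, 0, 1)
    ll <- lod_loq(s, sd)
    expect_equal(ll$lod / ll$loq, 0.3, tolerance = 1e-12)
    # monotone: larger intercept SD, larger LOQ; steeper slope, smaller LOQ
    expect_gt(lod_loq(s, sd + 0.1)$loq, ll$loq)
    expect_lt(lod_loq(s * 2, max(sd, 1e-6))$loq,
              lod_loq(s, max(sd, 1e-6))$loq)
  }
  expect_error(lod_loq(-1, 0.1), class = "hlmstab_invalid_fit")
})

test_that("curve recovery is the mean back-calculated level vs nominal", {
  expect_equal(round_half_up(curve_recovery(1.1133, 1)), 111.33)
  expect_equal(curve_recovery(c(5, 5, 5), 5), 100)
  expect_equal(round_half_up(curve_recovery(3086.33, 3000)), 102.88)
  expect_error(curve_recovery(numeric(0), 1), class = "hlmstab_empty_input")
})

test_that("FDA-style curve acceptance applies per-level tolerances", {
  x <- c(1, 15, 50, 150, 300)
  fit <- structure(list(slope = 1, intercept = 0), class = "calibration_fit")
  # lowest level off by 18% (allowed at LLOQ), one level off by 30% (fails)
  pts <- calibration_points(x, c(1.18, 15, 50, 195, 300))
  res <- check_calibration_acceptance(pts, fit)
  expect_true(res$detail$pass[1])          # 18% within the 20% LLOQ rule
  expect_false(res$detail$pass[4])         # 30% out
  expect_equal(res$fraction_pass, 0.8)
  expect_true(res$pass)                    # 80% >= 75%
})
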
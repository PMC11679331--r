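test_that("percent remaining normalizes to baseline and printed values", {
  s <- table7_series()
  pct <- percent_remaining(s)
  expect_equal(pct$pct_remaining[1], 100)
  expect_equal(round_half_up(pct$pct_remaining[pct$time_min == 2.5]), 92.48)
  expect_equal(round_half_up(pct$pct_remaining[pct$time_min == 70]), 21.95)
  # invariant to rescaling all concentrations
  s2 <- depletion_series(s$times, 3.7 * s$conc)
  expect_equal(percent_remaining(s2)$pct_remaining, pct$pct_remaining,
               tolerance = 1e-12)
  expect_error(depletion_series(c(0, 5), c(0, 1)),
               class = "hlmstab_invalid_baseline")
  expect_error(depletion_series(c(5, 10), c(10, 5)),
               class = "hlmstab_invalid_argument")
})

test_that("window selection: fixed default, auto vs prefix enumeration", {
  pct <- percent_remaining(table7_series())
  expect_equal(select_linear_window(pct, "fixed"), c(0, 30))
  expect_equal(sum(pct$time_min >= 0 & pct$time_min <= 30), 7)

  # pure exponential is log-linear over the whole range
  tt <- c(0, 5, 10, 20, 30, 40, 50, 60, 70)
  mono <- data.frame(time_min = tt, pct_remaining = 100 * exp(-0.05 * tt))
  expect_equal(select_linear_window(mono, "auto"), c(0, 70))

  # auto mode agrees with brute-force prefix enumeration on the real curve
  win <- select_linear_window(pct, "auto", r2_threshold = 0.95)
  orc <- prefix_window_oracle(pct$time_min, pct$pct_remaining, 0.95)
  expect_equal(win, orc)

  # and across thresholds
  for (th in c(0.9, 0.97, 0.99)) {
    orc <- prefix_window_oracle(pct$time_min, pct$pct_remaining, th)
    if (is.null(orc)) {
      expect_error(select_linear_window(pct, "auto", r2_threshold = th),
                   class = "hlmstab_no_linear_segment")
    } else {
      expect_equal(select_linear_window(pct, "auto", r2_threshold = th), orc)
    }
  }
})

test_that("depletion fit reproduces printed regression and the OLS oracle", {
  pct <- percent_remaining(table7_series())
  fit <- fit_depletion(pct, c(0, 30))
  expect_equal(fit$slope, -0.04643, tolerance = 1e-4 / 0.04643)
  expect_lt(abs(abs(fit$slope) - 0.04643), 1e-4)
  expect_lt(abs(fit$intercept - 4.657), 0.005)
  expect_lt(abs(fit$r_squared - 0.9889), 5e-4)
  expect_equal(fit$n_points, 7)

  tt <- c(0, 5, 10, 20)
  mono <- data.frame(time_min = tt, pct_remaining = 100 * exp(-0.05 * tt))
  f2 <- fit_depletion(mono, c(0, 20))
  expect_equal(f2$slope, -0.05, tolerance = 1e-12)
  expect_equal(f2$r_squared, 1, tolerance = 1e-12)

  set.seed(17)
  for (i in 1:10) {
    t5 <- sort(c(0, stats::runif(4, 1, 60)))
    p5 <- 100 * exp(-0.06 * t5) * exp(stats::rnorm(5, 0, 0.05))
    p5[1] <- 100
    f <- fit_depletion(data.frame(time_min = t5, pct_remaining = p5),
                       c(0, 60))
    orc <- wls_oracle(t5, log(p5))
    expect_equal(f$slope, orc$slope, tolerance = 1e-10)
    expect_equal(f$intercept, orc$intercept, tolerance = 1e-10)
  }

  bad <- data.frame(time_min = c(0, 5, 10, 20),
                    pct_remaining = c(100, 50, 0, 10))
  expect_error(fit_depletion(bad, c(0, 20)), class = "hlmstab_log_domain")
})

test_that("half-life is ln2 over the rate magnitude", {
  expect_equal(round_half_up(half_life(-0.04643)), 14.93)
  expect_equal(half_life(-log(2)), 1)
  expect_equal(round_half_up(half_life(-0.0693)), 10.00)
  expect_equal(half_life(0.05), half_life(-0.05))  # magnitude accepted
  expect_error(half_life(0), class = "hlmstab_no_depletion")
})

test_that("well-stirred clearance scales the rate by liver physiology", {
  expect_equal(round_half_up(intrinsic_clearance(14.93)), 54.31)
  expect_equal(intrinsic_clearance(0.693 * 45 * 26), 1, tolerance = 1e-12)
  set.seed(19)
  for (i in 1:10) {
    th <- stats::runif(1, 1, 100)
    sc <- physiology_scaling(stats::runif(1, 0.5, 2),
                             stats::runif(1, 30, 60),
                             stats::runif(1, 20, 30))
    expect_equal(intrinsic_clearance(2 * th, sc),
                 intrinsic_clearance(th, sc) / 2, tolerance = 1e-12)
  }
  expect_error(intrinsic_clearance(-1), class = "hlmstab_invalid_argument")
  expect_error(physiology_scaling(ln2_constant = 0),
               class = "hlmstab_invalid_argument")
})

test_that("clearance classification requires explicit cut-offs", {
  expect_error(classify_clearance(50), class = "hlmstab_missing_config")
  cut <- c(low_max = 8.6, high_min = 47)
  expect_equal(classify_clearance(54.31, cut), "high")
  expect_equal(classify_clearance(8.6, cut), "low")      # inclusive low side
  expect_equal(classify_clearance(47, cut), "high")      # inclusive high side
  expect_equal(classify_clearance(20, cut), "intermediate")
  expect_error(classify_clearance(1, c(low_max = 5, high_min = 4)),
               class = "hlmstab_missing_config")
})

test_that("the composed pipeline reproduces the printed stability result", {
  res <- run_stability_pipeline(table7_series(),
                                cutoffs = c(low_max = 8.6, high_min = 47))
  expect_lt(abs(res$slope_k - 0.04643), 1e-4)
  expect_lt(abs(res$r_squared - 0.9889), 5e-4)
  expect_lt(abs(res$t_half - 14.93), 0.02)
  expect_lt(abs(res$clint - 54.31), 0.05)
  expect_equal(res$clearance_class, "high")
  # rate identity holds exactly
  expect_equal(res$t_half * res$slope_k, log(2), tolerance = 1e-9)
})

test_that("pipeline recovers a noiseless monoexponential exactly", {
  tt <- c(0, 2.5, 5, 7.5, 15, 20, 30, 40, 50, 60, 70)
  for (k in c(0.02, 0.1, 0.3)) {
    s <- depletion_series(tt, 500 * exp(-k * tt))
    for (win in list(c(0, 30), c(0, 70), c(0, 15))) {
      res <- run_stability_pipeline(s, window = win)
      expect_equal(res$slope_k, k, tolerance = 1e-9)
      expect_equal(res$t_half, log(2) / k, tolerance = 1e-9 * log(2) / k)
    }
  }
  s <- depletion_series(c(0, 5, 10, 20, 30), 100 * exp(-0.1 * c(0, 5, 10, 20, 30)))
  res <- run_stability_pipeline(s)
  expect_equal(res$t_half, 6.93, tolerance = 0.001)
  expect_equal(res$clint, 0.693 / res$t_half * 1170, tolerance = 1e-12)
})

test_that("Clint times t-half is conserved and monotone in the rate", {
  tt <- c(0, 2.5, 5, 7.5, 15, 20, 30)
  ks <- c(0.01, 0.03, 0.05, 0.1, 0.2)
  res <- lapply(ks, function(k) {
    run_stability_pipeline(depletion_series(tt, 600 * exp(-k * tt)))
  })
  for (r in res) {
    expect_equal(r$clint * r$t_half, 0.693 * 1170, tolerance = 1e-9)
  }
  th <- vapply(res, `[[`, 0, "t_half")
  cl <- vapply(res, `[[`, 0, "clint")
  expect_true(all(diff(th) < 0))  # steeper depletion, shorter half-life
  expect_true(all(diff(cl) > 0))  # and larger clearance
})

test_that("a flat series raises no-depletion instead of a finite half-life", {
  flat <- depletion_series(c(0, 10, 20, 30, 40), rep(250, 5))
  expect_error(run_stability_pipeline(flat), class = "hlmstab_no_depletion")
})

test_that("simulated plateau depletion recovers the target half-life", {
  truth <- log(2) / 0.0464
  est <- vapply(1:200, function(s) {
    ser <- gen_depletion(depletion_scenario(cv_measurement = 0.02, seed = s))
    run_stability_pipeline(ser)$t_half
  }, numeric(1))
  expect_lt(abs(stats::median(est) - truth) / truth, 0.10)
})
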
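#' Define a calibration/QC assay scenario
#'
#' Parameters of the simulated assay: the nine-level calibration design
#' spanning 1-3000 ng/mL, the four QC levels, a true calibration line, and
#' a heteroscedastic noise model (additive + proportional response SD) —
#' the error structure that motivates 1/x weighting.
#'
#' @param cal_levels Calibration levels in ng/mL (default the nine-level
#'   design 1, 15, 50, 150, 300, 400, 500, 1500, 3000).
#' @param qc_levels QC levels in ng/mL (default 1, 3, 900, 2400 — LLOQ,
#'   LQC, MQC, HQC).
#' @param true_slope,true_intercept True calibration line. Defaults (0.6515,
#'   -0.5459) are realistic magnitudes for a peak-area-ratio assay.
#' @param cv_proportional Proportional component of the response SD
#'   (fraction of the true signal a*x; default 0.03).
#' @param sd_additive Additive response-SD floor (ratio units; default
#'   0.002).
#' @param n_replicates Replicates per level (default 6).
#' @param seed RNG seed.
#' @return An object of class `assay_scenario`.
#' @export
assay_scenario <- function(cal_levels = c(1, 15, 50, 150, 300, 400, 500,
                                          1500, 3000),
                           qc_levels = c(1, 3, 900, 2400),
                           true_slope = 0.6515, true_intercept = -0.5459,
                           cv_proportional = 0.03, sd_additive = 0.002,
                           n_replicates = 6L, seed = 1L) {
  if (any(cal_levels <= 0) || is.unsorted(cal_levels, strictly = TRUE)) {
    abort_hlmstab("`cal_levels` must be positive and strictly increasing",
                  "hlmstab_invalid_scenario")
  }
  if (any(qc_levels <= 0)) {
    abort_hlmstab("`qc_levels` must be positive", "hlmstab_invalid_scenario")
  }
  if (cv_proportional < 0 || sd_additive < 0 || n_replicates < 1L) {
    abort_hlmstab("noise parameters must be >= 0 and n_replicates >= 1",
                  "hlmstab_invalid_scenario")
  }
  structure(list(cal_levels = cal_levels, qc_levels = qc_levels,
                 true_slope = true_slope, true_intercept = true_intercept,
                 cv_proportional = cv_proportional,
                 sd_additive = sd_additive,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "assay_scenario")
}

#' Generate calibration points from an assay scenario
#'
#' Responses are y_ij = a x_i + b + e_ij with e_ij ~ Normal(0, sd) and
#' sd = sd_additive + cv_proportional * a * x_i, deterministic under the
#' scenario seed.
#'
#' @param scenario An [assay_scenario()].
#' @return A `calibration_points` data frame (one batch per replicate
#'   index, so replicate-curve intercept-SD estimation works out of the
#'   box).
#' @export
gen_calibration <- function(scenario) {
  if (!inherits(scenario, "assay_scenario")) {
    abort_hlmstab("`scenario` must be an assay_scenario",
                  "hlmstab_invalid_scenario")
  }
  with_seed(scenario$seed, {
    x <- rep(scenario$cal_levels, each = scenario$n_replicates)
    rep_id <- rep(seq_len(scenario$n_replicates),
                  times = length(scenario$cal_levels))
    sd_i <- scenario$sd_additive +
      scenario$cv_proportional * scenario$true_slope * x
    y <- scenario$true_slope * x + scenario$true_intercept +
      stats::rnorm(length(x), 0, sd_i)
    calibration_points(x, y, replicate = rep_id,
                       batch = sprintf("curve%02d", rep_id))
  })
}

#' Define a substrate-depletion scenario
#'
#' The simulated depletion follows C(t) = c0 * (P + (1 - P) * exp(-lambda
#' t)): first-order loss of a metabolizable fraction on top of a residual
#' plateau P (a phenomenological resistant fraction; no mechanism is
#' claimed). `lambda` is calibrated so that the ln-linear slope fitted on
#' the noiseless curve over the early window equals `-k`, i.e. `k` is the
#' observable early-window depletion rate.
#'
#' @param c0 Baseline concentration (ng/mL; default 618.73, about 1 uM of
#'   a 630 g/mol analyte).
#' @param k Target early-window depletion rate (per minute; default 0.0464).
#' @param plateau_fraction Residual plateau as a fraction of c0, in [0, 1)
#'   (default 0.22).
#' @param cv_measurement Replicate measurement CV (default 0.02).
#' @param times Sampling grid in minutes (default 0, 2.5, 5, 7.5, 15, 20,
#'   30, 40, 50, 60, 70).
#' @param n_replicates Replicates per time point (default 3).
#' @param calibration_window Early window used to calibrate lambda
#'   (default 0-30 min, matching the default fit window).
#' @param seed RNG seed.
#' @return An object of class `depletion_scenario`.
#' @export
depletion_scenario <- function(c0 = 618.73, k = 0.0464,
                               plateau_fraction = 0.22,
                               cv_measurement = 0.02,
                               times = c(0, 2.5, 5, 7.5, 15, 20, 30, 40, 50,
                                         60, 70),
                               n_replicates = 3L,
                               calibration_window = c(0, 30), seed = 1L) {
  if (k <= 0 || c0 <= 0) {
    abort_hlmstab("`k` and `c0` must be > 0", "hlmstab_invalid_scenario")
  }
  if (plateau_fraction < 0 || plateau_fraction >= 1) {
    abort_hlmstab("`plateau_fraction` must be in [0, 1)",
                  "hlmstab_invalid_scenario")
  }
  if (cv_measurement < 0 || n_replicates < 1L) {
    abort_hlmstab("`cv_measurement` must be >= 0 and n_replicates >= 1",
                  "hlmstab_invalid_scenario")
  }
  structure(list(c0 = c0, k = k, plateau_fraction = plateau_fraction,
                 cv_measurement = cv_measurement, times = times,
                 n_replicates = as.integer(n_replicates),
                 calibration_window = calibration_window,
                 seed = as.integer(seed)),
            class = "depletion_scenario")
}

# Solve for lambda such that the OLS ln-slope of the noiseless plateau curve
# over the calibration window equals -k. With P = 0, lambda = k exactly.
# The fitted slope magnitude is non-monotone in lambda (it falls again once
# the curve collapses onto the plateau within the window), so the root is
# taken on the rising branch, below the maximizing lambda.
calibrate_lambda <- function(k, plateau, times, window) {
  if (plateau == 0) return(k)
  tt <- times[times >= window[1] & times <= window[2]]
  slope_mag <- function(lambda) {
    p <- 100 * (plateau + (1 - plateau) * exp(-lambda * tt))
    -ln_linear_fit(tt, p)$slope
  }
  peak <- stats::optimize(slope_mag, c(k, 200 * k), maximum = TRUE,
                          tol = 1e-12)
  if (peak$objective < k) {
    abort_hlmstab(sprintf(
      "target rate k = %g is unreachable with plateau %g on this grid (max %g)",
      k, plateau, peak$objective), "hlmstab_invalid_scenario")
  }
  stats::uniroot(function(l) slope_mag(l) - k, lower = k,
                 upper = peak$maximum, tol = 1e-13)$root
}

#' Generate a replicated depletion series
#'
#' Draws `n_replicates` measurements per time point with multiplicative
#' lognormal noise (unit mean, CV = `cv_measurement`) around the plateau
#' model, then returns the per-time means as a [depletion_series()] with
#' replicates retained.
#'
#' @param scenario A [depletion_scenario()].
#' @param analyte Analyte label.
#' @return A `depletion_series`.
#' @export
gen_depletion <- function(scenario, analyte = "analyte") {
  if (!inherits(scenario, "depletion_scenario")) {
    abort_hlmstab("`scenario` must be a depletion_scenario",
                  "hlmstab_invalid_scenario")
  }
  lambda <- calibrate_lambda(scenario$k, scenario$plateau_fraction,
                             scenario$times, scenario$calibration_window)
  mu <- scenario$c0 * (scenario$plateau_fraction +
                       (1 - scenario$plateau_fraction) *
                         exp(-lambda * scenario$times))
  with_seed(scenario$seed, {
    n <- scenario$n_replicates
    cv <- scenario$cv_measurement
    if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      noise <- stats::rlnorm(length(mu) * n, meanlog = -sdlog^2 / 2,
                             sdlog = sdlog)
    } else {
      noise <- rep(1, length(mu) * n)
    }
    reps <- data.frame(
      time_min = rep(scenario$times, each = n),
      replicate = rep(seq_len(n), times = length(mu)),
      conc_ng_ml = rep(mu, each = n) * noise
    )
    means <- vapply(split(reps$conc_ng_ml, reps$time_min), mean, numeric(1))
    means <- means[order(as.numeric(names(means)))]
    depletion_series(scenario$times, unname(means), analyte = analyte,
                     replicates = reps)
  })
}

#' Generate matched matrix/neat response sets for matrix-effect studies
#'
#' Produces analyte and internal-standard response sets such that
#' [matrix_effect()] estimates `me_true` for the analyte and
#' [normalized_matrix_effect()] estimates `nme_true`. Noise is
#' multiplicative with CV `cv` and unit mean.
#'
#' @param me_true True analyte matrix effect (percent).
#' @param nme_true True IS-normalized matrix effect (ratio); the IS matrix
#'   effect is `me_true / nme_true`.
#' @param n Replicates per set (>= 3).
#' @param cv Measurement CV (fraction).
#' @param seed RNG seed.
#' @return A list with elements `analyte` and `is`, each holding `matrix`
#'   and `neat` response vectors.
#' @export
gen_matrix_sets <- function(me_true = 105.05, nme_true = 1.03, n = 6L,
                            cv = 0.05, seed = 1L) {
  if (n < 3L) {
    abort_hlmstab("`n` must be >= 3", "hlmstab_invalid_scenario")
  }
  if (me_true <= 0 || nme_true <= 0 || cv < 0) {
    abort_hlmstab("`me_true`, `nme_true` must be > 0 and `cv` >= 0",
                  "hlmstab_invalid_scenario")
  }
  me_is <- me_true / nme_true
  with_seed(seed, {
    draw <- function(mu) {
      if (cv == 0) return(rep(mu, n))
      sdlog <- sqrt(log(1 + cv^2))
      mu * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    list(
      analyte = list(matrix = draw(me_true / 100), neat = draw(1)),
      is = list(matrix = draw(me_is / 100), neat = draw(1))
    )
  })
}
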
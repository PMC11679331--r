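#' Construct calibration points
#'
#' A calibration point pairs a nominal analyte concentration (the spiked
#' level of a calibration standard) with the measured instrument response,
#' expressed as the analyte/internal-standard peak-area ratio.
#'
#' @param nominal_conc Nominal concentrations in ng/mL; all > 0.
#' @param response Peak-area ratios (analyte / internal standard); finite.
#' @param replicate Integer replicate index (recycled).
#' @param batch Batch/curve label (recycled). Used by the replicate-curve
#'   mode of [fit_calibration()]'s intercept-SD estimate.
#' @return A data frame of class `calibration_points`.
#' @examples
#' calibration_points(c(1, 15, 50), c(0.2, 9.5, 32.1))
#' @export
calibration_points <- function(nominal_conc, response, replicate = 1L,
                               batch = "b1") {
  if (length(nominal_conc) != length(response)) {
    abort_hlmstab("`nominal_conc` and `response` must have equal length",
                  "hlmstab_invalid_argument")
  }
  if (any(!is.finite(nominal_conc)) || any(nominal_conc <= 0)) {
    abort_hlmstab("all nominal concentrations must be finite and > 0",
                  "hlmstab_invalid_argument")
  }
  if (any(!is.finite(response))) {
    abort_hlmstab("all responses must be finite", "hlmstab_invalid_argument")
  }
  out <- data.frame(
    nominal_conc = as.numeric(nominal_conc),
    response = as.numeric(response),
    replicate = rep_len(as.integer(replicate), length(response)),
    batch = rep_len(as.character(batch), length(response)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("calibration_points", "data.frame")
  out
}

calibration_weights <- function(x, weighting) {
  switch(weighting,
    "none" = rep(1, length(x)),
    "1/x" = 1 / x,
    "1/x^2" = 1 / x^2,
    abort_hlmstab(sprintf("unknown weighting scheme '%s'", weighting),
                  "hlmstab_invalid_argument")
  )
}

#' Fit a weighted linear calibration curve
#'
#' Fits response = slope * concentration + intercept by weighted least
#' squares. Heteroscedastic LC-MS/MS response noise (error roughly
#' proportional to concentration) is the usual reason to weight by `1/x`,
#' which keeps the low end of a wide calibration range from being swamped
#' by the high standards.
#'
#' The weighted coefficient of determination is 1 - SSE_w/SST_w with SST_w
#' taken about the weighted mean response, which reduces to the ordinary
#' R-squared under equal weights.
#'
#' @param points A `calibration_points` object (or data frame with columns
#'   `nominal_conc`, `response`, optionally `batch`).
#' @param weighting One of `"1/x"` (default), `"none"`, `"1/x^2"`.
#' @param sd_intercept_mode How the intercept standard deviation (used for
#'   LOD/LOQ) is obtained: `"covariance"` (default) takes the standard error
#'   of the intercept from the weighted-regression covariance matrix of one
#'   pooled fit; `"replicate_curves"` fits each `batch` separately and takes
#'   the sample SD of the per-curve intercepts.
#' @return An object of class `calibration_fit` with elements `slope`,
#'   `intercept`, `r_squared`, `weighting`, `sd_intercept`, `n_points`,
#'   `residuals`.
#' @seealso [back_calculate()], [lod_loq()], [check_calibration_acceptance()]
#' @examples
#' pts <- calibration_points(c(1, 2, 3), c(1, 2, 3))
#' fit_calibration(pts, weighting = "none")
#' @export
fit_calibration <- function(points, weighting = c("1/x", "none", "1/x^2"),
                            sd_intercept_mode = c("covariance",
                                                  "replicate_curves")) {
  weighting <- match.arg(weighting)
  sd_intercept_mode <- match.arg(sd_intercept_mode)
  x <- points$nominal_conc
  y <- points$response
  if (length(unique(x)) < 3L) {
    abort_hlmstab("calibration requires at least 3 distinct nominal levels",
                  "hlmstab_degenerate_design")
  }
  if (isTRUE(all.equal(stats::var(x), 0))) {
    abort_hlmstab("zero variance in nominal concentrations",
                  "hlmstab_singular_design")
  }
  if (weighting != "none" && any(x <= 0)) {
    abort_hlmstab("1/x-type weighting requires all nominal levels > 0",
                  "hlmstab_invalid_argument")
  }
  w <- calibration_weights(x, weighting)
  fit <- stats::lm(y ~ x, weights = w)
  # exact-fit inputs are legitimate here; summary.lm warns on them
  sm <- suppressWarnings(summary(fit))
  sd_int <- sm$coefficients["(Intercept)", "Std. Error"]
  if (sd_intercept_mode == "replicate_curves") {
    batch <- if (!is.null(points$batch)) points$batch else rep("b1", length(x))
    if (length(unique(batch)) < 2L) {
      abort_hlmstab(
        "replicate-curve intercept SD needs at least 2 distinct batches",
        "hlmstab_invalid_argument")
    }
    intercepts <- vapply(split(seq_along(x), batch), function(i) {
      stats::coef(stats::lm(y[i] ~ x[i],
                            weights = calibration_weights(x[i], weighting)))[1]
    }, numeric(1))
    sd_int <- stats::sd(intercepts)
  }
  structure(list(
    slope = unname(stats::coef(fit)["x"]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    r_squared = sm$r.squared,
    weighting = weighting,
    sd_intercept = unname(sd_int),
    sd_intercept_mode = sd_intercept_mode,
    n_points = length(x),
    residuals = unname(stats::residuals(fit))
  ), class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("Weighted linear calibration fit\n")
  cat(sprintf("  y = %.6g x %+.6g   (weighting: %s, n = %d)\n",
              x$slope, x$intercept, x$weighting, x$n_points))
  cat(sprintf("  R-squared: %.4f   SD(intercept): %.4g [%s]\n",
              x$r_squared, x$sd_intercept, x$sd_intercept_mode))
  ll <- lod_loq(x$slope, x$sd_intercept)
  cat(sprintf("  LOD: %.3g ng/mL   LOQ: %.3g ng/mL\n", ll$lod, ll$loq))
  invisible(x)
}

#' Back-calculate concentration from a response
#'
#' Inverts the calibration line: (response - intercept) / slope. Negative
#' results (sub-blank responses) are returned as-is — truncation is the
#' caller's decision, because clipping biases low-end validation statistics.
#'
#' @param fit A `calibration_fit`.
#' @param response Peak-area ratio(s).
#' @return Concentration(s) in ng/mL.
#' @examples
#' fit <- fit_calibration(calibration_points(c(1, 2, 3), c(1, 2, 3)), "none")
#' back_calculate(fit, 2.5)
#' @export
back_calculate <- function(fit, response) {
  if (!inherits(fit, "calibration_fit")) {
    abort_hlmstab("`fit` must be a calibration_fit", "hlmstab_invalid_argument")
  }
  if (fit$slope == 0) {
    abort_hlmstab("calibration slope is zero; cannot invert",
                  "hlmstab_zero_slope")
  }
  (response - fit$intercept) / fit$slope
}

#' Limits of detection and quantification from the calibration fit
#'
#' Pharmacopoeial estimates based on the calibration slope and the standard
#' deviation of the intercept: LOD = 3 * SD(intercept) / slope and
#' LOQ = 10 * SD(intercept) / slope, so LOD/LOQ = 3/10 exactly.
#'
#' @param slope Calibration slope (response ratio per ng/mL); must be > 0.
#' @param sd_intercept Standard deviation of the intercept (response ratio);
#'   must be >= 0.
#' @return A list with elements `lod` and `loq`, both in ng/mL.
#' @examples
#' lod_loq(slope = 0.6515, sd_intercept = 0.0625)
#' @export
lod_loq <- function(slope, sd_intercept) {
  stopifnot_scalar_number(slope, "slope")
  stopifnot_scalar_number(sd_intercept, "sd_intercept")
  if (slope <= 0) {
    abort_hlmstab("LOD/LOQ need a positive calibration slope",
                  "hlmstab_invalid_fit")
  }
  if (sd_intercept < 0) {
    abort_hlmstab("`sd_intercept` must be >= 0", "hlmstab_invalid_argument")
  }
  list(lod = 3 * sd_intercept / slope, loq = 10 * sd_intercept / slope)
}

#' Mean back-calculated recovery against the nominal level
#'
#' 100 * mean(back-calculated) / nominal — the "% recovery" column of a
#' back-calculation table.
#'
#' @param back_calculated Back-calculated concentrations (ng/mL).
#' @param nominal Nominal concentration (ng/mL), > 0.
#' @return Percent recovery.
#' @examples
#' curve_recovery(c(1.10, 1.12, 1.12), nominal = 1)
#' @export
curve_recovery <- function(back_calculated, nominal) {
  if (length(back_calculated) == 0L) {
    abort_hlmstab("no back-calculated values supplied", "hlmstab_empty_input")
  }
  stopifnot_scalar_number(nominal, "nominal")
  if (nominal <= 0) {
    abort_hlmstab("`nominal` must be > 0", "hlmstab_invalid_argument")
  }
  100 * mean(back_calculated) / nominal
}

#' FDA-style calibration-curve acceptance check
#'
#' Back-calculates every calibration standard through the fitted curve and
#' applies the usual rule: each standard must fall within `tol_pct` of
#' nominal (`tol_lloq_pct` at the lowest level), and at least
#' `min_fraction` of standards must pass overall.
#'
#' @param points The `calibration_points` that were fitted.
#' @param fit The `calibration_fit`.
#' @param tol_pct Percent tolerance for standards above the LLOQ (default 15).
#' @param tol_lloq_pct Percent tolerance at the lowest level (default 20).
#' @param min_fraction Minimum passing fraction of standards (default 0.75).
#' @return A list: `pass` (logical), `fraction_pass`, and a per-point data
#'   frame `detail` with back-calculated values, signed percent error and
#'   pass flags (negative back-calculated values are flagged, not clipped).
#' @export
check_calibration_acceptance <- function(points, fit, tol_pct = 15,
                                         tol_lloq_pct = 20,
                                         min_fraction = 0.75) {
  bc <- back_calculate(fit, points$response)
  e <- 100 * (bc - points$nominal_conc) / points$nominal_conc
  lloq <- min(points$nominal_conc)
  tol <- ifelse(points$nominal_conc == lloq, tol_lloq_pct, tol_pct)
  ok <- abs(e) <= tol
  detail <- data.frame(
    nominal_conc = points$nominal_conc,
    back_calculated = bc,
    e_pct = e,
    negative_flag = bc < 0,
    tol_pct = tol,
    pass = ok
  )
  list(pass = mean(ok) >= min_fraction, fraction_pass = mean(ok),
       detail = detail)
}
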
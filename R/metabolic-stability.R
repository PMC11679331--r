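#' Construct a substrate-depletion time course
#'
#' Holds the concentration-time data from a microsomal incubation: analyte
#' remaining (ng/mL) at each sampling time (min), as the per-time mean of
#' replicates. Replicate-level data, when available, are retained in the
#' `replicates` attribute.
#'
#' @param times Sampling times in minutes; strictly increasing, first = 0.
#' @param conc Mean concentrations (ng/mL), one per time; `conc[1] > 0`,
#'   all >= 0.
#' @param analyte Analyte label.
#' @param replicates Optional data frame (`time_min`, `replicate`,
#'   `conc_ng_ml`) with the underlying replicate measurements.
#' @return An object of class `depletion_series`.
#' @examples
#' depletion_series(c(0, 10, 20), c(100, 60, 36))
#' @export
depletion_series <- function(times, conc, analyte = "analyte",
                             replicates = NULL) {
  if (length(times) != length(conc)) {
    abort_hlmstab("`times` and `conc` must have equal length",
                  "hlmstab_invalid_argument")
  }
  if (times[1] != 0) {
    abort_hlmstab("the first sampling time must be 0 min",
                  "hlmstab_invalid_argument")
  }
  if (any(diff(times) <= 0)) {
    abort_hlmstab("`times` must be strictly increasing",
                  "hlmstab_invalid_argument")
  }
  if (conc[1] <= 0) {
    abort_hlmstab("baseline concentration (t = 0) must be > 0",
                  "hlmstab_invalid_baseline")
  }
  if (any(conc < 0) || any(!is.finite(conc))) {
    abort_hlmstab("all concentrations must be finite and >= 0",
                  "hlmstab_invalid_argument")
  }
  structure(list(times = as.numeric(times), conc = as.numeric(conc),
                 analyte = analyte, replicates = replicates),
            class = "depletion_series")
}

#' @export
print.depletion_series <- function(x, ...) {
  cat(sprintf("Depletion series for %s: %d time points over %g-%g min\n",
              x$analyte, length(x$times), min(x$times), max(x$times)))
  print(data.frame(time_min = x$times, conc_ng_ml = x$conc,
                   pct_remaining = round_half_up(100 * x$conc / x$conc[1])),
        row.names = FALSE)
  invisible(x)
}

#' Percent of analyte remaining relative to baseline
#'
#' X_i = 100 * C_i / C_0, so the t = 0 point is 100 exactly. Invariant to
#' rescaling all concentrations by a common positive factor.
#'
#' @param series A `depletion_series`.
#' @return A data frame with columns `time_min` and `pct_remaining`.
#' @export
percent_remaining <- function(series) {
  if (!inherits(series, "depletion_series")) {
    abort_hlmstab("`series` must be a depletion_series",
                  "hlmstab_invalid_argument")
  }
  data.frame(time_min = series$times,
             pct_remaining = 100 * series$conc / series$conc[1])
}

ln_linear_fit <- function(time, pct) {
  fit <- stats::lm(log(pct) ~ time)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       # noiseless (exact-fit) series are legitimate inputs; summary.lm warns
       r_squared = suppressWarnings(summary(fit)$r.squared))
}

#' Select the log-linear regression window of a depletion curve
#'
#' Microsomal depletion curves are only log-linear early on; many substrates
#' flatten to a residual plateau once the fast-metabolized fraction is gone.
#' `"fixed"` mode returns the configured window (default 0-30 min).
#' `"auto"` mode returns the longest prefix window (starting at t = 0) with
#' at least `min_points` points whose ln-linear fit reaches `r2_threshold`.
#'
#' @param pct A data frame from [percent_remaining()].
#' @param mode `"fixed"` or `"auto"`.
#' @param window Numeric `c(t_start, t_end)` for fixed mode (default 0-30).
#' @param r2_threshold Minimum R-squared for auto mode (default 0.95).
#' @param min_points Minimum points in an auto window (default 4).
#' @return Numeric `c(t_start, t_end)`.
#' @export
select_linear_window <- function(pct, mode = c("fixed", "auto"),
                                 window = c(0, 30), r2_threshold = 0.95,
                                 min_points = 4L) {
  mode <- match.arg(mode)
  if (nrow(pct) < 4L) {
    abort_hlmstab("window selection needs at least 4 time points",
                  "hlmstab_invalid_argument")
  }
  if (mode == "fixed") {
    return(c(window[1], window[2]))
  }
  t <- pct$time_min
  p <- pct$pct_remaining
  best <- NULL
  for (k in seq(min_points, length(t))) {
    if (any(p[seq_len(k)] <= 0)) break
    f <- ln_linear_fit(t[seq_len(k)], p[seq_len(k)])
    if (f$r_squared >= r2_threshold) best <- k
  }
  if (is.null(best)) {
    abort_hlmstab(sprintf(
      "no prefix window of >= %d points reaches R^2 >= %g", min_points,
      r2_threshold), "hlmstab_no_linear_segment")
  }
  c(t[1], t[best])
}

#' Fit the first-order depletion rate over a window
#'
#' Ordinary least squares of ln(percent remaining) on time, restricted to
#' the window (inclusive). The slope is the signed first-order depletion
#' rate constant; on percent scale the intercept is near ln(100) = 4.605.
#'
#' @param pct A data frame from [percent_remaining()].
#' @param window Numeric `c(t_start, t_end)`.
#' @return A list with `slope` (per minute, signed), `intercept`
#'   (ln-percent), `r_squared`, `n_points`, `window`.
#' @export
fit_depletion <- function(pct, window) {
  keep <- pct$time_min >= window[1] & pct$time_min <= window[2]
  if (sum(keep) < 3L) {
    abort_hlmstab("depletion window must contain at least 3 points",
                  "hlmstab_invalid_argument")
  }
  p <- pct$pct_remaining[keep]
  if (any(p <= 0)) {
    abort_hlmstab("percent remaining must be > 0 inside the fit window",
                  "hlmstab_log_domain")
  }
  f <- ln_linear_fit(pct$time_min[keep], p)
  c(f, list(n_points = sum(keep), window = c(window[1], window[2])))
}

#' In vitro half-life from the depletion rate
#'
#' t1/2 = ln(2) / |slope|. Accepts the signed regression slope or its
#' magnitude. Rate magnitudes below 1e-12 per minute are indistinguishable
#' from no depletion at double precision and are treated as such.
#'
#' @param slope First-order depletion rate (per minute); non-zero.
#' @return Half-life in minutes.
#' @examples
#' half_life(-0.04643)  # 14.93 min
#' @export
half_life <- function(slope) {
  stopifnot_scalar_number(slope, "slope")
  if (abs(slope) < 1e-12) {
    abort_hlmstab("slope is zero: no measurable depletion, half-life undefined",
                  "hlmstab_no_depletion")
  }
  log(2) / abs(slope)
}

#' Physiological scaling factors for the well-stirred model
#'
#' The constants that scale an incubation depletion rate to whole-body
#' intrinsic clearance: incubation volume per mg microsomal protein,
#' microsomal protein content per gram of liver, and liver mass per kg body
#' weight. Defaults are the standard human values (1 mL/mg, 45 mg/g,
#' 26 g/kg); `ln2_constant` is the first-order rate constant ln 2, kept
#' configurable at its conventional 3-decimal value 0.693.
#'
#' @param ml_incubation_per_mg_protein mL incubation per mg protein.
#' @param mg_protein_per_g_liver mg microsomal protein per g liver.
#' @param g_liver_per_kg_bw g liver per kg body weight.
#' @param ln2_constant Rate-identity constant (default 0.693).
#' @return An object of class `physiology_scaling`.
#' @export
physiology_scaling <- function(ml_incubation_per_mg_protein = 1,
                               mg_protein_per_g_liver = 45,
                               g_liver_per_kg_bw = 26,
                               ln2_constant = 0.693) {
  vals <- c(ml_incubation_per_mg_protein, mg_protein_per_g_liver,
            g_liver_per_kg_bw, ln2_constant)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort_hlmstab("all scaling factors must be finite and > 0",
                  "hlmstab_invalid_argument")
  }
  structure(list(
    ml_incubation_per_mg_protein = ml_incubation_per_mg_protein,
    mg_protein_per_g_liver = mg_protein_per_g_liver,
    g_liver_per_kg_bw = g_liver_per_kg_bw,
    ln2_constant = ln2_constant
  ), class = "physiology_scaling")
}

#' Well-stirred-model intrinsic clearance
#'
#' Clint = ln2_constant * (1 / t1/2) * (mL incubation / mg protein) *
#' (mg protein / g liver) * (g liver / kg body weight), in mL/min/kg.
#' With default scaling, Clint * t1/2 = 0.693 * 1170 for every result.
#'
#' @param t_half In vitro half-life in minutes, > 0.
#' @param scaling A [physiology_scaling()] object.
#' @return Intrinsic clearance in mL/min/kg.
#' @examples
#' intrinsic_clearance(14.93)  # 54.31 mL/min/kg
#' @export
intrinsic_clearance <- function(t_half, scaling = physiology_scaling()) {
  stopifnot_scalar_number(t_half, "t_half")
  if (t_half <= 0) {
    abort_hlmstab("`t_half` must be > 0", "hlmstab_invalid_argument")
  }
  scaling$ln2_constant * (1 / t_half) *
    scaling$ml_incubation_per_mg_protein *
    scaling$mg_protein_per_g_liver *
    scaling$g_liver_per_kg_bw
}

#' Classify intrinsic clearance as low / intermediate / high
#'
#' Cut-offs differ between published classification schemes, so they are
#' mandatory configuration rather than defaults. Boundaries are inclusive:
#' `clint <= low_max` is low, `clint >= high_min` is high.
#'
#' @param clint Intrinsic clearance (mL/min/kg).
#' @param cutoffs Named numeric `c(low_max = ..., high_min = ...)` with
#'   `low_max < high_min`.
#' @return `"low"`, `"intermediate"` or `"high"`.
#' @export
classify_clearance <- function(clint, cutoffs) {
  if (missing(cutoffs) || is.null(cutoffs)) {
    abort_hlmstab("clearance cut-offs must be supplied via configuration",
                  "hlmstab_missing_config")
  }
  if (!all(c("low_max", "high_min") %in% names(cutoffs)) ||
      cutoffs[["low_max"]] >= cutoffs[["high_min"]]) {
    abort_hlmstab("`cutoffs` needs low_max < high_min",
                  "hlmstab_missing_config")
  }
  if (clint <= cutoffs[["low_max"]]) "low"
  else if (clint >= cutoffs[["high_min"]]) "high"
  else "intermediate"
}

#' Run the metabolic-stability pipeline
#'
#' Composes the stages: percent remaining, log-linear window selection,
#' OLS depletion fit, half-life, and well-stirred-model intrinsic
#' clearance. The result always satisfies t1/2 * |slope| = ln 2.
#'
#' @param series A `depletion_series`.
#' @param scaling A [physiology_scaling()] object.
#' @param window_mode `"fixed"` (default) or `"auto"`.
#' @param window Fixed window `c(t_start, t_end)` in minutes (default 0-30).
#' @param r2_threshold Auto-mode R-squared threshold (default 0.95).
#' @param cutoffs Optional clearance cut-offs for [classify_clearance()];
#'   when `NULL` the clearance class is left unset.
#' @return An object of class `stability_result` with the window, signed
#'   slope and its magnitude `slope_k`, intercept, R-squared, `t_half`
#'   (min), `clint` (mL/min/kg) and `clearance_class`.
#' @examples
#' s <- depletion_series(c(0, 5, 10, 20, 30), 100 * exp(-0.05 * c(0, 5, 10, 20, 30)))
#' run_stability_pipeline(s)
#' @export
run_stability_pipeline <- function(series, scaling = physiology_scaling(),
                                   window_mode = c("fixed", "auto"),
                                   window = c(0, 30), r2_threshold = 0.95,
                                   cutoffs = NULL) {
  window_mode <- match.arg(window_mode)
  pct <- percent_remaining(series)
  win <- select_linear_window(pct, mode = window_mode, window = window,
                              r2_threshold = r2_threshold)
  fit <- fit_depletion(pct, win)
  th <- half_life(fit$slope)
  cl <- intrinsic_clearance(th, scaling)
  structure(list(
    analyte = series$analyte,
    window = win,
    slope = fit$slope,
    slope_k = abs(fit$slope),
    intercept = fit$intercept,
    r_squared = fit$r_squared,
    n_points = fit$n_points,
    t_half = th,
    clint = cl,
    clearance_class = if (is.null(cutoffs)) NA_character_
                      else classify_clearance(cl, cutoffs),
    scaling = scaling
  ), class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("Metabolic stability of %s (window %g-%g min, %d points)\n",
              x$analyte, x$window[1], x$window[2], x$n_points))
  cat(sprintf("  ln(%% remaining) = %.5f t %+.4f   R^2 = %.4f\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  t1/2 = %.2f min   Clint = %.2f mL/min/kg%s\n",
              round_half_up(x$t_half), round_half_up(x$clint),
              if (is.na(x$clearance_class)) ""
              else sprintf("   [%s clearance]", x$clearance_class)))
  invisible(x)
}

#' Two-panel depletion plot
#'
#' Left: percent remaining against time. Right: the log-linear segment with
#' its regression line and annotation.
#'
#' @param x A `depletion_series`.
#' @param result Optional `stability_result`; computed with defaults when
#'   missing.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the `stability_result` used.
#' @export
plot.depletion_series <- function(x, result = NULL, ...) {
  if (is.null(result)) result <- run_stability_pipeline(x)
  pct <- percent_remaining(x)
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old), add = TRUE)
  graphics::plot(pct$time_min, pct$pct_remaining, type = "b", pch = 19,
                 xlab = "Time (min)", ylab = "% remaining",
                 main = x$analyte, ...)
  keep <- pct$time_min >= result$window[1] & pct$time_min <= result$window[2]
  graphics::plot(pct$time_min[keep], log(pct$pct_remaining[keep]), pch = 19,
                 xlab = "Time (min)", ylab = "ln(% remaining)",
                 main = sprintf("y = %.5fx %+.3f, R2 = %.4f",
                                result$slope, result$intercept,
                                result$r_squared))
  graphics::abline(result$intercept, result$slope, lty = 2)
  invisible(result)
}
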
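#' Signed percent error (accuracy)
#'
#' 100 * (calculated - nominal) / nominal. The accuracy statistic of QC
#' tables: negative means under-recovery.
#'
#' @param mean_calc Mean calculated concentration (ng/mL).
#' @param nominal Nominal concentration (ng/mL), > 0.
#' @return Signed percent error.
#' @examples
#' percent_error(2394.47, 2400)  # -0.2304
#' @export
percent_error <- function(mean_calc, nominal) {
  stopifnot_scalar_number(mean_calc, "mean_calc")
  stopifnot_scalar_number(nominal, "nominal")
  if (nominal <= 0) {
    abort_hlmstab("`nominal` must be > 0", "hlmstab_invalid_nominal")
  }
  100 * (mean_calc - nominal) / nominal
}

#' Percent relative standard deviation (precision)
#'
#' 100 * sd / mean, the coefficient of variation expressed as percent —
#' the precision statistic of QC tables.
#'
#' @param sd Sample standard deviation.
#' @param mean Sample mean; must be > 0.
#' @return Percent RSD (>= 0).
#' @examples
#' percent_rsd(8.65, 2394.47)  # 0.3612
#' @export
percent_rsd <- function(sd, mean) {
  stopifnot_scalar_number(sd, "sd")
  stopifnot_scalar_number(mean, "mean")
  if (mean <= 0) {
    abort_hlmstab("`mean` must be > 0", "hlmstab_invalid_mean")
  }
  if (sd < 0) {
    abort_hlmstab("`sd` must be >= 0", "hlmstab_invalid_argument")
  }
  100 * sd / mean
}

#' Summarize replicate QC determinations at one level
#'
#' Computes the replicate statistics reported for a quality-control level:
#' mean, sample SD (n - 1 denominator), percent RSD (precision), signed
#' percent error (accuracy) and percent recovery (100 * mean / nominal, so
#' recovery - 100 = error).
#'
#' @param concentrations Back-calculated concentrations (ng/mL), length >= 2.
#' @param nominal Nominal concentration (ng/mL), > 0.
#' @param level_label One of `"LLOQ"`, `"LQC"`, `"MQC"`, `"HQC"`.
#' @param timeframe Label such as `"intra_day"`, `"inter_day"` or
#'   `"stability:short_term"`.
#' @return An object of class `qc_summary`.
#' @examples
#' summarize_qc(c(2390, 2398, 2395), 2400, "HQC", "intra_day")
#' @export
summarize_qc <- function(concentrations, nominal,
                         level_label = c("LLOQ", "LQC", "MQC", "HQC"),
                         timeframe = "intra_day") {
  level_label <- match.arg(level_label)
  if (length(concentrations) < 2L) {
    abort_hlmstab("QC summary needs at least 2 replicate values",
                  "hlmstab_insufficient_replicates")
  }
  m <- mean(concentrations)
  s <- stats::sd(concentrations)
  structure(list(
    level_label = level_label,
    nominal = nominal,
    n = length(concentrations),
    mean = m,
    sd = s,
    rsd_pct = percent_rsd(s, m),
    e_pct = percent_error(m, nominal),
    recovery_pct = 100 * m / nominal,
    timeframe = timeframe
  ), class = "qc_summary")
}

#' @export
print.qc_summary <- function(x, ...) {
  cat(sprintf(
    "QC %s (%g ng/mL, %s): n=%d mean=%.4g SD=%.3g RSD=%.2f%% E=%+.2f%%\n",
    x$level_label, x$nominal, x$timeframe, x$n, x$mean, x$sd,
    round_half_up(x$rsd_pct), round_half_up(x$e_pct)))
  invisible(x)
}

#' Matrix effect from matrix-based vs neat responses
#'
#' 100 * mean(matrix responses) / mean(neat responses). Values above 100
#' indicate ionization enhancement by matrix co-eluents, below 100 ion
#' suppression.
#'
#' @param matrix_responses Peak-area ratios measured in biological matrix.
#' @param neat_responses Peak-area ratios measured in neat solvent.
#' @return Percent matrix effect.
#' @examples
#' matrix_effect(c(1.05, 1.06), c(1.00, 1.01))
#' @export
matrix_effect <- function(matrix_responses, neat_responses) {
  if (length(matrix_responses) == 0L || length(neat_responses) == 0L) {
    abort_hlmstab("both response sets must be non-empty", "hlmstab_empty_input")
  }
  if (mean(neat_responses) <= 0) {
    abort_hlmstab("mean neat response must be > 0", "hlmstab_division_error")
  }
  100 * mean(matrix_responses) / mean(neat_responses)
}

#' Internal-standard-normalized matrix effect
#'
#' Ratio of the analyte's matrix effect to the internal standard's. Values
#' near 1 mean the IS compensates for matrix-induced ionization changes.
#'
#' @param me_analyte Analyte matrix effect (percent), from [matrix_effect()].
#' @param me_is Internal-standard matrix effect (percent), > 0.
#' @return Dimensionless ratio.
#' @examples
#' normalized_matrix_effect(105.05, 101.68)  # 1.033
#' @export
normalized_matrix_effect <- function(me_analyte, me_is) {
  stopifnot_scalar_number(me_analyte, "me_analyte")
  stopifnot_scalar_number(me_is, "me_is")
  if (me_is <= 0) {
    abort_hlmstab("`me_is` must be > 0", "hlmstab_invalid_argument")
  }
  me_analyte / me_is
}

#' Extraction recovery
#'
#' 100 * mean(extracted) / mean(reference): the yield of the sample-
#' preparation step, comparing analyte extracted from matrix against the
#' same level prepared in neat solvent.
#'
#' @param extracted Measurements from extracted matrix samples.
#' @param reference Measurements from neat reference samples.
#' @return Percent recovery.
#' @export
extraction_recovery <- function(extracted, reference) {
  matrix_effect(extracted, reference)
}

stability_conditions <- c("long_term", "short_term", "autosampler",
                          "freeze_thaw")

#' Assess storage stability of a QC level
#'
#' Pass if the absolute accuracy error of the stored QC is within
#' `threshold_pct` (boundary inclusive).
#'
#' @param condition One of `"long_term"`, `"short_term"`, `"autosampler"`,
#'   `"freeze_thaw"`.
#' @param qc A `qc_summary` for the stored samples.
#' @param threshold_pct Acceptance threshold on |%E| (default 15).
#' @return A list: `condition`, `level_label`, `e_pct`, `rsd_pct`,
#'   `threshold_pct`, `pass`.
#' @export
stability_assessment <- function(condition, qc, threshold_pct = 15) {
  if (!condition %in% stability_conditions) {
    abort_hlmstab(sprintf("unknown stability condition '%s'", condition),
                  "hlmstab_invalid_condition")
  }
  if (!inherits(qc, "qc_summary")) {
    abort_hlmstab("`qc` must be a qc_summary", "hlmstab_invalid_argument")
  }
  list(condition = condition, level_label = qc$level_label,
       nominal = qc$nominal, e_pct = qc$e_pct, rsd_pct = qc$rsd_pct,
       threshold_pct = threshold_pct,
       pass = leq_tol(abs(qc$e_pct), threshold_pct))
}

#' FDA-style acceptance evaluation of QC summaries
#'
#' Applies the usual bioanalytical acceptance rule per level: |%E| and %RSD
#' within `tol_pct` (within `tol_lloq_pct` at the LLOQ). Thresholds are
#' configuration, not constants.
#'
#' @param summaries A list of `qc_summary` objects.
#' @param tol_pct Threshold for LQC/MQC/HQC (default 15).
#' @param tol_lloq_pct Threshold at LLOQ (default 20).
#' @return A data frame with one row per summary: level, timeframe, the
#'   statistics, per-rule flags and an overall `pass`.
#' @export
fda_acceptance <- function(summaries, tol_pct = 15, tol_lloq_pct = 20) {
  if (inherits(summaries, "qc_summary")) summaries <- list(summaries)
  if (length(summaries) == 0L) {
    abort_hlmstab("no QC summaries supplied", "hlmstab_empty_input")
  }
  rows <- lapply(summaries, function(q) {
    tol <- if (identical(q$level_label, "LLOQ")) tol_lloq_pct else tol_pct
    data.frame(
      level = q$level_label, timeframe = q$timeframe, nominal = q$nominal,
      n = q$n, mean = q$mean, sd = q$sd, rsd_pct = q$rsd_pct,
      e_pct = q$e_pct, recovery_pct = q$recovery_pct, tol_pct = tol,
      accuracy_pass = leq_tol(abs(q$e_pct), tol),
      precision_pass = leq_tol(q$rsd_pct, tol)
    )
  })
  out <- do.call(rbind, rows)
  out$pass <- out$accuracy_pass & out$precision_pass
  rownames(out) <- NULL
  out
}
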
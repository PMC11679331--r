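#' Resolve a run configuration
#'
#' Merges user settings (optionally from a YAML file) over the package
#' defaults and validates them. The resolved configuration is embedded in
#' every report so a run is reproducible from its output.
#'
#' @param path Optional path to a YAML configuration file.
#' @param ... Named settings overriding both defaults and file values:
#'   `weighting`, `window_mode`, `window`, `r2_threshold`, `scaling` (list
#'   of physiology factors), `fda_tol_pct`, `fda_tol_lloq_pct`,
#'   `stability_threshold_pct`, `clearance_cutoffs` (list with `low_max`,
#'   `high_min`, or NULL), `seed`.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(path = NULL, ...) {
  defaults <- list(
    weighting = "1/x",
    window_mode = "fixed",
    window = c(0, 30),
    r2_threshold = 0.95,
    scaling = list(ml_incubation_per_mg_protein = 1,
                   mg_protein_per_g_liver = 45,
                   g_liver_per_kg_bw = 26,
                   ln2_constant = 0.693),
    fda_tol_pct = 15,
    fda_tol_lloq_pct = 20,
    stability_threshold_pct = 15,
    clearance_cutoffs = NULL,
    seed = 1L
  )
  cfg <- defaults
  if (!is.null(path)) {
    file_cfg <- yaml::read_yaml(path)
    unknown <- setdiff(names(file_cfg), names(defaults))
    if (length(unknown) > 0L) {
      abort_hlmstab(sprintf("unknown config field(s): %s",
                            paste(unknown, collapse = ", ")),
                    "hlmstab_invalid_config")
    }
    cfg[names(file_cfg)] <- file_cfg
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown) > 0L) {
    abort_hlmstab(sprintf("unknown config field(s): %s",
                          paste(unknown, collapse = ", ")),
                  "hlmstab_invalid_config")
  }
  cfg[names(dots)] <- dots
  if (!cfg$weighting %in% c("none", "1/x", "1/x^2")) {
    abort_hlmstab("config: invalid weighting scheme", "hlmstab_invalid_config")
  }
  if (!cfg$window_mode %in% c("fixed", "auto")) {
    abort_hlmstab("config: invalid window_mode", "hlmstab_invalid_config")
  }
  cfg$window <- as.numeric(cfg$window)
  if (length(cfg$window) != 2L || cfg$window[1] >= cfg$window[2]) {
    abort_hlmstab("config: window must be c(t_start, t_end)",
                  "hlmstab_invalid_config")
  }
  # validates the factors
  do.call(physiology_scaling, cfg$scaling)
  structure(cfg, class = "run_config")
}

#' Assemble a validation report
#'
#' Bundles the computed sections into one machine-readable object. All
#' numbers are stored at full precision; display rounding happens only in
#' [render_report()]'s markdown/TSV renderings. Sections left `NULL` are
#' omitted from renderings without error.
#'
#' @param calibration A `calibration_fit`, or NULL.
#' @param qc A data frame from [fda_acceptance()], or NULL.
#' @param matrix_effect A list (e.g. `me_analyte_pct`, `me_is_pct`, `nme`),
#'   or NULL.
#' @param recovery A list of recovery percentages, or NULL.
#' @param storage_stability A list of [stability_assessment()] records, or
#'   NULL.
#' @param metabolic_stability A `stability_result`, or NULL.
#' @param greenness A `greenness_assessment`, or NULL.
#' @param config A [run_config()].
#' @param timestamp Report timestamp (fixed at build time so renderings are
#'   byte-deterministic).
#' @return An object of class `validation_report`.
#' @export
build_validation_report <- function(calibration = NULL, qc = NULL,
                                    matrix_effect = NULL, recovery = NULL,
                                    storage_stability = NULL,
                                    metabolic_stability = NULL,
                                    greenness = NULL,
                                    config = run_config(),
                                    timestamp = format(Sys.time(),
                                                       "%Y-%m-%dT%H:%M:%S%z")) {
  sections <- list()
  if (!is.null(calibration)) {
    ll <- lod_loq(calibration$slope, calibration$sd_intercept)
    sections$calibration <- list(
      slope = calibration$slope, intercept = calibration$intercept,
      r2 = calibration$r_squared, weighting = calibration$weighting,
      sd_intercept = calibration$sd_intercept, n_points = calibration$n_points,
      lod_ng_ml = ll$lod, loq_ng_ml = ll$loq)
  }
  if (!is.null(qc)) sections$qc <- qc
  if (!is.null(matrix_effect)) sections$matrix_effect <- matrix_effect
  if (!is.null(recovery)) sections$recovery <- recovery
  if (!is.null(storage_stability)) {
    sections$storage_stability <- storage_stability
  }
  if (!is.null(metabolic_stability)) {
    ms <- metabolic_stability
    sections$metabolic_stability <- list(
      analyte = ms$analyte, window_min = ms$window, slope = ms$slope,
      slope_magnitude = ms$slope_k, intercept = ms$intercept,
      r2 = ms$r_squared, n_points = ms$n_points, t_half_min = ms$t_half,
      clint_ml_min_kg = ms$clint, clearance_class = ms$clearance_class)
  }
  if (!is.null(greenness)) {
    sections$greenness <- list(overall = greenness$overall,
                               criteria = greenness$criteria)
  }
  structure(list(sections = sections,
                 config = unclass(config),
                 software = list(package = "hlmstab",
                                 version = as.character(
                                   utils::packageVersion("hlmstab"))),
                 timestamp = timestamp),
            class = "validation_report")
}

report_tables <- function(report) {
  s <- report$sections
  out <- list()
  fmt <- function(x) sprintf("%.2f", round_half_up(x))
  if (!is.null(s$calibration)) {
    cb <- s$calibration
    out$calibration <- data.frame(
      statistic = c("slope", "intercept", "r2", "weighting", "sd_intercept",
                    "lod_ng_ml", "loq_ng_ml"),
      value = c(format(cb$slope, digits = 6), format(cb$intercept, digits = 6),
                sprintf("%.4f", cb$r2), cb$weighting,
                format(cb$sd_intercept, digits = 4), fmt(cb$lod_ng_ml),
                fmt(cb$loq_ng_ml)))
  }
  if (!is.null(s$qc)) {
    q <- s$qc
    out$qc <- data.frame(level = q$level, timeframe = q$timeframe,
                         nominal = q$nominal, n = q$n, mean = fmt(q$mean),
                         sd = fmt(q$sd), rsd_pct = fmt(q$rsd_pct),
                         e_pct = fmt(q$e_pct), pass = q$pass)
  }
  if (!is.null(s$storage_stability)) {
    st <- s$storage_stability
    out$storage_stability <- data.frame(
      condition = vapply(st, `[[`, "", "condition"),
      level = vapply(st, `[[`, "", "level_label"),
      e_pct = fmt(vapply(st, `[[`, 0, "e_pct")),
      rsd_pct = fmt(vapply(st, `[[`, 0, "rsd_pct")),
      pass = vapply(st, `[[`, TRUE, "pass"))
  }
  if (!is.null(s$metabolic_stability)) {
    ms <- s$metabolic_stability
    out$metabolic_stability <- data.frame(
      statistic = c("window_min", "slope", "intercept", "r2", "t_half_min",
                    "clint_ml_min_kg", "clearance_class"),
      value = c(sprintf("%g-%g", ms$window_min[1], ms$window_min[2]),
                sprintf("%.5f", ms$slope), sprintf("%.3f", ms$intercept),
                sprintf("%.4f", ms$r2), fmt(ms$t_half_min),
                fmt(ms$clint_ml_min_kg), as.character(ms$clearance_class)))
  }
  if (!is.null(s$greenness)) {
    out$greenness <- data.frame(
      statistic = c("overall",
                    sprintf("criterion_%02d", s$greenness$criteria$index)),
      value = fmt(c(s$greenness$overall, s$greenness$criteria$score)))
  }
  out
}

#' Render a validation report
#'
#' JSON is the machine-readable source of truth (full precision);
#' markdown and TSV are human-readable renderings with 2-dp half-up display
#' rounding. Rendering is deterministic: the same report yields identical
#' bytes.
#'
#' @param report A [build_validation_report()] object.
#' @param format `"json"`, `"markdown"` or `"tsv"`.
#' @param path Optional output file; when given, the document is also
#'   written there.
#' @return The rendered document as a character scalar, invisibly when
#'   `path` is given.
#' @export
render_report <- function(report, format = c("json", "markdown", "tsv"),
                          path = NULL) {
  format <- match.arg(format)
  if (!inherits(report, "validation_report")) {
    abort_hlmstab("`report` must be a validation_report",
                  "hlmstab_invalid_argument")
  }
  if (format == "json") {
    doc <- as.character(jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                                         digits = NA, null = "null",
                                         pretty = TRUE, dataframe = "rows"))
  } else {
    tabs <- report_tables(report)
    if (format == "markdown") {
      chunks <- vapply(names(tabs), function(nm) {
        df <- tabs[[nm]]
        header <- paste0("| ", paste(names(df), collapse = " | "), " |")
        sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
        rows <- apply(df, 1, function(r) {
          paste0("| ", paste(r, collapse = " | "), " |")
        })
        paste(c(sprintf("## %s", nm), "", header, sep, rows, ""),
              collapse = "\n")
      }, character(1))
      doc <- paste(c(sprintf("# Validation report (%s %s, %s)",
                             report$software$package,
                             report$software$version, report$timestamp),
                     "", chunks), collapse = "\n")
    } else {
      chunks <- vapply(names(tabs), function(nm) {
        df <- tabs[[nm]]
        con <- textConnection("chunk", "w", local = TRUE)
        utils::write.table(df, con, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        close(con)
        paste(c(sprintf("# %s", nm), chunk), collapse = "\n")
      }, character(1))
      doc <- paste(chunks, collapse = "\n\n")
    }
  }
  if (!is.null(path)) {
    writeLines(doc, path, useBytes = TRUE)
    return(invisible(doc))
  }
  doc
}
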
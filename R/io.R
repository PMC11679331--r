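# CSV readers share one dialect: comma-separated, '.' decimal, UTF-8,
# header mandatory. Row-level problems are collected and reported together
# with file:line references (line 1 is the header).

read_table_checked <- function(path, required, numeric_cols) {
  if (!file.exists(path)) {
    abort_hlmstab(sprintf("input file not found: %s", path),
                  "hlmstab_missing_file")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    abort_hlmstab(sprintf("%s: missing required column(s): %s", path,
                          paste(missing, collapse = ", ")),
                  "hlmstab_schema_error")
  }
  problems <- character(0)
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "")
    if (length(bad) > 0L) {
      problems <- c(problems, sprintf("%s:%d non-numeric value in '%s'",
                                      path, bad + 1L, col))
    }
    df[[col]] <- v
  }
  list(data = df, problems = problems)
}

raise_schema_problems <- function(problems) {
  if (length(problems) > 0L) {
    abort_hlmstab(paste(c("schema errors:", problems), collapse = "\n  "),
                  "hlmstab_schema_error")
  }
}

#' Read a calibration CSV
#'
#' Expected columns: `sample_id`, `role` (CS/QC/BLANK), `nominal_ng_ml`,
#' `response_ratio`, `replicate`, `batch`, `day`. Non-blank rows must carry
#' a positive nominal concentration; violations are reported with file:line
#' references.
#'
#' @param path Path to the CSV file.
#' @return A list: `points` (a [calibration_points()] object built from the
#'   CS rows), `qc` (QC rows as a data frame), `blanks` (blank rows).
#' @export
read_calibration_csv <- function(path) {
  res <- read_table_checked(
    path,
    required = c("sample_id", "role", "nominal_ng_ml", "response_ratio",
                 "replicate", "batch", "day"),
    numeric_cols = c("nominal_ng_ml", "response_ratio", "replicate", "day"))
  df <- res$data
  problems <- res$problems
  bad_role <- which(!df$role %in% c("CS", "QC", "BLANK"))
  if (length(bad_role) > 0L) {
    problems <- c(problems, sprintf("%s:%d invalid role '%s'", path,
                                    bad_role + 1L, df$role[bad_role]))
  }
  non_blank <- df$role != "BLANK"
  bad_nom <- which(non_blank & (is.na(df$nominal_ng_ml) |
                                df$nominal_ng_ml <= 0))
  if (length(bad_nom) > 0L) {
    problems <- c(problems,
                  sprintf("%s:%d nominal_ng_ml must be > 0 for %s rows",
                          path, bad_nom + 1L, df$role[bad_nom]))
  }
  raise_schema_problems(problems)
  cs <- df[df$role == "CS", ]
  list(
    points = calibration_points(cs$nominal_ng_ml, cs$response_ratio,
                                replicate = cs$replicate, batch = cs$batch),
    qc = df[df$role == "QC", ],
    blanks = df[df$role == "BLANK", ]
  )
}

#' Read a QC determinations CSV
#'
#' Expected columns: `level`, `nominal_ng_ml`, `conc_ng_ml`, `replicate`,
#' `day`, `condition`.
#'
#' @param path Path to the CSV file.
#' @return A validated data frame.
#' @export
read_qc_csv <- function(path) {
  res <- read_table_checked(
    path,
    required = c("level", "nominal_ng_ml", "conc_ng_ml", "replicate", "day",
                 "condition"),
    numeric_cols = c("nominal_ng_ml", "conc_ng_ml", "replicate", "day"))
  problems <- res$problems
  bad <- which(is.na(res$data$nominal_ng_ml) | res$data$nominal_ng_ml <= 0)
  if (length(bad) > 0L) {
    problems <- c(problems, sprintf("%s:%d nominal_ng_ml must be > 0",
                                    path, bad + 1L))
  }
  raise_schema_problems(problems)
  res$data
}

#' Read a depletion time-course CSV
#'
#' Expected columns: `time_min`, `replicate`, `conc_ng_ml`, `analyte`,
#' `nadph` (plus/minus). Rows with `nadph = "minus"` are the negative
#' (no-cofactor) control: they are summarized but never fitted.
#'
#' @param path Path to the CSV file.
#' @return A list: `series` (a [depletion_series()] of per-time replicate
#'   means from the `plus` rows) and `control` (a per-time summary data
#'   frame of the `minus` rows, or `NULL` when absent).
#' @export
read_depletion_csv <- function(path) {
  res <- read_table_checked(
    path,
    required = c("time_min", "replicate", "conc_ng_ml", "analyte", "nadph"),
    numeric_cols = c("time_min", "replicate", "conc_ng_ml"))
  df <- res$data
  problems <- res$problems
  bad <- which(!df$nadph %in% c("plus", "minus"))
  if (length(bad) > 0L) {
    problems <- c(problems, sprintf("%s:%d nadph must be 'plus' or 'minus'",
                                    path, bad + 1L))
  }
  raise_schema_problems(problems)
  plus <- df[df$nadph == "plus", ]
  if (nrow(plus) == 0L) {
    abort_hlmstab(sprintf("%s: no NADPH-plus rows to fit", path),
                  "hlmstab_schema_error")
  }
  times <- sort(unique(plus$time_min))
  means <- vapply(times, function(t) mean(plus$conc_ng_ml[plus$time_min == t]),
                  numeric(1))
  series <- depletion_series(times, means, analyte = plus$analyte[1],
                             replicates = plus[, c("time_min", "replicate",
                                                   "conc_ng_ml")])
  control <- NULL
  minus <- df[df$nadph == "minus", ]
  if (nrow(minus) > 0L) {
    ct <- sort(unique(minus$time_min))
    control <- data.frame(
      time_min = ct,
      conc_ng_ml = vapply(ct, function(t) {
        mean(minus$conc_ng_ml[minus$time_min == t])
      }, numeric(1)))
  }
  list(series = series, control = control)
}

#' Read a greenness-criteria CSV
#'
#' Expected columns: `criterion_index`, `score`, `weight`, `note`. Indices
#' must cover 1-12 exactly.
#'
#' @param path Path to the CSV file.
#' @return A [greenness_criteria()] object.
#' @export
read_greenness_csv <- function(path) {
  res <- read_table_checked(
    path,
    required = c("criterion_index", "score", "weight", "note"),
    numeric_cols = c("criterion_index", "score", "weight"))
  raise_schema_problems(res$problems)
  df <- res$data[order(res$data$criterion_index), ]
  if (!identical(as.integer(df$criterion_index), 1:12)) {
    abort_hlmstab(sprintf("%s: criterion_index must cover 1-12 exactly", path),
                  "hlmstab_schema_error")
  }
  greenness_criteria(df$score, weight = df$weight, note = df$note)
}
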
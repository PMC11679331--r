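#' @keywords internal
"_PACKAGE"

# Classed error helper so callers can condition on failure modes.
abort_hlmstab <- function(message, class) {
  stop(structure(
    class = c(class, "hlmstab_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' Round half away from zero
#'
#' Display rounding used throughout the validation reports: ties round away
#' from zero ("half-up" on the magnitude), unlike [base::round()]'s
#' round-half-even. Applied only at render time; all computation keeps full
#' precision.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2, the convention of
#'   bioanalytical validation tables).
#' @return Numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(2.345, 2)   # 2.35
#' round_half_up(-1.315, 2)  # -1.32
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# Inclusive threshold comparison robust to floating-point representation:
# a statistic exactly at an acceptance boundary passes.
leq_tol <- function(x, limit) {
  x <= limit | abs(x - limit) <= 1e-9 * max(1, abs(limit))
}

# Evaluate an expression under a temporary RNG state; the caller's stream is
# untouched. All generators funnel through this so they are pure in (args, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort_hlmstab("`seed` must be a single finite number", "hlmstab_invalid_seed")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_hlmstab(sprintf("`%s` must be a single finite number", name),
                  "hlmstab_invalid_argument")
  }
  invisible(x)
}

#' Path to a packaged example data file
#'
#' @param file Name of a file under the package's `extdata` directory; with
#'   no argument, lists the available files.
#' @return A file path, or a character vector of file names.
#' @examples
#' hlmstab_example()
#' hlmstab_example("revumenib_hlm_depletion.csv")
#' @export
hlmstab_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "hlmstab")))
  }
  path <- system.file("extdata", file, package = "hlmstab")
  if (identical(path, "")) {
    abort_hlmstab(sprintf("no packaged file named '%s'", file),
                  "hlmstab_missing_file")
  }
  path
}
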
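#' Construct the 12 green-analytical-chemistry criteria
#'
#' The 12-principle greenness assessment assigns each principle a score in
#' [0, 1] and a positive weight (default 2 for all, i.e. equal weighting).
#'
#' @param score Numeric vector of exactly 12 scores in [0, 1], ordered by
#'   criterion index 1-12.
#' @param weight Positive weights (recycled; default 2).
#' @param note Optional free-text notes (recycled).
#' @return A data frame of class `greenness_criteria` with columns `index`,
#'   `score`, `weight`, `note`.
#' @export
greenness_criteria <- function(score, weight = 2, note = "") {
  if (length(score) != 12L) {
    abort_hlmstab("exactly 12 criterion scores are required",
                  "hlmstab_invalid_criteria")
  }
  if (any(!is.finite(score)) || any(score < 0) || any(score > 1)) {
    abort_hlmstab("criterion scores must lie in [0, 1]",
                  "hlmstab_invalid_criteria")
  }
  weight <- rep_len(weight, 12L)
  if (any(!is.finite(weight)) || any(weight <= 0)) {
    abort_hlmstab("criterion weights must be > 0", "hlmstab_invalid_criteria")
  }
  out <- data.frame(index = 1:12, score = as.numeric(score),
                    weight = as.numeric(weight),
                    note = rep_len(as.character(note), 12L),
                    stringsAsFactors = FALSE)
  class(out) <- c("greenness_criteria", "data.frame")
  out
}

greenness_color_bin <- function(score,
                                thresholds = c(dark_green = 0.8, green = 0.6,
                                               yellow = 0.4)) {
  ifelse(score >= thresholds[["dark_green"]], "dark_green",
    ifelse(score >= thresholds[["green"]], "green",
      ifelse(score >= thresholds[["yellow"]], "yellow", "red")))
}

#' Aggregate criterion scores into an overall greenness score
#'
#' The overall score is the weighted arithmetic mean of the 12 criterion
#' scores, sum(w_i s_i) / sum(w_i), bounded by the minimum and maximum
#' criterion score and invariant to rescaling all weights. Per-criterion
#' color bins (display only) mimic the published palette.
#'
#' @param criteria A [greenness_criteria()] object, or a numeric vector of
#'   12 scores (equal weights assumed).
#' @param color_thresholds Display binning thresholds.
#' @return An object of class `greenness_assessment` with elements
#'   `criteria` (including a `color` column) and `overall`.
#' @examples
#' agree_score(c(0.3, 1, 0.66, 1, 0.75, 1, 0.69, 1, 0, 1, 1, 0.8))
#' @export
agree_score <- function(criteria,
                        color_thresholds = c(dark_green = 0.8, green = 0.6,
                                             yellow = 0.4)) {
  if (is.numeric(criteria)) criteria <- greenness_criteria(criteria)
  if (!inherits(criteria, "greenness_criteria")) {
    abort_hlmstab("`criteria` must be a greenness_criteria object",
                  "hlmstab_invalid_criteria")
  }
  overall <- sum(criteria$weight * criteria$score) / sum(criteria$weight)
  criteria$color <- greenness_color_bin(criteria$score, color_thresholds)
  structure(list(criteria = criteria, overall = overall),
            class = "greenness_assessment")
}

#' @export
print.greenness_assessment <- function(x, ...) {
  cat(sprintf("Greenness assessment: overall score %.2f\n",
              round_half_up(x$overall)))
  print(as.data.frame(x$criteria), row.names = FALSE)
  invisible(x)
}

#' Ring diagram of a greenness assessment
#'
#' Twelve colored sectors (one per criterion) around the rounded overall
#' score, in the style of the standard greenness pictogram.
#'
#' @param x A `greenness_assessment`.
#' @param ... Ignored.
#' @return Invisibly, `x`.
#' @export
plot.greenness_assessment <- function(x, ...) {
  pal <- c(dark_green = "#1a7a1a", green = "#67c067", yellow = "#e6c229",
           red = "#c0392b")
  old <- graphics::par(mar = c(1, 1, 1, 1), pty = "s")
  on.exit(graphics::par(old), add = TRUE)
  graphics::plot(NA, xlim = c(-1.2, 1.2), ylim = c(-1.2, 1.2), axes = FALSE,
                 xlab = "", ylab = "", asp = 1)
  ang <- seq(pi / 2, pi / 2 - 2 * pi, length.out = 13)
  for (i in 1:12) {
    th <- seq(ang[i], ang[i + 1], length.out = 30)
    r_out <- 0.6 + 0.5 * x$criteria$score[i]
    graphics::polygon(c(0.55 * cos(th), rev(r_out * cos(th))),
                      c(0.55 * sin(th), rev(r_out * sin(th))),
                      col = pal[x$criteria$color[i]], border = "white")
    graphics::text(0.85 * cos(mean(th)), 0.85 * sin(mean(th)), i, cex = 0.7)
  }
  graphics::text(0, 0, sprintf("%.2f", round_half_up(x$overall)), cex = 2)
  invisible(x)
}
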
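# Independent oracles used to cross-check the fitting code. These go through
# the normal equations with solve() directly and share no code path with
# fit_calibration()/fit_depletion() (which use stats::lm).

weights_for <- function(x, scheme) {
  switch(scheme, "none" = rep(1, length(x)), "1/x" = 1 / x, "1/x^2" = 1 / x^2)
}

wls_oracle <- function(x, y, w = rep(1, length(x))) {
  A <- matrix(c(sum(w), sum(w * x), sum(w * x), sum(w * x^2)), 2, 2)
  b <- c(sum(w * y), sum(w * x * y))
  coef <- solve(A, b)
  e <- y - coef[1] - coef[2] * x
  ybar_w <- sum(w * y) / sum(w)
  r2 <- 1 - sum(w * e^2) / sum(w * (y - ybar_w)^2)
  s2 <- sum(w * e^2) / (length(x) - 2)
  se_intercept <- sqrt((s2 * solve(A))[1, 1])
  list(intercept = coef[1], slope = coef[2], r_squared = r2,
       se_intercept = se_intercept)
}

# Two-pass mean/variance oracle for replicate statistics.
moments_oracle <- function(v) {
  m <- sum(v) / length(v)
  s <- sqrt(sum((v - m)^2) / (length(v) - 1))
  list(mean = m, sd = s)
}

# Brute-force prefix-window enumeration for log-linear window selection:
# score every prefix of >= min_points by the squared correlation of ln(pct)
# with time and return the longest one reaching the threshold.
prefix_window_oracle <- function(time, pct, r2_threshold = 0.95,
                                 min_points = 4L) {
  best <- NULL
  for (k in seq(min_points, length(time))) {
    if (any(pct[seq_len(k)] <= 0)) break
    r2 <- stats::cor(time[seq_len(k)], log(pct[seq_len(k)]))^2
    if (r2 >= r2_threshold) best <- k
  }
  if (is.null(best)) return(NULL)
  c(time[1], time[best])
}

# Interval-consistency check for a printed summary table: given printed
# 2-dp inputs (mean, sd) and nominal, a printed derived cell is consistent
# if the interval it implies (value +/- 0.005) overlaps the interval of
# values reachable from inputs perturbed within their own rounding.
overlaps <- function(lo1, hi1, lo2, hi2) lo1 <= hi2 && lo2 <= hi1
h <- 0.005

check_printed_cells <- function(nominal, mean, sd, rsd = NA, e = NA,
                                recovery = NA, label = "") {
  out <- list()
  if (!is.na(rsd)) {
    lo <- 100 * (sd - h) / (mean + h)
    hi <- 100 * (sd + h) / (mean - h)
    out$rsd <- overlaps(lo, hi, rsd - h, rsd + h)
  }
  e_lo <- 100 * ((mean - h) - nominal) / nominal
  e_hi <- 100 * ((mean + h) - nominal) / nominal
  if (!is.na(e)) out$e <- overlaps(e_lo, e_hi, e - h, e + h)
  if (!is.na(recovery)) {
    out$recovery <- overlaps(e_lo + 100, e_hi + 100, recovery - h,
                             recovery + h)
  }
  data.frame(cell = sprintf("%s:%s", label, names(out)),
             consistent = unlist(out), row.names = NULL)
}

# Low-end back-calculation error under 1/x vs unweighted fitting, averaged
# over seeds, for heteroscedastic calibration data.
lowend_error_study <- function(n_seeds, cv_proportional = 0.06,
                               sd_additive = 0.002) {
  errs <- vapply(seq_len(n_seeds), function(s) {
    sc <- assay_scenario(cv_proportional = cv_proportional,
                         sd_additive = sd_additive, n_replicates = 3L,
                         seed = s)
    pts <- gen_calibration(sc)
    low <- pts$nominal_conc == min(pts$nominal_conc)
    err_for <- function(weighting) {
      fit <- fit_calibration(pts, weighting = weighting)
      mean(abs(back_calculate(fit, pts$response[low]) -
                 pts$nominal_conc[low]))
    }
    c(wls = err_for("1/x"), ols = err_for("none"))
  }, numeric(2))
  rowMeans(errs)
}

table7_series <- function() {
  read_depletion_csv(hlmstab_example("revumenib_hlm_depletion.csv"))$series
}
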
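---
title: "Methods: calibration, validation statistics and microsomal stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibration, validation statistics and microsomal stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlmstab)
```

# What the package computes

hlmstab covers the quantitative half of a bioanalytical LC-MS/MS assay run
in human liver microsomes (HLMs): turning peak-area ratios into
concentrations through a weighted calibration curve, summarizing
quality-control (QC) replicates into the precision/accuracy/recovery
statistics that regulatory validation requires, estimating in vitro
metabolic stability from a substrate-depletion time course, and
aggregating a 12-criterion green-analytical-chemistry assessment.

The worked example shipped with the package is an assay for revumenib, a
menin inhibitor, quantified in HLMs with encorafenib as internal standard;
all packaged fixtures are small plain-text CSV tables.

# Weighted calibration

A calibration standard at nominal concentration $x$ (ng/mL) yields a
response $y$, the analyte/IS peak-area ratio. The model is the straight
line $y = a x + b$, fitted by weighted least squares with weights $w_i$
equal to $1$, $1/x_i$ or $1/x_i^2$. LC-MS/MS response noise grows roughly
in proportion to the signal, so over a wide range (the default design
spans 1–3000 ng/mL) the unweighted fit lets the top standards dominate and
degrades accuracy at the bottom; $1/x$ weighting is the conventional
remedy and is the package default. The test suite demonstrates the effect
empirically: on heteroscedastic simulated assays the $1/x$ fit has a
smaller mean absolute back-calculation error at the lowest level than the
unweighted fit (200 simulated assays at 6% proportional CV).

Numerical choices:

* The weighted $R^2$ is $1 - \sum w_i e_i^2 / \sum w_i (y_i - \bar y_w)^2$
  with $\bar y_w$ the weighted mean response. It reduces to the ordinary
  $R^2$ under equal weights. Fitting is delegated to `stats::lm`, whose
  summary implements exactly this definition; an independent
  normal-equations oracle in the tests pins the agreement at $10^{-10}$.
* The intercept SD that feeds the sensitivity limits
  (LOQ $= 10\,\mathrm{SD}_b / a$, LOD $= 3\,\mathrm{SD}_b / a$) is by
  default the standard error of the intercept from the covariance matrix
  of one pooled weighted fit. When an assay runs several independent
  calibration curves, `sd_intercept_mode = "replicate_curves"` instead
  fits each batch separately and takes the sample SD of the per-curve
  intercepts. Both conventions are found in validation practice and they
  are not interchangeable numerically, so the mode is explicit.
* Back-calculated concentrations below zero (sub-blank responses) are
  returned as-is and flagged downstream; silently clipping them to zero
  would bias low-end accuracy statistics upward.
* Curve acceptance follows the usual bioanalytical rule — each standard
  within ±15% of nominal (±20% at the lowest level), at least 75% of
  standards passing — with every threshold configurable, because agencies
  state these as guidance rather than constants.

# Validation statistics

Replicate QC determinations at one level are summarized by their mean,
sample SD ($n-1$ denominator), precision
$\%\mathrm{RSD} = 100\,s/\bar x$, signed accuracy error
$\%E = 100(\bar x - x_\mathrm{nom})/x_\mathrm{nom}$ and recovery
$100\,\bar x / x_\mathrm{nom}$, so recovery $-$ 100 $= \%E$ identically.
The matrix effect is the mean-response ratio of matrix-prepared to neat
samples ($\times 100$); the IS-normalized matrix effect divides the
analyte's by the internal standard's, and extraction recovery is the same
ratio applied to extracted versus reference sets. Storage-stability
checks (long-term, short-term, autosampler, freeze–thaw) pass when
$|\%E|$ stays within a threshold, 15% by default, with the boundary
inclusive — a statistic exactly at the limit passes, and the comparison
tolerates floating-point representation of values like $0.45/3$.

Reports round half away from zero to 2 decimals at render time only; all
stored numbers keep full precision. Published validation tables are
themselves rounded that way, which has a consequence the consistency
checker in the test suite makes explicit: a derived cell (say, $\%E$ at a
3 ng/mL QC) often cannot be reproduced exactly from the rounded mean,
because a mean printed to 2 dp carries only ±0.005 of information —
0.17 percentage points of slack at that level. The checker therefore
tests interval consistency (the printed derived value must be reachable
from the printed inputs within their own rounding) rather than exact
re-rounding.

# Substrate-depletion kinetics and intrinsic clearance

An HLM incubation at a substrate concentration well below the
Michaelis–Menten constant depletes approximately first order:
$C(t) = C_0 e^{-kt}$. The pipeline normalizes each time point to percent
remaining $X(t) = 100\,C(t)/C_0$ (so $X(0)=100$ exactly and the series is
invariant to rescaling), fits ordinary least squares of $\ln X$ on $t$
over a window, and converts the fitted slope to the in vitro half-life
$t_{1/2} = \ln 2 / |k|$. Intrinsic clearance then follows the well-stirred
liver model:

$$
\mathrm{Cl_{int}} \;=\; 0.693 \cdot \frac{1}{t_{1/2}}
\cdot \frac{\text{mL incubation}}{\text{mg protein}}
\cdot \frac{\text{mg microsomal protein}}{\text{g liver}}
\cdot \frac{\text{g liver}}{\text{kg body weight}}
$$

with default human factors 1 mL/mg, 45 mg/g and 26 g/kg. Decisions worth
stating:

* **Fit window.** Real depletion curves frequently flatten onto a residual
  plateau after the fast phase; only the early segment is log-linear. The
  default is a fixed 0–30 min window. An automatic mode returns the
  longest prefix window (≥ 4 points) whose ln-linear $R^2$ clears a
  threshold (0.95 by default); it exists because other substrates plateau
  at other times, and it is cross-checked in the tests against brute-force
  enumeration of every prefix window.
* **Percent space.** The regression runs on $\ln(\%\,\mathrm{remaining})$
  rather than $\ln(\mathrm{concentration})$. The slope is identical; the
  intercept is near $\ln 100 = 4.605$ and is only comparable to reported
  intercepts in percent space.
* **Slope sign.** The regression slope of a depleting series is negative;
  the half-life uses its magnitude and results carry both (`slope`,
  `slope_k`). Rate magnitudes below $10^{-12}$ min$^{-1}$ are treated as
  no depletion and raise an error instead of returning an astronomically
  large finite half-life — a flat negative-control series must not
  produce a clearance number.
* **The 0.693 constant.** The rate identity constant $\ln 2$ enters the
  clearance formula at its conventional 3-decimal value 0.693 and is a
  configurable field of `physiology_scaling()`, so
  $\mathrm{Cl_{int}} \cdot t_{1/2} = 0.693 \times 1170$ mL·min/kg·min
  holds exactly with the defaults (the conservation is asserted to
  $10^{-9}$ in the tests). The half-life itself uses $\ln 2$ at full
  precision.
* **Classification.** Low/intermediate/high clearance cut-offs differ
  between published schemes, so `classify_clearance()` requires them as
  configuration; there are no hidden defaults presented as literature
  values. Boundaries are inclusive on both sides.
* **Replicates.** Per-time replicate means are taken before the log
  transform (the packaged example table is itself a mean of three
  incubation repeats); replicate-level rows are retained for inspection.

Worked numbers, computed from the packaged 11-point depletion table over
the fixed window: $|k| = 0.04643$ min$^{-1}$, $R^2 = 0.9889$,
$t_{1/2} = 14.93$ min, $\mathrm{Cl_{int}} = 54.31$ mL/min/kg — a
high-clearance profile under any common cut-off scheme.

```{r}
depl <- read_depletion_csv(hlmstab_example("revumenib_hlm_depletion.csv"))
run_stability_pipeline(depl$series)
```

# Greenness aggregation

The 12-principle greenness assessment assigns each criterion a score in
$[0,1]$ and a positive weight (2 for every criterion in the packaged
example, i.e. equal weighting). The overall score is the weighted
arithmetic mean $\sum w_i s_i / \sum w_i$ — permutation invariant,
invariant to rescaling all weights, and bounded by the extreme criterion
scores. For the packaged example the mean of the 12 scores is 0.7667,
displayed as 0.77. Per-criterion color bins (≥0.8 dark green, ≥0.6 green,
≥0.4 yellow, else red) mimic the familiar ring pictogram and are display
configuration only; no quantitative result depends on them. Deriving
criterion scores from method metadata is out of scope — users supply the
scores, the package aggregates and renders them.

# The synthetic-data generators

The generators exist so that every pipeline stage is testable without
instrument data, and their defaults are the study conditions the packaged
example represents:

* `assay_scenario()`: nine calibration levels at 1, 15, 50, 150, 300,
  400, 500, 1500, 3000 ng/mL and QCs at 1/3/900/2400 ng/mL; responses
  $y = a x + b + \varepsilon$ with
  $\sigma(\varepsilon) = \sigma_\mathrm{add} + \mathrm{CV} \cdot a x$
  (defaults 0.002 and 3%). The true line (0.6515, −0.5459) sets realistic
  magnitudes for a peak-area-ratio assay and is never a test target.
* `depletion_scenario()`: $C(t) = C_0\,[P + (1-P)e^{-\lambda t}]$ — first
  order loss of a metabolizable fraction over a residual plateau $P$
  (default 0.22, matching the flat ~22% tail of the example table). The
  plateau is phenomenological; no mechanism (saturable binding, resistant
  fraction) is asserted. $\lambda$ is calibrated by root finding so that
  the ln-linear slope fitted to the noiseless curve over the early window
  equals the requested rate $-k$; the fitted slope is non-monotone in
  $\lambda$ (it falls again once the curve collapses onto the plateau
  inside the window), so the root is taken on the rising branch below the
  maximizing $\lambda$, and unreachable rates raise an error instead of
  returning the wrong branch. With $P = 0$, $\lambda = k$ exactly.
  Measurement noise is multiplicative lognormal with unit mean
  (concentrations are positive and LC-MS error is roughly proportional);
  the default replicate CV of 2% is an assumption — the example table
  prints only per-time means, so no empirical replicate CV is available.
  The default sampling grid is the table's 11 points over 0–70 min.
* `gen_matrix_sets()` draws matched matrix/neat response sets whose mean
  ratios estimate a requested matrix effect and IS-normalized ratio.

All generators are pure functions of their scenario and seed: they save
and restore the caller's RNG state, and fixed seeds give byte-identical
output. What passing simulation tests shows is that the estimators
recover the parameters of these idealized data (exactly when noiseless,
within stated tolerance under noise). What it does not show: robustness
to chromatographic drift, carry-over, integration errors or outlier
replicates, none of which the generators emulate.

Problem sizes used by the test suite — 500 simulated assays for the
slope-unbiasedness check, 1000 depletion seeds at 2% CV for the
half-life recovery study (median within 10% of truth), 200 seeds for the
weighting comparison — are the package's choice of a size at which the
Monte-Carlo error is comfortably below the tolerances being asserted.

# Reports and reproducibility

`build_validation_report()` assembles whichever sections were computed
(absent sections are omitted, not faked), embeds the resolved
`run_config()` and package version, and fixes the timestamp at build time
so rendering is deterministic. JSON is the machine-readable source of
truth at full precision; markdown and TSV renderings apply the 2-dp
half-up display rounding. The same inputs, configuration and seed
therefore produce byte-identical JSON.

# Known limitations

* Calibration is strictly linear; quadratic or 4PL response models are
  not provided.
* Kinetics are single-phase first order. Michaelis–Menten saturation,
  biphasic depletion and non-well-stirred liver models (parallel tube,
  dispersion) are out of scope.
* The package starts from integrated peak-area ratios; peak detection and
  integration belong to instrument software.
* Greenness criterion scores are inputs, not derived quantities.
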
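---
title: "Methods: kinetics, carbon balance and transcriptome analysis of triple-phase oxygen-shift fermentations"
author: "oxyshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triple-phase oxygen-shift analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxyshift)
```

## The process and its model

A triple-phase batch fermentation drives *Corynebacterium glutamicum*
from aerobiosis via microaerobiosis into anaerobiosis within one
reactor: constant, low aeration lets the growing culture deplete
dissolved oxygen (DO reaches 0 % of saturation while growth continues),
the onset of organic-acid secretion (lactate, succinate, acetate) marks
the beginning of oxygen limitation, and a deliberate aeration stop
finally renders the process anaerobic. The phases are bordered by the
culture's own physiology: each has a characteristic specific growth
rate $\mu$, biomass yield $Y_{X/S}$ and product yield spectrum
$Y_{P/S}$.

`oxyshift` models this as a piecewise-exponential batch process with
piecewise-constant stoichiometry. Within phase $p$,

$$X(t) = X_0^{(p)} e^{\mu_p (t - t_p)}, \qquad
  \Delta S = \frac{\Delta X}{Y_{X/S,p}}, \qquad
  \Delta P_i = Y_{P_i/S,p}\,\frac{\Delta S}{M_{glc}}\, M_i ,$$

with molar masses $M$ (glucose 180.16, lactate 90.08, succinate
118.09, acetate 60.05 g mol⁻¹). The default parameters are the
reference phase table of the process
(`default_phase_params()`): $\mu$ = 0.40/0.21/0.09 h⁻¹, $Y_{X/S}$ =
0.52/0.29/0.16 g g⁻¹ and the lactate/succinate/acetate yields per
phase. This deliberately ignores Monod-type oxygen kinetics: the
observed microaerobic phase shows simultaneous growth and fermentation
at *constant* yields, so piecewise-constant stoichiometry is both
simpler and sufficient for parameter recovery. No oxygen-transfer
(kLa/OTR) differential equation is solved; DO is a descriptive
monotone decay that reaches 0 before the microaerobic onset, because
the phase logic keys on product onset and the switch event, not on DO.

### Carbon closure by construction

CO₂ evolution is the carbon residual of each phase's stoichiometry:
per mol glucose (6 C-mol), biomass binds
$Y_{X/S} \cdot 180.16 \cdot 0.514 / 12.011$ C-mol (51.4 % carbon in
dry biomass) and each acid $Y_{P/S} \cdot n_C$ C-mol; CO₂ takes the
rest, so the noise-free balance closes at exactly 1.00 C-mol per
C-mol at every time point. Two consequences deserve emphasis:

* With the reference anaerobic yields, biomass plus acids bind *more*
  than 6 C-mol per mol glucose — anaerobic succinate formation fixes
  CO₂ through anaplerotic carboxylation. The generator therefore emits
  a **negative net CO₂ evolution rate** in the anaerobic phase. This
  is a modelling assumption, not a measured quantity: the real process
  stopped exhaust-gas analysis with the aeration stop, and no
  per-phase CO₂ yield is available. `integrate_co2()` accepts negative
  rates for this reason.
* The emitted rate column is constructed so that the documented
  summation convention — "average between sequential points, then
  sum", i.e. the trapezoidal rule — reproduces the model's cumulative
  CO₂ *exactly* ($q_{i+1} = 2\,\Delta C_i/\Delta t_i - q_i$).
  Otherwise quadrature error on an exponential (~0.1 % at 15-min
  sampling) would contaminate a closure that is exact by construction.

### Observation noise

Noise is multiplicative, lognormal and mean-one
(`meanlog = -sdlog²/2`), applied to observations only — the underlying
state is deterministic. Concentrations are positive and chromatographic
errors are roughly relative, which makes a lognormal factor the natural
choice; mean-one keeps observations unbiased so that Monte-Carlo means
converge to the generating values. Defaults are cv = 0.03 for biomass
and metabolites (typical OD/HPLC reproducibility) and 0.08 for the
RNA-content assay.

### Sampling grid

The default grid is `seq(0, 14, 0.25)` h. With the reference
parameters glucose (60 g L⁻¹) is exhausted at ≈14.3 h, which caps the
horizon; 15-minute resolution — routine for at-line autosamplers —
gives ≥13 observations per phase, enough for the window-search
regressions below.

## Phase segmentation

`segment_phases()` places the aerobic→microaerobic boundary at the
first time any organic acid exceeds `product_threshold`, linearly
interpolated between the bracketing samples, and the
microaerobic→anaerobic boundary at the `aeration_stop` event. The
threshold defaults to 0.10 g L⁻¹, a typical HPLC quantification floor;
the onset itself is only defined operationally (a vanishing threshold
has no noise-robust meaning), and the generator uses the *same*
threshold to define its ground-truth boundary, so segmentation and
truth agree by design. Windows are half-open — a sample exactly on a
boundary belongs to the later phase — so no sample is counted twice.

```{r segment}
tr <- simulate_fermentation(process_scenario(seed = 1))
segment_phases(tr)
```

## Growth rates: R²-guided window choice, done carefully

Growth rates are slopes of $\ln X$ versus $t$. The classical recipe —
pick the contiguous sample window that maximizes the regression R² —
has a statistical trap that matters here: across the
$O(n^2)$ candidate sub-windows of noisy single-phase data, R² is
maximized by windows in which the noise happens to *steepen* the
slope (R² rewards signal variance relative to residual variance).
Literal exhaustive maximization therefore overestimates $\mu$
systematically; at cv = 0.03 we measure a mean recovered anaerobic
$\mu$ of 0.130 h⁻¹ against a generating value of 0.090 h⁻¹.

`fit_growth_rate()` therefore uses a *significance-guarded* search by
default: it keeps the full window unless some sub-window's line fits
significantly better, judged by a nested F-test on the points the
trimming would exclude (model "all points on one line" against
"sub-window on a line, excluded points free"), Bonferroni-corrected
across candidates at `alpha = 0.001`. On data that are exponential
throughout, the full window is retained (up to the test level) and the
estimate is the unbiased full-window slope; a genuine breakpoint — a
lag phase, a phase transition — produces an overwhelming F and is
trimmed away. The literal variant remains available as
`method = "exhaustive"` for comparison. Ties are resolved
deterministically (more points, then the earlier start), and the
selection is invariant to rescaling biomass (an OD-to-CDW coefficient
$\alpha$ shifts the intercept of $\ln X$, never the slope or the
chosen window).

## Yields: regression orientation against attenuation

Yields are slopes of concentration-versus-concentration regressions
over a phase window. Both axes carry relative measurement error, and
ordinary least squares is attenuated by the errors-in-variables factor
$\mathrm{var}(x^*) / (\mathrm{var}(x^*) + \sigma_x^2)$ of whichever
variable serves as regressor. In the aerobic window this is not a
subtlety: glucose falls only ~6 g L⁻¹ from 60 g L⁻¹, so a 3 % relative
error (σ ≈ 1.7 g L⁻¹) attenuates the biomass-on-glucose slope by
almost half — the recovered $Y_{X/S}$ would be ≈0.29 instead of 0.52.
Meanwhile biomass spans a ninefold range in the same window and is an
almost noise-free regressor in the relative sense.

`fit_yield()` therefore orients the regression onto whichever variable
has the larger relative spread (`sd/mean`) and inverts the slope when
glucose ends up as the response, applying the second-order ratio bias
correction $\hat Y = |b|^{-1} / (1 + (\mathrm{se}_b/b)^2)$ for the
convexity of the inversion. Both orientations coincide on noise-free
data, and every noise-free estimate equals its generating parameter to
≤1e-6 relative error. Product slopes are converted from g g⁻¹ to
mol mol⁻¹ via the molar masses. Volumes cancel: the batch volume is
constant, so concentration regressions equal amount regressions.

## Specific substrate uptake

$q_S = \mu / Y_{X/S}$ with Gaussian error propagation,
$\sigma_q = \sqrt{(\sigma_\mu / Y)^2 + (\mu\,\sigma_Y / Y^2)^2}$ — the
general form, so that $\mu = 0$ with $\sigma_\mu = 0$ gives
$q_S = 0 \pm 0$ rather than 0/0. Report tables round half-up to two
decimals (full precision is retained internally):

```{r qs}
q <- compute_qs(c(0.40, 0.01), c(0.52, 0.04))
c(value = q$value, stderr = q$stderr)
```

## Differential expression: the empirical m/a cutoff

Expression is quantified as TPM over CDS lengths (gene-level CDS
quantification; no fragment-length correction). For each comparison
against the aerobic reference sample, the m-value is the log₂ TPM
ratio and the a-value the arithmetic mean of the two samples' TPM on
the linear scale — the literal reading of "mean of TPM"; the MA-plot
convention (mean of log₂ TPM, threshold equivalent 2 TPM) is *not*
used, and a pseudocount (default 1 TPM, configurable, 0 allowed for
positive matrices) guards the ratio for silent genes. A gene is called
`up` iff $m > 1.50$ and $a > 1.00$, `down` iff $m < -1.50$ and
$a > 1.00$; inequalities are strict, and $a \le 1$ excludes the gene
as low-signal regardless of m. No count-model test is performed — in a
process whose transcriptome changes wholesale, the
most-genes-unchanged assumption behind dispersion-based null tests is
exactly what fails, which is why the cutoff is empirical.

The microaerobic phase call averages the m- and a-values of the three
microaerobic comparisons *before* applying the cutoff (averaging the
comparison values, not the TPMs). Phase-wise up/down sets are
partitioned into the seven disjoint Venn regions per polarity; a gene
up in one phase and down in another appears in both polarity diagrams
and is flagged. COG-class summaries report mean ± SD of m over the
altered subset only, and the regulator screen separates regulators
significant in ≥1 comparison from the candidates significant in more
than one. Note that TPM is compositional: planting log₂ shifts changes
the per-sample normalization slightly, so recovered m-values are
planted shifts plus a small common offset; with ≤10 % of genes
altered, the offset stays well inside the cutoff margin.

## Cell physiology conversions

All four conversions are first-order homogeneous bookkeeping, each
pinned by an invariance test:

* RNA per cell: $10^9 \cdot m_{RNA}[\mu g] / N_{cells}$, with
  $N_{cells}$ from OD600 via 1 OD ≈ 1e8 cells mL⁻¹ when not counted
  directly.
* The RNA–growth-rate regression extrapolates to $\mu = 0$; the first
  sampling point is excluded by default (it precedes balanced growth),
  configurably.
* Enzyme activity: Beer–Lambert with ε = 6.3 mM⁻¹ cm⁻¹ at 340 nm,
  net slope = reaction − baseline (clipped at zero with a warning),
  1 U ≡ 1 µmol min⁻¹ (standard enzymology convention).
* Intracellular concentration: lysate concentration rescaled by total
  lysate volume over the intracellular volume, the latter from the
  cell-volume-to-biomass ratio of 1.95 µL per mg CDW; the acid /
  phosphate / KOH neutralization bookkeeping is collapsed into a
  single `lysate_total_volume_mL` input, and internal-standard
  recovery enters as an optional multiplicative factor (default 1).

## What the generator does and does not emulate

The generator reproduces the *structure* of the study conditions:
piecewise-exponential growth with the reference phase parameters, DO
decline, product-onset and switch boundaries, closure-exact CO₂,
TPM-scale count matrices with planted log₂-fold structure and
negative-binomial overdispersion, and growth-rate-linear RNA content.
It does not emulate: transition smoothing between phases (real yield
changes are not instantaneous), autocorrelated or heteroscedastic
assay drift, compositional library artifacts beyond TPM
renormalization, operon structure or any biological covariance between
genes, rRNA depletion efficiency, or mechanistic oxygen transfer.
Passing recovery tests therefore demonstrates that the estimators are
faithful to their definitions and unbiased under realistic independent
relative noise — not that they are robust to every failure mode of
real process data.

Problem sizes used throughout the test suite and the reproduction
script: 50 simulated traces (57 samples each) for kinetic and closure
recovery, 50 replicate six-point datasets for the RNA intercept,
universes of 100–500 genes for expression properties with 1000-draw
Monte-Carlo checks of the count expectation — sizes at which the
Monte-Carlo standard errors are several times smaller than the
tolerances being asserted.

## Known limitations

* Yield estimates remain mildly attenuated when *both* variables have
  comparable relative spread (e.g. anaerobic $Y_{X/S}$ recovers ≈0.158
  for a generating 0.16); a full errors-in-variables (Deming) fit
  would need a known error-variance ratio, which real records rarely
  have.
* The organic-acid onset is threshold-relative; reported boundaries
  inherit the threshold choice, which is why the rule is recorded in
  every segmentation object.
* The negative anaerobic CO₂ rate is a closure construction, not a
  claim about the real exhaust stream.
* Absolute differential-expression counts of the real process (and
  gene-level fold changes such as the strong *adhA* repression) depend
  on the deposited dataset and are outside what a synthetic universe
  can or should reproduce; the DE machinery is validated by planted
  recovery and exhaustive set-algebra oracles instead.
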
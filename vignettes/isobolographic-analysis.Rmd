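---
title: "Isobolographic synergy analysis with isobolr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isobolographic synergy analysis with isobolr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isobolr)
library(ggplot2)
```

## The question the package answers

Two cytotoxic agents are applied to cells, alone and in combination. Does the
combination kill more cells than the two agents "should" achieve together if
they merely added up? isobolr implements the classical Loewe-additivity
answer, the isobologram, around plate-reader viability assays of the kind
used to study chemo-sensitization — e.g. whether a non-toxic dose of the
opioid antagonist naloxone sensitizes head-and-neck squamous carcinoma cells
to cisplatin.

Under Loewe additivity, doses of two agents that produce the same effect are
exchangeable. At a fixed effect level $E$, the set of additive dose pairs
$(a, b)$ forms the *isobole*. When the relative potency of the agents does
not depend on the effect level, that isobole is the straight segment between
the axis intercepts $(ED_E^A, 0)$ and $(0, ED_E^B)$, and a combination
$(a, b)$ can be summarized by the interaction index

$$\gamma = \frac{a}{ED_E^A} + \frac{b}{ED_E^B},$$

with $\gamma = 1$ on the line, $\gamma < 1$ below it (supra-additive
territory) and $\gamma > 1$ above it. Because the intercepts are estimates,
the verdict is made against a confidence envelope of the line, not the line
itself: only a combination point falling strictly below the lower envelope is
called **synergistic**.

## From absorbance to effect

The raw datum is a well absorbance (OD450, XTT-type assay), proportional to
viable cells. `normalize_viability()` converts it per plate:

$$\text{viability}\% = 100 \cdot \frac{A}{\overline{A}_{\text{control}}},
  \qquad \text{effect}\% = 100 - \text{viability}\%.$$

Effect is the percent reduction in viability relative to the untreated
control wells of the *same plate* (per-plate normalization guards against
plate-to-plate gain differences). Effects are not clamped: a
proliferation-promoting treatment (e.g. a growth-stimulating opioid dose)
legitimately has a negative effect. Blank subtraction is not applied by
default; plates blanked upstream are handled identically since the
normalization is scale-invariant.

## Effective doses by shape-preserving interpolation

`interpolate_ed()` finds $ED_E$ as the smallest dose at which the piecewise
cubic interpolant through the per-dose mean effects reaches $E$. Numerical
choices, made once:

* **Monotone (Fritsch–Carlson) Hermite cubic**, not a natural cubic spline.
  On the short (3–8 point) curves typical of these assays a natural spline
  can overshoot between nodes and manufacture spurious crossings; the
  monotone interpolant reproduces every node exactly and stays within the
  range of neighboring node effects.
* **Anchored at (0, 0)** — an untreated well has zero effect by definition
  of the normalization.
* **Linear dose axis** — the companion significance screen
  (`fit_linear()`, an OLS F-test of mean effect on dose) also operates on
  the linear axis; it warns, but does not stop, when the dose-effect
  relation is weak.
* **First-crossing rule** — with noisy, locally non-monotone means the
  smallest dose reaching $E$ is reported (the conservative choice).
* **No extrapolation** — a level above the maximum observed mean effect is
  an error, never an extrapolated number. Root isolation uses bisection-type
  refinement to a tolerance of $10^{-10}$ of the dose range.

Uncertainty comes from `bootstrap_ed()`: replicates are resampled with
replacement *within each dose* (B = 2000 by default), the interpolant is
refitted, and the percentile interval of the resampled $ED_E$ is reported.
Resamples whose curve no longer reaches $E$ are dropped and counted; more
than 50% unreachable invalidates the interval with a diagnostic error. With
very few replicates per dose (n = 3 is common in these assays) percentile
intervals are known to run slightly narrow; the package reports the interval
as defined rather than applying small-sample corrections, and the coverage
behaviour is quantified by the test suite.

## The synergy engine

`assess_synergy()` chains the full analysis:

1. **Escalation of the analysis level.** The default isobole level is
   $E = 50$. If the observed combination effect is significantly above 50%
   (one-sample t-test of the replicate effects against 50, two-sided,
   $\alpha = 0.05$) the analysis level is raised to
   $E^* = \lfloor \text{mean effect} \rfloor$: comparing a combination that
   achieves ~85% effect against the 50% isobole would understate the doses
   additivity requires. $E^*$ is capped at the highest effect level both
   single-agent curves reach, since intercepts are never extrapolated.
2. **Potency-ratio constancy.** $R_E = ED_E^A / ED_E^B$ is computed at 50%
   and at the maximum common effect level (defined as the minimum over the
   two curves of their maximum mean effect — the largest level at which both
   intercepts exist). Each paired bootstrap draw of each ratio is
   dichotomized as $>1$ vs $\le 1$ and the 2×2 table is tested with a
   likelihood-ratio G-test ($G = 2\sum O \ln(O/E)$, $\chi^2_1$, 0.5 added to
   all cells if an expected count is zero). A non-significant G licenses the
   linear isobole (the Tallarida condition). This operationalization — a
   test of proportions on dichotomized draws — is one defensible reading of
   applying a contingency-table G-test to two ratios; with thousands of
   draws it is sensitive to small proportion differences, so the flag is
   reported as context, and the synergy verdict never depends on it.
3. **Envelope and verdict.** For each paired resample the additivity segment
   is drawn between the resampled intercepts; the envelope is the pointwise
   2.5%/97.5% percentile band of the segment's B-axis value over a grid of
   A-axis doses. The combination is *synergistic* if it falls strictly below
   the lower envelope, *antagonistic-consistent* above the upper,
   *inconclusive* if $\gamma < 1$ but inside the band, and
   *additive-consistent* otherwise (ties count as additive). The object
   reports the assessment at $E = 50$ and at $E^*$; the headline verdict is
   the escalated one.

```{r pipeline}
truth <- assay_truth(seed = 7)
viab  <- simulate_plate(truth) |> normalize_viability()
nx    <- build_effect_curve(viab, "naloxone")
cis   <- build_effect_curve(viab, "cisplatin")
combo <- combination_observation(viab, "naloxone", "cisplatin", 10, 20)
fit   <- assess_synergy(nx, cis, combo, B = 2000, seed = 7)
fit
```

```{r isobologram, fig.width = 8, fig.height = 4}
autoplot(fit)
```

## What the synthetic generator emulates — and what it does not

`assay_truth()` / `simulate_plate()` exist so that every downstream stage is
testable against known ground truth. The defaults are the package's model of
a naloxone + cisplatin chemo-sensitization experiment:

* near-linear single-agent dose-effect curves with ED50s of 51 µM
  (naloxone) and 44 µM (cisplatin), saturating at 100%;
* a combination condition (naloxone 10 µM + cisplatin 20 µM) with a true
  effect of 85% — far above the ~32% a Loewe-additive combination of those
  doses would produce, i.e. a genuinely synergistic ground truth;
* n = 3 replicate wells per condition (in vitro assays in this field are
  typically run in triplicate), additive Gaussian noise of σ = 8 percentage
  points on viability, six control wells with a 5% CV.

Two generator choices deserve emphasis. First, the dose grids keep the
low-dose gradient of such experiments (naloxone from 0.1 µM, cisplatin from
5 µM) but extend both agents to 100 µM. A grid stopping at 40 µM would put
both ED50s *outside* the tested range of a near-linear curve, and the
escalated (~84%) level far beyond it; since the estimator refuses to
extrapolate, the simulated gradient must cover the levels being analyzed.
Second, the noise model can in principle push an absorbance negative when
the true effect is near 100%; simulated absorbances are floored at a tiny
positive value (an optical density cannot be negative), which slightly
truncates the upper tail of effects at the very top of the dose range —
levels above the analysis levels of interest.

The generator is additive-Gaussian on viability with independent wells. It
does not emulate edge effects, seeding-density gradients, plate-position
correlation, heteroscedastic noise, or measurement rounding. Passing tests
therefore demonstrate the *statistical machinery* — normalization,
interpolation, bootstrap calibration, classification — under the stated
noise model, not robustness to every artifact of real plates.

A consequence worth knowing: with σ = 8 and n = 3 the bootstrap ED intervals
are a few µM wide, much tighter than intervals obtained from sparser or
noisier real data. At E = 50 the default combination point (10, 20) then
falls below the lower envelope — the simulated evidence for synergy is
already decisive at 50% — whereas noisier designs typically yield the
two-stage picture (inconclusive at 50%, synergistic at the escalated level).
The test suite documents both regimes.

## In-vivo module

`simulate_growth()` draws a four-arm xenograft experiment: exponential
growth $V(t) = V_0 e^{rt}$ per animal, with group rates calibrated so that
over a six-week course naloxone reduces final mean volume by ~37% vs
control and adding naloxone to cisplatin reduces it by a further ~64% vs
cisplatin alone; 30 animals (8/8/7/7), baseline 100 mm³ (20% CV between
animals), caliper measurements twice a week with 5% CV noise per dimension.
Volumes use the standard caliper formula $V = \tfrac12 L W^2$; width larger
than length is treated as a transcription slip and swapped with a warning.

`compare_groups()` analyzes a single endpoint day (default: the last day
measured in all groups, nearest-day matched within ±1 day): pooled-variance
(Student) independent t-test for two groups — the pooled form is what
"independent t-test" denotes in the SPSS tradition these experiments are
analyzed in, with Welch available upstream via `stats::t.test()` if wanted —
and one-way ANOVA plus pairwise pooled t-tests with Bonferroni adjustment
over the number of pairs for more than two.

```{r invivo, fig.width = 7, fig.height = 4}
series <- simulate_growth(growth_truth(seed = 1)) |> tumor_series()
plot_tumor_growth(series)
glance(compare_groups(series))
```

## Problem sizes and limitations

The package's own validation uses B = 2000 bootstrap resamples for a single
assessment, 100 simulated experiments for the verdict-reproduction study,
500 repeats (B = 1000) for CI-coverage calibration, and 200 runs under an
additive ground truth for the false-positive study — sizes at which the
binomial error of the estimated rates is a small fraction of the margins
being checked.

Known limitations, by design:

* Only two-agent combinations and a single combination dose pair per
  assessment; no Chou–Talalay CI, Bliss, ZIP, or response-surface models —
  the claim evaluated is specifically the linear Loewe isobole.
* The linear fit is a screen, never the ED model; no 4PL/Hill fitting.
* Percentile bootstrap with n = 3 is honest but slightly anti-conservative;
  treat borderline envelope calls (points grazing the band) as inconclusive
  in spirit.
* The in-vivo module compares endpoints; it is not a longitudinal
  mixed-model analysis and applies no censoring for humane endpoints.
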
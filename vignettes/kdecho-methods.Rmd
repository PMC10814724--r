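---
title: "Coronary artery Z-scores in a murine Kawasaki disease model: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coronary artery Z-scores in a murine Kawasaki disease model: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdecho)
```

## The problem

Kawasaki disease (KD) is a pediatric systemic vasculitis whose most feared
complication is coronary artery dilatation and aneurysm. In the standard
mouse model, *Lactobacillus casei* cell wall extract (LCWE) injected
intraperitoneally into young C57BL/6 mice induces KD-like coronary
vasculitis. Histology — the traditional readout — requires sacrifice, so it
cannot follow the same animal over time. Echocardiography can, and the
clinical tool for deciding whether a coronary artery is abnormally large
for a given body size is the **Z-score**: the number of residual standard
deviations an observed vessel dimension lies from the value predicted by a
body-size-indexed normative model, with `Z > 3.0` (strictly) classified as
a coronary artery lesion (CAL).

`kdecho` implements that analysis end to end for the murine setting:
a day-0 normative model of coronary diameter indexed to the square root of
body surface area (BSA), Z-scoring and CAL classification, the derived
measurements used in dose-response and carotid-coronary association
analyses, and the cohort-level statistics. Because no per-animal
measurement table is publicly deposited for this model, the package also
ships a seeded synthetic-cohort generator that emulates the study design,
so every stage has realistic, reproducible test inputs.

## The normative model

For a measurement $y$ (coronary inner diameter by default) the day-0
(pre-treatment) reference model is

$$\hat y = \alpha + \beta \sqrt{\mathrm{BSA}}, \qquad
Z = \frac{y - \hat y}{s_\mathrm{res}},$$

fitted by ordinary least squares on the baseline cohort, with
$s_\mathrm{res} = \sqrt{\mathrm{SSE}/(n-2)}$. The degenerate `mean_sd` mode
sets $\beta = 0$, $\alpha$ to the baseline mean and $s_\mathrm{res}$ to the
baseline SD ($n-1$ denominator); this is the model that corresponds to
reference ranges reported as plain mean ± SD, and it is the *matched*
model whenever the true dependence of the measurement on body size is
absent — as it is under the generator's defaults, where the configured
√BSA slope is 0. The denominators are chosen so the training-set
invariants are exact: OLS residuals sum to zero and the sample SD of the
training Z-scores equals $\sqrt{(n-2)/(n-1)}$.

Two practical notes on mode choice:

* A fitted regression slope is pure noise when the true slope is zero, and
  it is *extrapolated* when post-baseline animals are scored: mice gain
  roughly 0.15 g/day, so day-21/28 animals sit ~0.5 cm beyond the day-0
  √BSA range, where slope noise inflates the false-positive rate of the
  `Z > 3` rule (from the nominal 0.135% to roughly 0.3% with an n = 38
  baseline). The package therefore defaults to regression mode for model
  fitting — the general tool — but its own reference analyses of the
  default synthetic cohorts use `mean_sd` mode, the matched model for a
  zero-slope baseline.
* Whether the original analysis regressed on √BSA or used the plain day-0
  mean/SD cannot be resolved from the published text (the printed norms,
  0.217 ± 0.028 mm for the inner and 0.472 ± 0.056 mm for the outer
  coronary diameter, carry no BSA term). Both modes are provided and
  neither is asserted to be "the" original computation.

BSA itself is never measured in mice; it is computed from body weight via
the Meeh allometric formula $\mathrm{BSA} = k\,W^{2/3}$ with the murine
coefficient $k = 9.8$ cm² g^(-2/3) (configurable). Any positive monotone
choice of $k$ only rescales the regressor, so nothing downstream depends
delicately on it.

## Derived measurements

* **Weight-adjusted dimension**: diameter / body weight × 100, with
  pseudo-units mm g⁻¹ × 100. These are kept in separate `_wadj` columns so
  they can never be silently mixed with raw mm.
* **Wall thickness, two definitions**: the caliper difference
  (outer − inner diameter) and the mean of the upper and lower wall
  ((upper + lower)/2, optionally weight-adjusted). Both appear in the
  vasculitis literature; they are distinct named quantities here
  (`*_wall_diff_mm` vs `*_wall_mean_mm`) and are never substituted for one
  another.

## The synthetic cohort generator

`generate_cohort()` emulates the study design: dose groups
control/low/medium/high (nominal 0/1/2/4 mg/kg — labels only, effects are
configured explicitly rather than derived from a dose-effect law), 9
animals per group measured at days 0, 7, 14, 21 and 28, and a day-0
normative cohort of 38 animals (baseline-only controls are appended when
the longitudinal animals provide fewer). Its statistical structure:

* **Baseline**: every measurement at day 0, and the control group at all
  days, is drawn from the configured normative distribution — coronary
  inner 0.217 ± 0.028 mm and outer 0.472 ± 0.056 mm by default; the
  carotid (outer 0.60 ± 0.05, inner 0.45 ± 0.04 mm), wall
  (0.075 ± 0.010 mm), aortic (outer 1.20 ± 0.10, inner 1.05 ± 0.09 mm) and
  ejection-fraction (65 ± 5%) norms are plausible values for healthy young
  C57BL/6 mice, chosen once and freely configurable.
* **Treatment effects** are additive mean shifts in units of the
  measurement's normative SD, per (group, day, measurement). The coronary
  inner defaults are +2 SD (day 7) rising to +5 SD (days 21-28) for high
  dose, +1 to +3 for medium, +0.5 to +1.5 for low (day-14 values
  interpolate); expressing effects in SD units makes the `Z > 3`
  percentages analytically checkable: with the medium-dose mean sitting at
  exactly +3 SD, half the animals exceed the cutoff; with the high-dose
  mean at +5 SD and an absolute noise SD of 0.04 mm, the exceedance
  probability is $\Phi((5 \cdot 0.028 - 3 \cdot 0.028)/0.04) = \Phi(1.4)
  \approx 91.9\%$ — reproducing the reported pattern of a lesion rate
  above 80% at high dose and near 50% at medium dose from day 21 onward,
  against 0% in controls. Ejection fraction drops
  1.5 SD in the high-dose group at day 21; carotid/aortic diameter and
  wall shifts are dose- and time-monotone package defaults in the reported
  directions (dilation, thickening, inner-lumen narrowing).
* **Within-animal structure**: treated animals at days > 0 share a latent
  severity factor with loading ρ = 0.6 across carotid outer diameter,
  carotid walls and coronary inner diameter, giving a population
  carotid-coronary correlation of ρ² = 0.36 — the basis of the
  carotid-as-window-on-coronary association. Controls and day-0 records
  carry no severity factor, so they are pure, independent normative draws
  and null comparisons stay exactly calibrated.
* **Anatomical coupling**: the inner and outer caliper of the same vessel
  are drawn with correlation 0.95. This leaves every marginal distribution
  untouched (so norm recovery is unaffected) but is essential for
  validity: with independent draws the default carotid norms would produce
  inner > outer in about 1% of rows, i.e. nearly every cohort would
  contain anatomically impossible records.
* **Body weight** is linear growth (20 ± 1.5 g baseline, 0.15 g/day) with
  0.3 g visit-level noise — reports of this model state only that the
  animals weigh about 20 g,
  so the growth parameters are package choices.
* **Reported baseline Ns**: with `published_ns = TRUE` the day-0
  coronary inner diameter is observed in only 18 of 38 animals and the
  outer in 37, emulating the published Ns by missingness; the default
  measures everything on all 38.

The reported design of nine animals per time point is ambiguous between
nine per dose group and nine in total; the generator defaults to 9 per
group per day (configurable), the reading under which every group × day
cell is analysable.

What the generator does **not** emulate: non-Gaussian measurement error,
operator or session effects, attrition/mortality, growth curvature, or any
pharmacokinetic dose-response law. Passing tests therefore demonstrate
that the *analysis machinery* is correct and calibrated under the assumed
Gaussian structure, not that real echo data satisfy those assumptions.

## Cohort statistics

Summaries are mean ± SEM per group × day cell (SEM undefined and reported
missing for single-value cells; empty cells are absent, never zero).
Group comparisons use the classical pooled-variance two-tailed Student's
t-test (df = n₁ + n₂ − 2), since that is the test named by the study;
Welch's form is available behind a flag. Associations use Pearson
correlation with the two-tailed t-transform p-value (df = n − 2); the
carotid-coronary association is evaluated at day 28 on weight-adjusted
values by default, with a raw-mm option. Missing values are dropped
cellwise/pairwise, never imputed, and no multiple-testing correction is
applied — matching the original analysis — but every report counts the
tests it ran. The dose-response table orders group means by dose rank per
day and flags whether they are non-decreasing.

## Pipeline and reproducibility

`run_pipeline()` chains generate → derive → fit-norms → score → analyze
with per-stage CSV handoffs (plus the model as full-precision JSON) so
every intermediate is independently inspectable, and writes a manifest
with the package version, seed, config hash and an md5 checksum per
output file. Stage outputs are written to `.partial` files and renamed on
success. All randomness flows from the single config seed: identical
config + seed reproduces identical checksums. Cohort CSVs are written
with 17 significant digits and parsed with a correctly-rounded decimal
reader, so the CSV round trip is bit-exact, missing values included.

## Problem sizes and numerical choices

The package's reference analyses and tests use problem sizes chosen to
make each stochastic claim sharp relative to its tolerance: 200 seeded
cohorts of n = 18 (inner) and n = 37 (outer) for norm recovery (grand-mean
standard error ≈ 0.0005 mm against a ±0.002 mm band); 100 seeded default
cohorts for the control-row false-positive check; 10,000 simulated
treated animals scored against a 20,000-animal day-0 baseline for the
high/medium `Z > 3` percentages (so threshold-estimation noise contributes
< 0.5 percentage points; with the default n = 38 baseline it alone would
contribute ~10 points for the medium dose); and 100,000 draws for the
null-calibration check of P(Z > 3) = Φ(−3) = 0.00135. Slope-recovery
fixtures use a widened weight spread and n = 40,000 because a realistic
murine weight SD of 1.5 g concentrates √BSA into ~0.2 cm, under which no
moderate-n fit can pin a 0.004 mm/cm slope to ±0.0005.

Degenerate inputs are errors, not silent fallbacks: constant baselines
(zero SD), zero √BSA variance in regression mode, fewer than 2 (mean/SD)
or 3 (regression) baseline values, all-missing Z-score sets, and
outer < inner calipers all fail with messages naming the field or row.
The CAL rule is strictly `Z > cutoff`: a Z of exactly 3.0 is normal.

## Known limitations

* Effects are mean shifts with Gaussian noise; real vasculitis produces
  skewed, occasionally bimodal dilation distributions.
* The latent severity factor is shared equally across coupled
  measurements; real carotid-coronary coupling is likely heteroscedastic
  and time-varying.
* The normative model is homoscedastic with a single residual SD; no
  LMS/percentile-curve modelling is attempted (the reference ranges are a
  single mean ± SD).
* Published real-data p-values (e.g. the day-28 carotid-coronary
  p = 0.004/0.005) depend on the real measurement error structure and are
  not reproducible from synthetic data; only directions and the Z > 3
  percentages are.
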
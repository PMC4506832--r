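---
title: "Modeling NRT thresholds along the cochlear tonotopic axis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling NRT thresholds along the cochlear tonotopic axis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrtmodel)
```

## What the package models

Neural Response Telemetry (NRT) thresholds — the minimal stimulation
current, in device current-level (C.L.) units, eliciting a detectable
electrically evoked compound action potential — vary across the 22
contacts of a cochlear-implant array and across subjects. The variation
mixes the tonotopic position of each contact with electrode physics
(impedance, distance to the modiolus, scalar placement), subject history
(etiology, ages, duration of profound deafness), and subject-level
offsets. The package separates these contributions in three stages:
a geometric mapping from CT measurements to characteristic neuron
frequency (CNF), a random-intercept linear mixed model with a cubic
spline in frequency, and a residue profile along the tonotopic axis.
A calibrated synthetic-cohort generator stands in for patient-level data,
which are not publicly deposited, and makes every stage testable by
parameter recovery.

## Geometry: from CT measurements to characteristic frequency

Cochlear duct length is estimated from the large diameter $A$ of the
basal turn by the spiral arc-length relation

$$\mathrm{CDL} = 2.62\,A\,\ln(1 + \theta/235),$$

which at the full coil angle $\theta = 990^\circ$ (2.75 turns) gives
$\mathrm{CDL} = 4.3259\,A$. The same relation evaluated at the insertion
angle $\theta_{e1}$ of the most apical contact gives that contact's arc
distance from the round window; subtracting the manufacturer arc
spacings $Y_n$ places the remaining contacts, and dividing by CDL yields
relative organ-of-Corti positions $x_{en} \in [0,1]$ measured from the
base. Positions are then mapped to relative spiral-ganglion positions
and finally to frequency by the Greenwood function with human
parameters,

$$CF(z') = 165.4\,(10^{2.1 z'} - 0.88),$$

where $z'$ is measured **from the apex**. Since $x_{en}$ is a from-base
fraction, the package evaluates $CF(1 - z_{en})$: deeper insertion means
lower characteristic frequency. Two conventions deserve note:

* **Logarithm base.** The arc-length relation is used with the natural
  logarithm throughout; the 4.3259 constant is only consistent with
  $\ln$, not $\log_{10}$.
* **Greenwood parenthesization.** The standard Greenwood form
  $A(10^{ax} - k)$ is used, with $k = 0.88$ inside the parentheses; the
  apex then maps to 19.85 Hz and the base to 20677 Hz.

**The OC→SG map is pluggable.** Published fits exist for the
correspondence between organ-of-Corti and spiral-ganglion relative
position, but the closed form
$Z = 100\,[1 + (23/x - x/0.0099 + 0.76)^2]^{-1}$ sometimes quoted for it
is not monotone over $(0,1]$ (it spikes near $x \approx 0.48$), which
makes it unusable as a coordinate transform. `oc_to_sg()` therefore
ships that form for reference (`variant = "printed"`) but defaults to
the identity (`variant = "identity"`), so downstream statistics are
well defined. Substituting a proper monotone fit is a one-line change
at the pipeline level.

**Array registry.** Contact spacings per array type (perimodiolar PMA,
straight SA, slim-straight SSA) are manufacturer data not available
here; the registry ships uniform placeholder layouts over nominal
organ-of-Corti-path spans (PMA 14 mm, SA 15 mm, SSA 16 mm), chosen to be
geometrically consistent with the per-array insertion-angle
distributions over the observed range of cochlear sizes. Users can
override them with a YAML file (see `?array_registry` and
`inst/extdata/arrays.yaml`).

## The threshold model

For subject $i$, electrode $j$:

$$y_{ij} = s(CNF_{ij}) + \beta_1\,\mathrm{imp}^2_{ij} +
\beta_2\,\mathrm{dist}^2_{ij} + \beta_3\,1[\mathrm{ST}_i] +
\mathrm{array}_i + \mathrm{etiology}_i + \beta_4\,\mathrm{age}_i +
\beta_5\,\mathrm{dur}_i + b_i + \epsilon_{ij},$$

with $b_i \sim N(0, \sigma_b^2)$ and
$\epsilon_{ij} \sim N(0, \sigma_e^2)$. The spline $s$ uses the
truncated-power cubic basis
$\{f, f^2, f^3, (f-5000)^3_+, (f-10000)^3_+\}$ on the raw Hz scale —
knots are specified in Hz, and the truncated-power basis maps one-to-one
onto "piecewise cubic polynomial with two knots", which keeps every
coefficient interpretable. B-splines would be numerically nicer but are
not needed: the fitter rescales all design columns to unit
root-mean-square internally (cubic columns reach $10^{12}$) and
back-transforms estimates and covariances exactly, which keeps the
normal equations well conditioned without changing the model. Frequency
axes are displayed on a log scale only; the basis itself is in raw Hz.

**Estimation.** REML, with the variance ratio
$\lambda = \sigma_b^2/\sigma_e^2$ profiled out: for fixed $\lambda$ the
fixed effects are generalized least squares and $\hat\sigma_e^2$ is
closed-form, so the whole problem is a one-dimensional maximization over
$\log\lambda$ (derivative-free search on the bracket $[10^{-8}, 10^8]$,
tolerance $10^{-8}$ on $\log\lambda$). Because the random structure is a
single intercept per subject, $V_0^{-1}$ reduces to per-group sweeps
(Sherman–Morrison on the all-ones block) and each profile evaluation is
$O(np + p^3)$. The boundary $\hat\sigma_b^2 = 0$ is evaluated explicitly
and reported when it wins — it is a legitimate estimate, not an error —
in which case the fit coincides with OLS. Degenerate grouping (one
observation per subject) falls back to OLS with a warning, since the two
variance components are not separable. The restricted log-likelihood
follows the standard definition (it matches `lme4` and `nlme` to
machine precision on fixtures, which the test suite verifies against a
brute-force grid-search oracle as well).

**Inference.** Wald tests with the normal reference: $z = \hat\beta/SE$,
two-sided $p$. No degrees-of-freedom correction (Satterthwaite,
Kenward–Roger) is applied; with ~31 subjects and subject-level
covariates this is mildly anticonservative (the suite measures ~6.6%
empirical size at nominal 5% over 200 null replicates, inside the
tolerance band). Confidence bands for the frequency curve are
population-level: $x'\hat\beta \pm z_{0.975}\sqrt{x'V x}$ with $V$ the
fixed-effect covariance — they reflect uncertainty in the mean curve,
not prediction intervals for new electrodes.

**BIC and functional form.** `model_bic()` reports
$-2\ell_{REML} + k\ln N$ with $k$ = fixed effects + 2 variance
components and $N$ the number of observations; model selection uses the
smaller-is-better convention. One subtlety: restricted likelihoods are
defined relative to the fixed-effect design and are **not comparable**
across models with different fixed effects (the $\log|X'V^{-1}X|$ term
scales with the basis columns). `select_functional_form()` — which
compares linear, quadratic, cubic and spline shapes — therefore refits
candidates by full maximum likelihood and compares ML-BIC, the same
convention `lme4` applies when comparing fixed-effect structures.

**BLUPs and residues.** Random intercepts are predicted by the standard
shrinkage formula
$\hat b_i = \frac{\sigma_b^2 n_i}{\sigma_e^2 + n_i \sigma_b^2}\bar r_i$
($\bar r_i$ = subject mean marginal residual). Residue profiling bins
the *conditional* residuals (observed − fixed-effect prediction −
BLUP) into log-spaced CNF bins and flags bins whose mean exceeds twice
its standard error: since the BLUP removes subject offsets, a flagged
bin indicates thresholds systematically above or below the model in a
frequency region — a candidate signature of abnormal local neuron
activation. The choice of conditional rather than marginal residuals is
deliberate: the residue is meant as a subject-independent proxy of
neuron function.

## The synthetic cohort generator

`generate_cohort()` draws, per subject: array type (27:2:2 mix of
PMA:SA:SSA), cochlear duct length $N(35.05, 4.68^2)$ mm clipped to the
observed [26.38, 43.42] range (diameter $A$ = CDL/4.3259), insertion
angle by array type (PMA $346\pm22^\circ$, SA $312\pm46^\circ$, SSA
$335\pm35^\circ$), whole-array scala-vestibuli translocation of PMA
arrays with probability 0.3548, etiology with frequencies 11/8/4/4/3/1
(progressive SNHL, genetic, autoimmune, ototoxic, otosclerosis, viral),
and ages built compositionally: age of profound deafness
$N(40.26, 23.20^2)$ clipped to [0, 80], duration $N(5.30, 5.32^2)$
clipped to [1, 30], age at implantation their sum, age at test = age at
implantation + U(0.5, 6) years (recordings are made at least 6 months
post-implantation; the demographic correlation structure beyond this
composition is an assumption, as joint distributions are not reported).
Per electrode: impedance = 8.71 + subject shift $N(0, 2.05^2)$ +
electrode noise $N(0, 1.60^2)$, clipped to [2.86, 19.07] kΩ; distance to
the modiolus = subject mean $N(0.6, 0.25^2)$ + noise $N(0, 0.2^2)$,
clipped to [0.05, 2.5] mm — a realistic CT-derived range, chosen here
since distance distributions are not reported.

Thresholds are assembled from the model above with the multivariate
adjusted estimates as ground truth (impedance² −0.11, distance² +2.20,
scala tympani −8.50, ototoxic −24.33, age at test +0.29, duration
−0.17, array PMA −5.94 / SA +13.43 vs slim straight, etc.), rounded to
integer current levels and clipped to the 0–255 device range.

**Insertion-angle feasibility.** Angles are drawn from the stated
normals untruncated (they may exceed 360°; only $0 < \theta \le 990$ is
enforced). Truncating at the observed maximum of 360° would bias the
mixture mean ~3.5° below the observed 343°. When a drawn (CDL, angle)
pair cannot contain the full array — the arc of electrode 1 shorter than
the contact span, about 3–5% of draws in small cochleae — the angle is
raised to the minimum geometrically consistent value rather than
resampled; the residual effect on the mean insertion angle is +0.9° at
n = 40000.

**The double-bump frequency profile.** `default_double_bump_shape()`
encodes the characteristic threshold-frequency curve: a steep rise from
500 to 3000 Hz, a dip in the 4000–5000 Hz region, a dome peaking at
10000 Hz, over an ascending base-to-apex trend. The coefficients are
derived in closed form on the kHz scale: the cubic below the first knot
has stationary points at exactly 3 kHz (maximum) and 5 kHz (minimum);
the first truncated term cancels the slope at 10 kHz, making it the dome
peak; the second tempers the decline above 10 kHz. The amplitude
constant (0.35 C.L./kHz³) sets the 500→3000 Hz rise to ≈12 C.L., a
realistic threshold swing across an array.

**Calibration.** The covariates and the frequency profile already
explain part of the NRT spread, so the free components — $\sigma_e$,
$\sigma_b$ and the intercept — are back-solved, not set:
`calibrate_generator()` measures the covariate-explained within- and
between-subject SDs on a large noise-free cohort and solves

$$\sigma_e^2 = W^2 - w_0^2, \qquad
\sigma_b^2 = B^2 - b_0^2 - \sigma_e^2/n_e,$$

targeting the observed grand mean 169.68 C.L., within-subject SD 13.66
and between-subject SD 18.60 (the $\sigma_e^2/n_e$ term arises because
the between-subject SD is computed on subject means, which retain
$1/n_e$ of the residual variance). Two refinement iterations on
full-noise cohorts absorb the small nonlinearities from integer
rounding and range clipping. The shipped defaults
($\sigma_e = 12.99$, $\sigma_b = 13.28$, intercept 161.64 C.L.) were
produced by this procedure at 4000 subjects and are frozen in
`generator_config()`; the calibration function remains exported and
tested.

**Within-subject SD.** `summarize_cohort()` uses the pooled one-way
ANOVA estimator
$\sqrt{\sum_i\sum_j (y_{ij}-\bar y_i)^2 / \sum_i (n_i - 1)}$
(the Bland–Altman repeated-measurements form), the between-subject SD of
subject means, and grand means as means of subject means.

## What the generator does and does not emulate

It reproduces: the repeated-measures variance partition (within 13.66 /
between 18.60 C.L.), the marginal covariate distributions and mixes
reported for the study population, whole-array scalar placement, the
adjusted effect structure, and device quantization. It does **not**
emulate: partial (within-array) translocations, correlation between
impedance and scalar position or insertion depth, measurement error in
the CT-derived geometry, per-electrode failure/deactivation (every
subject contributes all 22 electrodes, while real cohorts have inactive
electrodes), or any dependence of the residual on frequency beyond the
spline. Parameter-recovery results therefore validate the estimation
machinery under the model's own assumptions; they do not certify
robustness to the misspecifications above.

## Problem sizes and reproducibility

The shipped defaults keep every computation interactive: calibration
cohorts of 4000 subjects (a few seconds), summary checks at 500
subjects, parameter recovery over 20 replicates of the study-sized
31×22 design, and a 200-replicate null simulation for the empirical
size of the Wald test. Generation, fitting and reporting are pure
functions of (configuration, seed): rerunning any stage with the same
inputs reproduces its output exactly, which the suite asserts.

## Known limitations

* The Wald normal reference is anticonservative at 31 subjects for
  subject-level covariates; with ~10 translocated subjects the scalar
  effect is estimated with SE ≈ 5–7 C.L. per cohort, so single-cohort
  scalar inferences are weak (recovery across replicates is unbiased).
* The identity OC→SG default understates the basal compression of the
  spiral-ganglion map; CNF values toward the base are therefore upper
  bounds.
* `p_sv_translocation` applies to whole arrays; partial translocation
  is out of scope.
* Raw p-values throughout; no multiple-testing correction is applied
  (α = 0.05, two-tailed), matching the original analysis convention.
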
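# nrtmodel

Modeling of auditory-neuron response thresholds in cochlear-implant
recipients.

## The problem

Cochlear implants stimulate spiral-ganglion neurons directly; the minimal
current eliciting a detectable electrically evoked compound action
potential — the NRT threshold, in device current-level (C.L.) units — is a
window on the quality of the electrode–neuron interface. But thresholds
recorded across the 22 contacts of an array confound several things: where
each contact actually sits along the tonotopic axis (insertion depth and
cochlear size vary widely between subjects), its impedance, its distance
to the modiolus, whether the array slipped from the scala tympani (ST)
into the scala vestibuli (SV), etiology and history of deafness, and
subject-level offsets. `nrtmodel` is a toolkit for disentangling them,
written for hearing scientists and audiology groups analyzing per-electrode
e-CAP threshold tables.

Two pieces make up the core:

**Tonotopic mapping.** Cochlear duct length is estimated from the CT-measured
large diameter *A* of the basal turn by the spiral arc-length relation
*CDL = 2.62 A* ln(1 + θ/235) (= 4.3259 *A* at the full θ = 990° coil).
The most apical electrode's insertion angle gives its arc position; the
manufacturer contact spacings place the rest; and the Greenwood
place–frequency function *CF(z) = 165.4 (10^{2.1 z} − 0.88)* converts each
relative spiral-ganglion position (measured from the apex) into the
characteristic neuron frequency (CNF) the contact stimulates.

**Threshold model.** NRT thresholds are modeled as

> NRT_ij = s(CNF_ij) + β·imp²_ij + β·dist²_ij + β·1[ST_i] + array_i +
> etiology_i + β·age_i + β·dur_i + b_i + ε_ij

a linear mixed model with a subject random intercept *b_i* ~ N(0, σ_b²),
where *s(·)* is a truncated-power cubic spline in frequency with knots at
5000 and 10000 Hz. Estimation is restricted maximum likelihood with the
variance ratio σ_b²/σ_e² profiled out; fixed effects get Wald tests, the
frequency–response curve gets a 95 % confidence band, and BIC compares
candidate functional forms. Conditional residuals ("residues"), binned
along the CNF axis, serve as a proxy for local auditory-neuron function.

Because per-electrode patient tables of this kind are not publicly
deposited, the package ships a calibrated synthetic cohort generator
(`generate_cohort()`) that reproduces the covariate structure of a
31-subject, 22-electrode implanted population — impedances 8.71 ± 2.6 kΩ,
duct lengths 35.05 ± 4.68 mm, per-array insertion angles, 35.48 %
perimodiolar SV translocation, etiology mix — with the published adjusted
effect estimates as ground truth, so every stage is testable by parameter
recovery.

## Worked example

```r
library(nrtmodel)

cohort <- generate_cohort(generator_config(seed = 42))
s <- summarize_cohort(cohort)
fit <- run_multivariate(cohort)   # spline(CNF) + covariates + (1 | subject)
```

The cohort reproduces the repeated-measurement structure of a real
population:

```
mean NRT 170.03 C.L., within-subject SD 13.56, between-subject SD 18.08
```

and the fitted model recovers the generating effects (truth: impedance²
−0.11 C.L./kΩ², scala tympani −8.50 C.L.):

```
Random-intercept linear mixed model (REML)
  groups:  31 (subject_id), obs: 682
  sigma_b = 15.25, sigma_e = 12.98, REML logLik = -2833, BIC = 5791
  ...
  I(impedance_kohm^2)  -0.0795
  scalarST             -6.7155
```

```r
wald_test(fit$fit, "scalarST")
#> scala tympani effect: -6.72 C.L. (SE 7.40), z = -0.91, p = 0.364
```

(single 31-subject cohorts estimate the subject-level scalar effect
noisily — `recovery_experiment()` shows the estimator is centered on the
truth across replicates). The population-level frequency curve with its
95 % band shows the characteristic double-bump shape rising to a peak near
10 kHz:

```r
frequency_curve(fit$fit, cohort, n_grid = 5)
#>     cnf_hz    fit    lwr    upr
#> 1  1067.35 174.20 152.55 195.85
#> 2  2228.94 179.11 157.77 200.44
#> 3  4654.68 179.16 157.82 200.50
#> 4  9720.33 188.23 166.78 209.68
#> 5 20298.87 165.73 136.62 194.84
```

`residue_profile(fit$fit, cohort)` then bins the conditional residuals
along the CNF axis and flags bins whose mean exceeds twice its standard
error — candidate regions of abnormal neuron activation.

See `vignettes/nrt-threshold-modeling.Rmd` for the full account of the
model, the generator's calibration, and the design choices.

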
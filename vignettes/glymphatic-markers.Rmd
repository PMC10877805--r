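---
title: "Glymphatic MRI markers: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glymphatic MRI markers: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glymph)
```

## The problem this package addresses

Clearance of interstitial solutes from the brain runs along perivascular
spaces (the glymphatic pathway). Three MRI-accessible quantities are commonly
used as in-vivo proxies of this system: the DTI-ALPS index (diffusivity along
the perivascular axis at the lateral-ventricle body), the visual grade of
enlarged perivascular spaces (PVS) in basal ganglia and white matter, and the
head-size-normalized choroid plexus volume. In AD-continuum cohorts these
markers are analyzed against amyloid burden (PET SUVR) and white matter
hyperintensity (WMH) burden, and against cognitive composites, with
covariate-adjusted partial correlations, ordinal models for the grades, and
bootstrap mediation. `glymph` implements this chain end to end, plus a
synthetic-data module so that every stage is testable at desk scale without
cohort imaging data.

## The ALPS index

At the level of the body of the lateral ventricle, projection fibers run
inferior-superior (z), association fibers anterior-posterior (y), and the
deep medullary veins — and with them the perivascular spaces — left-right
(x). Water mobility along x in these two fiber systems is therefore
perivascular-dominated, while Dyy in the projection area and Dzz in the
association area are fiber-perpendicular references. The one-sided index is

$$\mathrm{ALPS} = \frac{D_{xx}^{proj} + D_{xx}^{assoc}}
                        {D_{yy}^{proj} + D_{zz}^{assoc}},$$

evaluated on mean diffusivities inside 6-mm spheres, and the reported value
is the mean of the left and right indices. Isotropic diffusion gives exactly
1; values well above 1 indicate preserved perivascular diffusivity.

Design choices in the engine:

* **ROI centers are configuration, not constants.** Studies place the
  spheres manually on fiber-direction maps and publish no coordinates. We
  ship defaults — projection (±26, −22, 26) mm, association (±36, −22, 26)
  mm on the 2-mm template grid — as an overridable table
  (`default_roi_set()`, YAML I/O).
* **Voxel membership is center-in-sphere.** A voxel belongs to an ROI when
  its center lies within `diameter/2` of the sphere center. This rule is
  deterministic and testable by enumeration (a 6-mm sphere centered on a
  voxel center of the 2-mm grid contains exactly 19 voxels).
* **The shift battery counts template voxels.** The five-position battery
  (±2, ±1, 0) displaces the centers along y by whole 2-mm voxels; the middle
  placement is the default analysis value, the battery quantifies
  anterior-posterior placement sensitivity.
* **QC is a flag, not a gate.** Each ROI records an anisotropy proxy from
  the three diagonal diffusivities; near-isotropic content (e.g. a sphere in
  CSF) is flagged, never silently corrected. Scans with a chin-up position
  (AC-PC angle > 20°) are excluded at the cohort level.

## Tensor phantoms

`generate_tensor_phantom()` builds axis-aligned homogeneous slabs (projection
fibers along z, association fibers along y) in which the perpendicular
diffusivities are `d_perp` and the x-diffusivity is `alps_truth * d_perp`, on
an isotropic background. Slabs rather than curved tracts suffice because the
index only reads ROI-mean diffusivities; homogeneity makes the noiseless
index equal `alps_truth` to machine precision at every shift, which is the
property the engine's exactness tests use. Optional Gaussian noise on every
voxel provides an unbiasedness check across seeds. Phantoms do not emulate
real DWI artifacts (motion, eddy currents, Gibbs ringing, registration
error), so passing phantom tests validates the geometry and arithmetic of the
engine, not robustness to acquisition defects.

## Marker derivations

* WMH burden is `log10` of lesion volume in ml, centering a ~1 ml reference
  group near 0. The base is configurable; zero volumes require an explicit
  floor (default suggestion 0.01 ml) rather than being silently clamped.
* Normalized choroid plexus volume is the mm³/ml volume ratio (scale ~1 for
  typical adults), invariant to consistent unit rescaling.
* PVS grades follow the printed counting rules. Two tie conventions are not
  printed anywhere and were fixed once: basal-ganglia "5~10" is inclusive on
  both ends (grade 3 starts strictly above 10), and a white-matter section
  with exactly 10 PVS stays grade 2 ("no more than 10 in a single section").
* Amyloid positivity is strict SUVR > 1.11; group assignment is CN−
  (cognitively normal, amyloid-negative, Fazekas < 2), CN+/MCI+/AD+
  (amyloid-positive with matching diagnosis), everything else excluded with
  a reason. QC exclusions: GDS ≥ 5, chin-up, PET–DTI interval ≥ 12 months.
* The vascular risk score is the count of the five recorded flags (0–5); the
  underlying studies reference a supplementary definition that is not
  printed, so a transparent count is used.

## The statistical chain

**W-scores.** For each marker a least-squares model on the CN− reference
(default covariates age, sex, TIV) yields
`W = (observed − predicted) / residual SD` with the residual SD on
`n − p − 1` degrees of freedom. ALPS is sign-flipped before scoring so that
higher W means more abnormal for every marker. The reference covariate set
follows the marker-association model 1 because the supplementary W-score
definition is not printed; it is an explicit argument.

**Partial correlations.** Product-moment partial correlation is the
correlation of OLS residuals, p from t on `n − k − 2` df. The Spearman
variant ranks only x and y (covariates stay numeric), matching common
implementations; this is a documented switch rather than a hidden choice.
Pearson is used for ALPS/choroid analyses, Spearman for the ordinal PVS
grades. Model 1 adjusts age, sex, TIV; model 2 adds APOE ε4 carriage;
marker–cognition models adjust age, sex, education, APOE.

**Ordinal PVS models.** A proportional-odds cumulative-logit model
(maximum likelihood via `MASS::polr`) regresses each grade on both exposures
jointly plus covariates, with Wald p-values. The reference analyses used a
mixed-model routine whose grouping structure is unprinted; this package's
cohorts have no site structure, so no random effects are fitted — a
deliberate simplification, stated here rather than imitated blindly.
Non-convergence and single-grade outcomes are flagged or raised, never
silent.

**FDR.** Benjamini–Hochberg step-up via `stats::p.adjust`, cross-checked in
the tests against a definitional brute-force implementation on all orderings
of small p-value sets.

**Continuum curves.** W-scores are smoothed against the ordered stage axis
(CN− = 0 … AD+ = 3) with a cubic smoothing spline (df = 3) and a seeded
within-stage bootstrap band. The x axis is an ordinal construct — the
original report does not define one — so the curve is an interpolation
device for stage means, not a time course.

**Mediation.** Product-of-coefficients mediation with case-resampling
bootstrap: `a` from `m ~ x + C`, `b` and `c'` from `y ~ x + m + C`, total
`c` from `y ~ x + C`; indirect `= a·b`, and `c = c' + a·b` holds exactly for
OLS. Choices made where the source is silent:

* **Percentile CI** at 95% (BCa behind a flag) — "95% bootstrap CI" admits
  several readings; percentile is the simplest faithful one.
* **Bootstrap p** `= 2·min(P(θ* ≤ 0), P(θ* ≥ 0))` since only FDR-p values
  are printed, never the raw p definition.
* **Single-exposure models** (the other exposure omitted), matching the
  published path diagrams; a joint-exposure analysis is possible by passing
  the other exposure as a covariate.
* **Variables z-scored** before fitting so indirect effects are on the
  standardized β scale; covariates follow the printed list (age, sex, APOE —
  deliberately without TIV or education).
* FDR is applied across each mediator's 2-exposure × 4-domain battery.

## The cohort generator

`generate_cohort()` draws from a linear structural-equation model in which
every analysis above is correctly specified:

1. Covariates: age ~ N(75.2, 8.4²) years, male sex ~ Bernoulli(0.38),
   TIV ~ N(1470, 160²) ml, education ~ N(16.1, 2.4²) years,
   APOE ε4 ~ Bernoulli(0.5) — frequencies chosen once to approximate the
   cohort the generator mirrors.
2. Exposures: SUVR and WMH burden are group-mixture draws (per-group means
   and SDs from the mirrored cohort's demographic table; 48/26/19 across
   CN+/MCI+/AD+, 40 CN− references) standardized by the analytic
   amyloid-positive mixture moments.
3. Mediators and cognition are linear in the standardized exposures with
   independent Gaussian residuals; **path coefficients are back-solved from
   the requested partial correlations** given the implied exposure
   correlation, so the generative effect sizes are the published
   covariate-adjusted partial correlations themselves (WMH–ALPS −0.458,
   Aβ–ALPS −0.249, WMH–choroid 0.294, Aβ–choroid 0.223; ALPS and choroid
   versus the four cognitive domains per the published correlation table).
   Direct exposure→cognition effects default to −0.1 and the mediator paths
   absorb the rest. Infeasible combinations (non-positive residual variance)
   are rejected as a non-invertible implied covariance.
4. Covariate effects load on the observed scale with the structural part
   scaled by `sqrt(1 − Σγ²)`. TIV loads on nothing (ALPS is a ratio; choroid
   is already TIV-normalized) and education only on cognition, so the
   injected partial correlations hold exactly under **both** adjustment sets
   used by the analyses. Age and sex load everywhere, APOE on amyloid and
   cognition.
5. PVS grades come from latent cumulative-logit models (logistic residuals —
   chosen over probit so the fitted proportional-odds model is correctly
   specified) with slopes per standardized exposure and fixed increasing
   cutpoints.
6. Observed SUVR is clamped to respect each group's amyloid status at the
   1.11 cutoff while the *latent* amyloid variable drives the paths; this
   leaves WMH- and mediator-related correlations untouched and attenuates
   amyloid-involved correlations by ~2–4% at most.

Two consequences worth knowing: the group-mean structure induces a small
(~0.04) WMH–amyloid correlation even when all paths are zero (a strict null
requires equal group means), and group differences in ALPS/choroid/cognition
emerge through the paths rather than being set per group, so the generator
reproduces effect sizes, not every marginal group mean.

What the generator does **not** emulate: site/scanner heterogeneity, missing
data, non-Gaussian marker distributions, measurement error in SUVR or TIV,
and selection effects. Passing recovery tests therefore shows the estimators
are correct under the stated model, not that real-data estimates are
unbiased.

## Problem sizes and numerical conventions

The test suite exercises: phantom exactness on a 48×56×48 2-mm grid
(machine-precision agreement, tolerance 1e−10); oracle equivalence of
partial correlation (1e−12), BH-FDR (exact) and the mediation identity
(1e−10); effect-size recovery as means over 200 simulated cohorts of n = 93
(tolerance ±0.05); bootstrap coverage at n = 500 over 500 simulations with
B = 500 (92–98% at nominal 95%); ordinal slope recovery at n = 5000
(±0.15); and exhaustive PVS truth tables. The acceptance script averages
500 cohorts of n = 93. Confirmatory mediation uses B = 5000 replicates;
simulation studies use B = 100–500, which is ample for point-estimate means
and adequate for CI calibration checks.

Degenerate inputs are errors, not warnings: zero-variance residuals,
rank-deficient designs, empty ROI masks, denominators ≤ 0 in the ALPS ratio,
single-grade ordinal outcomes, out-of-range p-values. All randomness is
seed-driven, and every generator and bootstrap restores the caller's RNG
state.

## Known limitations

* ROI placement is fixed in template space; per-subject manual correction on
  fiber-direction maps (standard in applied work) is out of scope, partially
  compensated by the anisotropy QC flag and the shift battery.
* The ordinal model omits random effects; multi-site grades would need a
  mixed cumulative-link model.
* The continuum curve treats stage as equally spaced.
* Bootstrap mediation assumes linearity and no exposure–mediator
  interaction; no sensitivity analysis for sequential ignorability is
  provided.
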
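# glymph

Glymphatic MRI markers and their statistical chain: the DTI-ALPS
perivascular diffusivity index, CSVD/amyloid/glymphatic marker derivation,
and the cohort statistics (W-scores, partial correlations, ordinal PVS
models, FDR, bootstrap mediation) used to link amyloid and white-matter
lesion burden to glymphatic function and cognition along the AD continuum.

The package is aimed at neuroimaging analysts who have per-subject
diffusivity maps (Dxx, Dyy, Dzz) registered to a 2-mm template and a cohort
table of markers, covariates and cognitive composites — and at methodologists
who want the full chain exercisable without any cohort data, via the built-in
tensor phantoms and structural-equation cohort generator.

## The core quantities

**DTI-ALPS.** At the lateral-ventricle body, perivascular spaces along the
deep medullary veins run left–right (x), projection fibers run along z and
association fibers along y. With 6-mm spherical ROIs in each fiber area the
one-sided index is

    ALPS = (Dxx_proj + Dxx_assoc) / (Dyy_proj + Dzz_assoc)

and the analysis value is the left/right average, computed at five
anterior–posterior ROI placements (±2, ±1, 0 voxels; the middle placement is
the default). Isotropic diffusion gives exactly 1.

**Markers.** log10 WMH volume (ml) as CSVD burden; choroid plexus volume
normalized by TIV (mm³/ml); PVS visual grades 1–4 in basal ganglia and white
matter from counting rules; amyloid positivity at SUVR > 1.11; AD-continuum
groups CN−/CN+/MCI+/AD+ with QC exclusions (GDS ≥ 5, chin-up > 20°, PET–DTI
interval ≥ 12 months).

**Statistics.** W-scores against the CN− reference (ALPS sign-flipped so
higher = more abnormal); covariate-adjusted partial correlations (Pearson
for continuous markers, Spearman for grades; model 1: age/sex/TIV, model 2:
+APOE); proportional-odds cumulative-logit models for PVS grades;
Benjamini–Hochberg FDR; product-of-coefficients mediation
(indirect = a·b, percentile bootstrap CI, 5000 replicates by default) with
per-mediator FDR across the 2-exposure × 4-domain battery.

See `vignette("glymphatic-markers")` for the models, assumptions and design
choices.

## Worked example

```r
library(glymph)

# a tensor phantom whose ground-truth index is 1.355
ph <- generate_tensor_phantom(phantom_spec(alps_truth = 1.355))
alps_battery(ph$volume)
#>   y_shift  left right average
#> 1      -2 1.355 1.355   1.355
#> 2      -1 1.355 1.355   1.355
#> 3       0 1.355 1.355   1.355
#> 4       1 1.355 1.355   1.355
#> 5       2 1.355 1.355   1.355
```

All five ROI placements recover the ground truth exactly because the phantom
slabs are homogeneous — the engine's arithmetic and geometry are exact.

```r
# a synthetic AD-continuum cohort: 40 CN- references + 93 amyloid-positive
coh <- generate_cohort(default_sem_params(seed = 1))
table(coh$group)
#>  AD+  CN-  CN+ MCI+
#>   19   40   48   26

pos <- subset(coh, group != "CN-")
partial_corr(pos, "wmh_burden", "alps",
             c("age", "sex", "tiv", "apoe4_carrier"))
#> <partial_corr> wmh_burden ~ alps | age, sex, tiv, apoe4_carrier (pearson):
#>   r = -0.465, p = 4.407e-06, n = 93
```

The generator injected a WMH–ALPS partial correlation of −0.458; this
cohort's estimate is −0.465 (sampling error at n = 93 is about ±0.1).

```r
mediate(pos, "wmh_burden", "alps", "memory", n_boot = 5000, seed = 1)
#> <mediation_result> wmh_burden -> alps -> memory | age, sex, apoe4_carrier
#>   a = -0.456, b = 0.550
#>   indirect = -0.251 [-0.434, -0.113], p = 0
#>   direct = -0.009, total = -0.260 (n = 93, B = 5000)
```

Higher WMH burden predicts lower ALPS (a < 0), lower ALPS predicts worse
memory (b > 0), and the indirect effect a·b is clearly negative: ALPS
mediates the WMH–memory association in this cohort. `total = direct +
indirect` holds exactly.

The same chain is available from the shell:

```sh
Rscript inst/cli/glymph.R simulate --out-dir out --seed 1
Rscript inst/cli/glymph.R analyze  --out-dir out --cohort out/cohort.csv
Rscript inst/cli/glymph.R alps     --out-dir out \
    --dxx s_Dxx.nii --dyy s_Dyy.nii --dzz s_Dzz.nii
```

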
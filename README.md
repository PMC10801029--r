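# fwtract

Free-water-corrected deterministic tractography for clinically feasible
single-shell diffusion tensor imaging (DTI), with the survey-reliability
statistics used to evaluate it against expert raters.

## Why

Vasogenic edema around brain tumors elevates the free-water content of
peritumoral tissue. In single-shell DTI the extra isotropic signal depresses
fractional anisotropy (FA), so deterministic tractography — which stops when
FA falls below a threshold — loses real white-matter tracts exactly where a
surgical plan needs them (false negatives at the brain–tumor interface).

`fwtract` separates the two signal compartments per voxel,

    S_i = S0 [ (1 - f) exp(-b_i g_i' D_t g_i) + f exp(-b_i d_w) ],

estimating the free-water fraction `f` and the tissue tensor `D_t`
(`d_w = 3.0e-3 mm^2/s`, free water at body temperature) from an
MD-interpolated initialization with a tissue-MD box and a noise-scaled prior
anchor — the constraints that make the single-shell problem identifiable.
Tracking the tissue compartment restores the edematous bundle; every
streamline point is then stamped with its local free-water value, and an
adaptive correction slider (0 % = uncorrected appearance, 100 % = fully
corrected, cutoff `tau` linear in between, pure CSF never shown) dynamically
recovers the sub-threshold segments.

The package also ships a digital DWI phantom (bundle + lesion + edematous
free-water shell + CSF, two-compartment forward model, Rician noise) so the
whole chain is testable without patient data, and the ordinal
agreement statistics used in rater studies: ordinal-weighted Gwet AC2
(`AC2 = (pa - pe)/(1 - pe)`) with the poor/fair/moderate/substantial/
excellent benchmark scale, the Stuart–Maxwell marginal-homogeneity test,
Spearman correlations with exact small-sample p-values, Bonferroni/Holm
adjustment, and a multi-rater ratings simulator.

## Worked example

```r
library(fwtract)

# 1. a synthetic surgical case: bundle crossing a peritumoral edema shell
ph <- standard_edema_phantom(seed = 7)

# 2. standard (uncorrected) tensor fit and tractography
tf     <- fit_tensor(ph$dwi, ph$gtab, ph$truth$brain)
maps   <- tensor_metrics(tf)
params <- tracking_params(seed = 7)
seeds  <- seeds_from_mask(ph$truth$bundle, params)
t_std  <- track(tf, maps, seeds, params)

# 3. free-water fit, corrected maps, corrected tractography
fit   <- fit_freewater(ph$dwi, ph$gtab, ph$truth$brain)
cmaps <- corrected_fa(fit$tensor, fit$fw)
t_cor <- track(fit$tensor, cmaps, seeds, params, fw_gate = fit$fw)

be <- ph$truth$bundle$data & ph$truth$edema$data
cat(sprintf("FA in the edematous bundle: uncorrected %.2f, corrected %.2f\n",
            mean(maps$fa[be]), mean(cmaps$fa[be])))

# 4. free-water parameterization + adaptive correction slider
fwt  <- parameterize_tractogram(t_cor, fit$fw)
cfg  <- slider_config()
s100 <- apply_threshold(fwt, cutoff_from_slider(100, cfg), cfg)
st   <- recovery_stats(t_std, s100, ph$truth$edema)
cat(sprintf("edema-traversing streamlines: standard %d, corrected at 100%% %d (ratio %.1f)\n",
            st$n_through_a, st$n_through_b, st$ratio))
cat(sprintf("free-water ratio of this case: %.3f\n",
            free_water_ratio(ph$truth$lesion, ph$truth$edema)))

# 5. survey statistics: a published agreement pair and its label
ac2 <- ac2_from_agreement(0.8533, 0.4329)
cat(sprintf("AC2 from pa = 85.33%%, pe = 43.29%%: %.2f (%s)\n",
            ac2, benchmark_label(ac2)))
```

Output:

```
FA in the edematous bundle: uncorrected 0.13, corrected 0.55
edema-traversing streamlines: standard 178, corrected at 100% 490 (ratio 2.8)
free-water ratio of this case: 0.972
AC2 from pa = 85.33%, pe = 43.29%: 0.74 (substantial)
```

Reading: the uncorrected FA of the contaminated bundle section (0.13) sits
below the 0.15 tracking threshold, so standard tractography loses the bundle
inside the edema; the corrected (tissue) FA of 0.55 is far above it, and
corrected tracking at slider 100 % traverses the edema with 2.8 times as
many streamlines. The free-water ratio — perilesional volume over total
abnormal volume — is the per-case edema-severity covariate. The last line
converts a published percent-agreement / chance-agreement pair into the
agreement coefficient and its reliability label.

## Command line

A thin wrapper over the same functions, installed at `exec/fwtract` inside
the package (or run as
`Rscript -e 'quit(status = fwtract::fwtract_main())' --args ...`):

```
fwtract pipeline --preset standard-edema --seed 7 --out-dir out/
fwtract fit-freewater --dwi dwi.nii.gz --bval bvals --bvec bvecs \
        --mask mask.nii.gz --out-prefix sub01
fwtract threshold --trk fwt.trk --slider 60 --ref fa.nii.gz --out out.trk
fwtract survey-stats --ratings ratings.csv --out report.csv
```

`pipeline` runs phantom → tensor fit → free-water fit → both trackings →
parameterization → slider 0 %/100 % → recovery report end to end.

## Layout

- `R/dwi_io.R`, `R/trk_io.R` — NIfTI volumes/masks, FSL bval/bvec, TrackVis
  TRK with a per-point `freewater` scalar channel; world-mm spatial types
- `R/tensor_model.R`, `R/eig3.R`, `R/interp.R` — WLS tensor fit, FA/MD/
  eigenvector maps, forward signal model, vectorized 3×3 eigensolver
- `R/freewater.R` — bi-compartment fit, corrected maps, free-water ratio
- `R/tracking.R` — deterministic Euler tractography with FA threshold,
  bend limit and free-water gate
- `R/fw_tractogram.R` — parameterization, slider, thresholding, recovery
  statistics
- `R/phantom.R` — phantom generator and the standard edema benchmark
- `R/rater_stats.R` — Gwet AC2, benchmark labels, Stuart–Maxwell, Spearman,
  multiplicity, ratings simulator
- `R/cli.R` — the `fwtract` subcommand dispatcher
- `vignettes/free-water-tractography.Rmd` — the model, its assumptions,
  parameter choices and limitations
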
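# plaspect

Combined diffusion-relaxation (T2\*-ADC) placental MRI analysis:
voxelwise mapping, unsupervised spectral-component decomposition, and
cohort statistics, with a synthetic placental phantom/cohort generator
providing ground truth for every stage.

## The problem

Combined T2\*-diffusion acquisitions sample every voxel of the placenta
and adjacent uterine wall under many (echo time, b-value) combinations in
one scan. For a single spin population the magnitude signal follows

    S(TE, b) = S0 · exp(-(TE - TEmin)/T2*) · exp(-b · ADC)

but placental voxels mix several microenvironments (pooled maternal blood,
fetal capillaries, villous tissue, septa, vessels). This package models
each voxel's reference-normalised signal as a simplex-weighted mixture of
M shared, non-negative T2\*-ADC spectra,

    y_v / y_ref,v ≈ K F w_v,    F ≥ 0 (columns sum to 1),  w_v on the simplex,

where K is the kernel dictionary over a log-spaced (T2\*, ADC) grid. A
"full" decomposition learns F and all w_v from training scans (alternating
an exact per-voxel simplex least-squares step with an exact per-component
simplex-QP spectra step under a spectral smoothness penalty); a "reduced"
decomposition projects new scans onto the fixed spectra, so components
mean the same thing for every scan. Per-scan mean component weightings are
then compared across a cohort (control vs congenital heart disease) by
ANCOVA adjusting for gestational age and maternal age, with within-group
Pearson trends over gestation and Benjamini–Hochberg FDR correction across
the M components per test family.

Audience: quantitative MRI researchers who want a tested, reproducible
reference implementation of this analysis chain, plus a phantom generator
to validate it.

## Worked example

```r
library(plaspect)

protocol <- default_protocol()       # 4 echo times x 61 volumes = 244
grid     <- build_spectral_grid()    # 50 x 50 log-spaced (T2*, ADC) plane

# a 3-component digital phantom with disjoint, known composition
peaks <- list(data.frame(t2star = 0.030, adc = 0.001, amplitude = 1),
              data.frame(t2star = 0.065, adc = 0.020, amplitude = 1),
              data.frame(t2star = 0.110, adc = 0.300, amplitude = 1))
spec <- phantom_spec(grid_shape = c(16, 16, 8), n_lobules = 6,
                     components = peaks,
                     spatial_pattern = rep("lobule_partition", 3),
                     grid = grid, snr = Inf, seed = 7)
scan <- synthesize_scan(spec, protocol)

# voxelwise T2*/ADC mapping with ROI summaries
fit <- fit_roi(scan$series, scan$mask)
str(fit$summary)

# learn 3 components and compare with the generating truth
dec <- full_inspect(list(list(series = scan$series, mask = scan$mask)),
                    m_components = 3, grid = grid, seed = 2)
sqrt(mean((scan$truth$weights - dec$weight_maps[[1]]$weights)^2))
find_peaks(dec$components$amplitudes[, 3], grid, min_amplitude = 0.02)
```

Printed output (seed 7/2, R 4.3):

```
List of 7
 $ n_voxels        : int 524
 $ n_excluded      : int 0
 $ volume_mm3      : num 14148
 $ mean_t2star_ms  : num 64.1
 $ median_t2star_ms: num 65.2
 $ mean_adc        : num 0.0869
 $ median_adc      : num 0.0193
[1] 0
     t2star       adc amplitude low_t2star high_t2star vascular_adc
1 0.1135237 0.3237458 0.2041752      FALSE        TRUE         TRUE
```

The weight maps are recovered exactly (RMSE 0 against ground truth), and
the third component's dominant spectral peak lands one grid step from the
planted high-T2\* vascular peak (0.110 s, 0.30 mm²/s), flagged both
`high_t2star` and `vascular_adc`; the ROI summaries are the per-scan
quantities the cohort statistics consume. (`mean_adc` is inflated over
the median by the vascular component's voxels — both statistics are
reported for exactly this reason.)

## Analysis workflow

The `analysis/` scripts chain the stages on a simulated study cohort
(67 scans: 50 control / 17 CHD) and write tables and figures under
`results/`:

    Rscript analysis/01_simulate.R    # cohort of synthetic scans + table
    Rscript analysis/02_fit.R         # T2*/ADC maps + ROI summaries
    Rscript analysis/03_decompose.R   # full (training) + reduced (all scans)
    Rscript analysis/04_stats.R       # demographics, ANCOVA, trends, FDR
    Rscript analysis/05_report.R      # weighting-vs-GA panels, montages

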
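---
title: "Decomposing combined T2*-diffusion placental MRI into tissue components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing combined T2*-diffusion placental MRI into tissue components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(plaspect)
```

## The signal model

A combined T2\*-diffusion acquisition interleaves echo times and diffusion
weightings in a single scan, so every voxel is sampled under many
`(TE, b)` combinations. For a single spin population with effective
transverse relaxation time $T_2^*$ and apparent diffusion coefficient
$\mathrm{ADC}$, the magnitude signal follows

$$ S(T_E, b) \;=\; S_0 \, e^{-(T_E - T_{E,\min})/T_2^*} \, e^{-b\,\mathrm{ADC}}, $$

where $T_{E,\min}$ is the shortest echo time acquired and $S_0$ is the
signal of the reference volume ($b = 0$, $T_E = T_{E,\min}$) — the image on
which the placental region of interest (ROI; whole placenta plus adjacent
uterine wall) is segmented. `signal_kernel()` and `forward_signal()`
implement this model; `default_protocol()` builds the full acquisition:
echo times (78, 114, 150, 186) ms, each combined with one $b=0$ volume and
diffusion shells $b$ = (5, 10, 25, 50, 100, 200, 400, 600, 1200, 1600)
s·mm$^{-2}$ × 3 directions, 18 × 8, 36 × 7 and 800 × 15 directions — 61
volumes per echo time, 244 in total.

Two unit conventions deserve note. Internally all times are seconds; the
reporting layer converts $T_2^*$ to milliseconds. The ADC axis follows the
printed convention of the placental literature this package targets, in
which free water sits at 0.3 mm²·s$^{-1}$ and placental tissue near 0.02;
we mirror that scale (spectral grid up to 1.0 mm²·s$^{-1}$) rather than
re-deriving the unit. The model is isotropic: gradient directions carry no
information and repeated directions act as replicate measurements, so a
scalar ADC is fitted. The number of $b=0$ volumes per echo time is not
constrained by the acquisition table; we use one, the minimum consistent
with a well-defined reference volume.

## Voxelwise mapping

`fit_voxel()` / `fit_batch()` / `fit_roi()` fit $(S_0, T_2^*, \mathrm{ADC})$
per voxel by bounded nonlinear least squares: a weighted log-linear closed
form (weights $y^2$, the first-order equivalent of linear-scale least
squares) provides the start, refined by a projected Levenberg–Marquardt
iteration with bounds $T_2^* \in [1\,\mathrm{ms}, 1\,\mathrm{s}]$,
$\mathrm{ADC} \in [0, 1]$. Because every voxel shares the protocol design,
the iteration is vectorised across voxels: each step is a handful of
`(measurements × voxels)` element-wise operations plus a closed-form
symmetric 3×3 solve per voxel, with per-voxel damping and acceptance. The
cost tolerance is $10^{-10}$ with at most 200 iterations. Degenerate voxels
(all-zero, non-finite, fewer than three usable measurements) are flagged
and excluded — never imputed — and ROI summaries (mean/median T2\* in ms,
mean ADC, ROI volume) report the excluded count. Whether failed voxels were
excluded from ROI means in comparable pipelines is usually unstated; we
exclude and log, which is the conservative, reportable choice.

Rician bias is *not* corrected in the default fit, matching the common
practice of fitting magnitude data directly; `rician_mean()` provides the
analytic magnitude bias for calibration checks.

## The spectral decomposition

The decomposition represents each ROI voxel's $S_0$-normalised signal as a
simplex-weighted mixture of $M$ canonical spectra over a discretised
$(T_2^*, \mathrm{ADC})$ plane:

$$ \frac{y_v}{y_{v,\mathrm{ref}}} \;\approx\; K\,F\,w_v, \qquad
   F \ge 0,\; \mathbf{1}^\top F = \mathbf{1}^\top,\;
   w_v \in \Delta^{M-1}, $$

with $K$ the kernel dictionary (rows = protocol measurements, columns =
grid atoms; the reference row is identically 1) and $F$ the per-component
amplitude columns. The fitted objective is

$$ \sum_v \lVert y_v/y_{v,\mathrm{ref}} - K F w_v \rVert^2
   \;+\; \lambda \sum_m f_m^\top L f_m, $$

where $L$ is the 4-neighbour graph Laplacian of the spectral plane
(a smoothness penalty; $\lambda = 10^{-3}$ by default). The estimator
alternates:

1. **Weight step** — per-voxel simplex-constrained least squares against
   the component signatures $KF$, solved *exactly* by a primal active-set
   QP in compiled code (`src/simplex_lsq.cpp`).
2. **Spectra step** — block-coordinate descent over components: each
   column of $F$ solves its simplex-constrained QP exactly by an
   active-set method with the quadratic term
   $\alpha_m K^\top K + \lambda L$ applied implicitly, warm-started from
   the previous support.

Both steps are exact minimisations of their blocks, so the objective is
non-increasing across iterations by construction; iteration stops when the
relative objective change drops below $10^{-6}$ (default cap 500
iterations). Initialisation is deterministic: ridge-regularised
non-negative per-voxel spectra (multiplicative updates) on a seeded voxel
subsample, clustered by k-means; centroids seed $F$. Published
descriptions of this class of decomposition leave the estimator internals
open, so this alternating scheme *is* the package's concrete definition
of the decomposition; its regularisation (spectral-plane smoothness, no
spatial regularisation of weights) keeps per-voxel projection
embarrassingly parallel.

Each voxel is normalised by its *measured* reference-volume value
$y_{v,\mathrm{ref}}$ (first $b=0$ at the shortest echo time) rather than
by a fitted $S_0$: the dictionary row at the reference is identically 1,
so this normalisation makes data and model exactly consistent there — a
noiseless multi-compartment voxel is then represented exactly, whereas a
mono-exponentially *fitted* $S_0$ is systematically wrong for
multi-compartment decays and measurably biases component weights.
Published pipelines rarely state their normalisation; this is our
documented choice, and it makes weights interpretable as fractions of the
reference-volume signal. Its cost is that the per-voxel reference value
carries measurement noise into the normalisation (a ~2% scale jitter at
SNR 50), which perturbs weights without biasing their ROI means
appreciably.

Magnitude data carry a Rician noise floor: heavily attenuated
measurements (large TE and b) have expectation above their true
amplitude, which a least-squares mixture fit misreads as extra
slow-decaying signal. Both decomposition entry points therefore accept a
`noise_sigma` option applying the moment-based magnitude correction
$\tilde y = \sqrt{\max(y^2 - 2\sigma^2, 0)}$ before normalisation, with
$\sigma$ either given or estimated from background voxels
(`estimate_noise_sigma()`, using $E[y^2] = 2\sigma^2$ off-tissue).
Reconstruction chains for such acquisitions routinely include a denoising
stage; the noise-floor correction is this pipeline's counterpart. It is
off by default and enabled in the package's own cohort pipeline.

Component labels are made reproducible by canonical ordering: ascending
amplitude-weighted mean log $T_2^*$, ties broken by mean log ADC. `full_inspect()`
learns spectra and weights from training scans; `reduced_inspect()`
projects any scan onto fixed spectra — identical components for all data —
and reproduces a training scan's maps exactly (the weight step is the same
solver at the same fixed point). The default $M = 7$ follows the component
count previously found to best explain placental and adjacent uterine-wall
combined T2\*-diffusion signal. `find_peaks()` annotates spectral local
maxima with the interpretation flags used in this literature: low
$T_2^*$ (< 0.06 s), high $T_2^*$ (> 0.09 s), and ADC above free water
(0.3 mm²·s$^{-1}$, read as perfusing/vascular spins).

The default spectral grid spans $T_2^*$ 0.01–0.30 s and ADC
$10^{-4}$–1.0 mm²·s$^{-1}$ with 50 × 50 log-spaced points, covering the
reported placental peak regimes with margin.

## The synthetic cohort generator

No imaging data are distributed with this package, so every claim is
tested against simulated scans with known ground truth.

**Phantom geometry.** `phantom_spec()` + `synthesize_scan()` build a
lobulated placental slab: an ellipsoid (semi-axes 40%, 40%, 28% of the
grid) plus a one-sided adjacent shell ("uterine wall"), subdivided into
Voronoi lobules seeded at random interior points. Default desk scale is
32×32×16 voxels at 3 mm isotropic; cohort runs use smaller grids (stated
below).

**Component spectra.** The seven default components
(`default_component_peaks()`) are free parameters — the source figures are
graphical only — chosen once to respect the described categories:
component 1 low-$T_2^*$/low-ADC (two peaks), component 3 containing a
high-ADC (> 0.1) peak with $T_2^* > 0.07$ s, component 7 multi-peak with
all $T_2^* > 0.09$ s including a supra-free-water peak, and the ordering
key (amplitude-weighted mean log $T_2^*$) spaced geometrically (ratio
≈ 1.2–1.5) so canonical labels are stable under estimation noise.

**Spatial patterns.** Real component maps are strongly heterogeneous: hot
spots at lobule centres, rims around lobule peripheries, bands along the
uterine wall and septa, and components locally absent. The generator
reproduces that dominance structure — each component has a niche where it
is the largest contributor (periphery, wall/septa, lobule centres, or its
own subset of lobule bodies), over a small everywhere-positive floor —
plus multiplicative log-normal texture at lobule scale (s.d. 0.4) and
voxel scale (s.d. 0.3). A flat, spatially featureless mixture would be
unidentifiable for *any* unsupervised decomposition (the factorisation is
non-unique without near-dominant voxels), and would also be a poor model
of the tissue. The `lobule_partition` pattern builds fully disjoint
one-hot phantoms for identifiability tests.

**Noise.** Magnitude (Rician) noise with $\sigma = S_0/\mathrm{SNR}$ per
channel, SNR 50 at the reference volume by default (no SNR is published
for the source acquisition; 50 is a realistic figure for 3 T placental
EPI at 3 mm). A Gaussian option exists for testing linear solvers.

**Cohort structure.** `cohort_spec()` + `simulate_cohort_table()` emulate
the study design: 50 control scans from 36 participants and 17 CHD scans
from 12 (some participants scanned twice, repeat fraction 0.4),
gestational age (GA) uniform on 20–40 weeks, maternal age
control ~ N(35, 3²) vs CHD ~ N(32, 4²) years, BMI ~ N(26.2, 3²) shared.
Per-scan expected weightings follow
`baseline + slope · max(0, GA − 30) + group offset`, clipped and
renormalised: a hinge changepoint at 30 weeks rather than a smooth
nonlinearity, mirroring trends that emerge most clearly after 30 weeks.
Defaults put offsets only in components 3 (+0.05, CHD higher) and 4
(−0.05) and give controls a rising component 4 and declining components
5–7, CHD rising components 2–3 and declining 5–7. Baselines
(0.20, 0.10, 0.15, 0.15, 0.15, 0.15, 0.10) and a between-scan biological
s.d. of 0.03 per component are free parameters chosen once as plausible
values; none are published. Offsets must keep `baseline + offset`
positive (error otherwise, naming the component); small negatives produced
by trends at GA extremes are clipped then renormalised.
`simulate_cohort()` additionally builds image volumes whose ROI-mean
weightings match the table targets exactly (multiplicative raking) and
whose slab volume grows with GA as $(\mathrm{GA}/30)^{1.5}$.

What the generator does *not* emulate: motion, distortion, contractions,
reconstruction/denoising effects, fetal or maternal vascular trees,
directional diffusion, and any published per-component weighting values
(none exist). Passing tests therefore demonstrate correctness of the
estimators under the stated generative assumptions, not agreement with any
real cohort.

## Statistics

`ancova_group()` is ordinary least squares of
`outcome ~ group + GA + maternal age` (two-level group factor, no
interaction), with the group coefficient's two-sided t-test — implemented
from the design matrix up so an independent `lm()` oracle can verify it.
`pearson_trend()` computes within-group Pearson correlation against GA
with the $t_{n-2}$ p-value. `bh_fdr()` applies Benjamini–Hochberg
(delegated to `stats::p.adjust`; an independent brute-force step-up serves
as the test oracle). `demographics_tests()` gates on Shapiro–Wilk
normality per group: non-normal variables (GA, maternal age in practice)
by Mann–Whitney U — exact enumeration over group assignments when both
groups have n ≤ 10, otherwise the normal approximation with tie and
continuity corrections — and normal variables (BMI) by pooled-variance
t-test, each summarised by the matching convention (mean ± sd vs
median/IQR).

`run_component_analysis()` runs three FDR families, each corrected across
the M components separately: (a) ANCOVA group comparisons, (b)
control-group GA trends, (c) CHD-group GA trends. Keeping the families
separate (rather than pooling all 21 tests) is the most conservative
reading of a correction described as being over the seven components; the
per-group trend families likewise. Repeat scans are treated as
independent rows, as such cohort analyses conventionally do, and the
report carries that caveat; no mixed model is fitted.

## Problem sizes and numerical choices

Test and acceptance runs use deliberately modest sizes chosen to exercise
every code path at comfortable runtime: voxel-fit calibration on 1000
voxels × 3 SNR levels (25/50/100) over the full 244-measurement protocol;
decomposition recovery on a noiseless 3-component disjoint phantom
(16×16×8, full grid) and 7-component SNR-50 cohorts of six to eight scans
of 16–18 voxels per side (with the noise-floor correction enabled);
statistical calibration on 500 null and 200 effect cohort tables at
the study's 50-vs-17 design; and an end-to-end run (simulate → fit → full
decomposition on control first scans → reduced projection of all scans →
statistics) on 67 scans of 14×14×7 voxels. Tie-breaks and degeneracies are
handled deterministically: equal-distance Voronoi assignments go to the
lowest lobule index, canonical-order ties break on mean log ADC, all
random streams derive from a single integer seed via a fixed linear map,
and solver tolerances are stated above. Component matching in recovery
tests pairs true to estimated components by exhaustive minimum-cost
assignment on peak distance (estimated dominant peak to nearest true
peak), counting a component as matched within one grid step for noiseless
single-peak phantoms and within two grid steps (≈ one resolution element)
at SNR 50.

## Known limitations

* The decomposition's objective is non-convex; the deterministic
  initialisation makes runs reproducible, not provably global.
* Reference-volume normalisation injects the reference measurement's noise
  into every voxel's weights (small at the working SNR, but present).
* Weights are relative signal fractions: a change in one component forces
  reciprocal changes in others, and no claim of one-to-one mapping between
  components and anatomical compartments is made.
* Rician bias at high attenuation (large TE and b) is not modelled by the
  least-squares fit; at SNR 50 it mainly affects the most attenuated
  measurements (the optional noise-floor correction mitigates this for the
  decomposition).
* Spectral resolution is acquisition-limited at the corners of the plane:
  atoms above the free-water ADC retain signal only at the smallest
  b-values, and T2* beyond the 108 ms echo-time span has weak curvature,
  so spectra there localise only to within roughly two grid steps even
  without noise.
* Repeat scans violate row independence in the statistics; the package
  keeps the simple fixed-design analysis and flags the caveat rather than
  fitting a mixed model.
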
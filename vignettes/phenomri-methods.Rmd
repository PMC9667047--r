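---
title: "Models and methods behind phenomri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phenomri}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomri)
```

phenomri implements a multiparametric quantitative-MRI analysis chain for
discriminating a heterogeneous, highly malignant tumor phenotype from a
homogeneous, low-malignancy one, together with the digital phantoms used
to validate every stage against known ground truth. This vignette is the
package's account of the underlying models, the tunable parameters, the
numerical choices, and what the synthetic validation does and does not
demonstrate.

## Signal models and fitting

### Relaxometry and diffusion

Three mono-exponential voxel models are fitted within the tumor ROI:

* saturation recovery, `SI(TR) = A + C (1 − e^{−TR/T1})`, at eight
  repetition times (123–7500 ms),
* spin-echo decay, `SI(TE) = A + C e^{−TE/T2}`, at five echo times
  (10–90 ms),
* diffusion decay, `S(b) = S0 e^{−b·ADC}`, at twelve b-values
  (20–2200 s/mm²), all twelve in a single mono-exponential fit (no
  IVIM segmentation, no kurtosis model).

All three are *separable*: for a fixed relaxation or diffusion constant
the amplitudes enter linearly. The fitter exploits this by profiling the
amplitudes out (variable projection) and searching the single nonlinear
constant on a bounded interval — a shared coarse grid (64 candidates,
log-spaced for T1/T2, linear for ADC) brackets the optimum per voxel, and
a vectorized golden-section refinement (36 iterations, ≈1e−8 relative
precision) drives all voxels to their minima simultaneously. This is
deterministic, needs no starting values, and cannot be trapped by a bad
initialization; on noise-free input it reproduces truth to better than
1e−5 relative error (tested), and it agrees with exhaustive 2-D grid
search and with an independent Levenberg–Marquardt fit on random voxels.

Search bounds are T1 ∈ [1, 10000] ms, T2 ∈ [1, 1000] ms,
ADC ∈ [0, 5e−3] mm²/s. A voxel whose estimate lands on a bound, whose
amplitude is non-positive, or whose signal is constant is flagged invalid
rather than silently clipped; only valid voxels enter ROI statistics. A
signal that *increases* with b is non-physical and flagged invalid with
ADC reported as 0; a constant signal across b legitimately yields ADC = 0.
The offset `A` is fitted freely for T1 and T2, exactly as the printed
signal equations state, since the vendor fit's internal constraints are
unknown.

Contrast retention is quantified as `ΔT1 = T1(pre) − T1(post)` per voxel
(positive where retained agent shortens T1), with validity the
conjunction of both maps.

### DCE pharmacokinetics

Tissue concentration follows the extended Tofts model
`Ct(t) = vp·Cp(t) + Ktrans ∫ Cp(u) e^{−Ktrans (t−u)/ve} du` with a
population arterial input function. The AIF is a biexponential bolus
decay, `Cp(τ) = D (a₁ e^{−m₁τ} + a₂ e^{−m₂τ})`, with defaults a₁ = 0.8,
m₁ = 3 /min, a₂ = 0.2, m₂ = 0.06 /min, onset delay 3 s and peak
D = 5 mM. The shape parameters are plausible for a murine bolus; the
amplitude only sets the internal concentration scale. Because forward
simulation and inversion share every constant, the testable contract is
self-consistency, not agreement with any particular scanner's absolute
Ktrans values — those also depend on the (unpublished) relaxivity of the
agent at field.

The convolution is evaluated by the exact recursive exponential scheme
for a piecewise-linear plasma curve on the uniform frame grid (610
frames / 1200 s by default, injection at 60 s), with a series expansion
for `k·dt < 1e−6`. Since the bolus arrival is a step in `Cp`, the scheme
is first-order accurate at the kink: against the closed-form solution for
the biexponential AIF the discrete curve differs by a few percent at the
default frame interval and converges linearly under grid refinement
(tested). Forward and inverse use the same discretization, so round trips
are exact to machine precision.

Fitting again uses separability: for fixed `k = Ktrans/ve` the model is
linear in `(Ktrans, vp)`, so the fit is a 1-D search over `k` (61
log-spaced candidates over 1e−3–1e3 /min, golden-section refinement) with
nonnegative least squares per candidate, followed by a bounded
quasi-Newton polish only when the unconstrained optimum had to be
projected onto the box Ktrans ∈ [0, 5] /min, ve ∈ [0.01, 1],
vp ∈ [0, 0.2] (with a quadratic penalty for ve + vp > 1). Noise-free
recovery over random parameter draws is accurate to ≪1% (tested); a
purely vascular curve (`Ct = vp·Cp`) returns Ktrans ≈ 0 with `ve`
reported as undefined, and an all-zero curve is flagged degenerate.

Signal↔concentration conversion has two modes. Relative enhancement
`(SI − SI₀)/SI₀`, with `SI₀` the mean over all frames before injection,
feeds the semi-quantitative metrics: peak post-injection enhancement,
maximum slope (forward difference of a 3-frame moving average, per
minute — raw 2 s frames are noise-dominated), and the trapezoidal AUC
from the injection instant to scan end. Relaxivity mode inverts the
spoiled-gradient-echo signal equation (TR 24.6 ms, flip angle 30°,
r₁ = 6 L mmol⁻¹ s⁻¹ by default) using the fitted pre-contrast T1, and
feeds the Tofts fit. The pipeline fits the ROI-mean curve (the study
default; a voxel-wise map fitter `fit_dce_map()` is provided and
validated, but is an order of magnitude more expensive and changes no
group-level conclusion on these phantoms); for a heterogeneous tumor the
ROI-level Ktrans is therefore an effective, ROI-averaged quantity.

### Histogram features

First-order features of the masked, valid voxel values: mean,
bias-corrected skewness (adjusted Fisher–Pearson G1), bias-corrected
*excess* kurtosis (G2; the Pearson convention is a configuration switch),
range, the 90th percentile as the linear-interpolation quantile between
order statistics (p90 of 1…100 is 90.1), IQR = p75 − p25, and Shannon
entropy of a 64-bin equal-width histogram spanning the sample min–max
(bin count configurable; the binning of the original analysis tools is
not published, and entropy values are comparable only at fixed binning).
"p90" is read as the 90th-percentile *value* of the distribution; the
mean of supra-p90 values is the plausible alternative reading and can be
computed from the same sample. Moment features require n ≥ 4 and nonzero
variance, otherwise they are NA.

### LA-ICP-MS quantification

External calibration regresses per-level mean line intensities on nominal
concentrations of gelatin standards (0–600 mg/L) by weighted least
squares with weights `1/s_i²` from the replicate scatter at each level
(10 ablated lines per standard); a pooled replicate variance substitutes
where a level has zero scatter, and noise-free standards reduce exactly
to ordinary least squares. Detection limits use the blank-replicate
standard deviation: LOD = 3σ/slope, LOQ = 10σ/slope, so LOQ/LOD ≡ 10/3.
σ could alternatively be read as the residual sd of the fit; the blank
reading is the most common and is the one implemented. Line scans are
quantified spot-wise as `(intensity − intercept)/slope` at the 15 µm spot
spacing; sub-LOD values are retained unclipped but flagged. Standards are
prepared in mg/L while tissue is reported in µg/g; the bridge assumes
tissue density 1 g/mL, making the two scales numerically equal. Per
tumor, three simulated sections give a triplicate mean ± sample SD.

### Statistics and PCA

Every comparison first runs the Shapiro–Wilk test per group at α = 0.05;
if *any* group rejects normality the comparison is nonparametric
(Mann–Whitney U between phenotypes, Kruskal–Wallis across days),
otherwise parametric (Welch t-test, one-way ANOVA). The U test is exact
when both groups have n ≤ 8 and no ties (verified against exhaustive
enumeration), with the tie-corrected normal approximation otherwise. No
multiple-testing correction is applied — a deliberate
faithful-reproduction choice; raw p-values are reported. Pearson
correlation (ΔT1 vs. Gd section means) uses the t-distribution with
n − 2 df.

PCA operates on the fixed ten-variable table, z-scored per column because
the variables carry incommensurate units (an ADC is ~1e−3 mm²/s, a T1
~2000 ms). Components come from the SVD of the centered matrix;
explained-variance ratios are λᵢ/Σλ, which sum to one at full rank; each
component's sign is fixed so its largest-magnitude loading is positive.
PCA runs per day (primary, 16 tumors each) and pooled. Phenotype
classification thresholds the PC1 score at the midpoint of the two group
means, taking the better orientation.

## The digital phantom

Each tumor is an ellipse (axis ratio 0.85, random orientation and ±1
voxel center jitter) on a 32×32 grid at 0.28 mm pixel spacing, 1 mm
slice. The grid size is the package's study-scale choice: it leaves
~40–190 ROI voxels per tumor depending on day and phenotype — enough for
stable first-order histograms — while keeping a full 48-tumor study with
610-frame DCE simulation at a few seconds, so cohort-level properties can
be verified over 100 master seeds. Tumor radius grows linearly with day,
faster for the heterogeneous phenotype (at day 9 the homogeneous tumor
has roughly half the area, mirroring the growth contrast of the animal
models).

The heterogeneous phenotype carries (i) a coherent necrotic core whose
radius is {0.15, 0.25, 0.35} of the tumor radius on days {3, 6, 9}, with
longer T1/T2, elevated ADC, near-zero Ktrans and reduced Gd retention,
and (ii) scattered sub-resolution necrotic/edematous foci in 25% of rim
voxels, adding an exponential ADC elevation (mean 0.6e−3 mm²/s). The
speckle term is what keeps the ADC histogram *leptokurtic* with elevated
p90 and range at every time point: a large coherent core alone would make
the histogram bimodal, which drives excess kurtosis negative — the
opposite of the heavy-tailed histograms reported for necrotic tumors.
That is also why the core stays a minority phase (≤12% of area) by
construction. The homogeneous phenotype is uniform, densely cellular
tissue: lower T1/T2, higher mean ADC with a narrow distribution, lower
Ktrans but larger ve/vp (intact perfusion with wash-out), and low Gd
retention.

Per-tumor base values are drawn uniformly from tissue-class intervals
(see `default_param_ranges()`), then modulated by a smooth ±5% bilinear
random field; Gd retention declines with day in both phenotypes. Every
stochastic element derives its RNG stream from the master seed via a
stable string-hash (`derive_seed()`), so adding one simulated series
never shifts another's noise, and identical seeds give bit-identical
phantoms.

Noise is additive Gaussian, clamped at zero to respect nonnegative
intensities (a Rician magnitude option exists for low-SNR realism; at the
simulated SNR the Gaussian approximation is appropriate). Default noise
levels are 1% of the proton-density scale for the mapping series and
≈2% of the DCE baseline signal.

What passing the synthetic validation shows: the estimators invert their
own forward models correctly at protocol settings, error grows gracefully
with noise, and the group-level analysis recovers contrasts that are
built into the truth. What it does not show: robustness to motion,
partial-volume and slice-profile effects, B1 inhomogeneity, RARE echo
trains, k-space artifacts, real AIF variability, or MRI↔LA-ICP-MS
co-registration error — none of which are simulated. Absolute Ktrans and
Gd values are internally consistent, not calibrated to any scanner or
spectrometer.

## Degenerate inputs and tie-breaks

Constant or all-zero voxels, bound hits, and non-physical diffusion
signals are flagged invalid and excluded from ROI samples. An empty
ROI or an ROI with zero valid voxels is an error, never a silent NA.
Enhancement conversion flags voxels with non-positive baseline, and
relaxivity inversion flags samples leaving the physical signal range.
Identical groups give p = 1; zero-variance inputs to correlation or
z-scoring are rejected. A constant histogram sample has zero entropy and
undefined moments. Negative quantified concentrations are retained
(unbiased near the blank) and only flagged.

## Known limitations

Single-slice maps only (volume is the single multi-slice quantity, as in
the underlying protocol); ROI-level PK fitting by default; the AIF is
parametric and shared across animals; entropy depends on the 64-bin
choice; the necrotic-core construction is a two-phase caricature of real
necrosis; and the LA-ICP-MS section mean covers the tumor bounding box,
so it slightly dilutes the ROI mean with background spots.
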
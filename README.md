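# phenomri

Multiparametric quantitative MRI and laser-ablation ICP-MS analysis for
discriminating tumor phenotypes of different malignancy, validated end to
end on digital phantoms with known ground truth.

## The problem

Highly malignant, metastasizing tumors (such as the murine 4T1 mammary
carcinoma) differ from low-malignancy tumors of the same genetic background
(67NR) in structural heterogeneity: they develop necrotic cores,
intratumoral edema and hemorrhage, and leaky, poorly developed vasculature.
A multiparametric small-animal MRI protocol can read these differences
non-invasively:

* **ADC mapping** (multi-b diffusion): `S(b) = S0 · exp(−b · ADC)` —
  cellularity and necrosis; first-order histogram features (mean, excess
  kurtosis, range, p90) capture the heterogeneity of the ADC distribution.
* **T1/T2 relaxometry** (variable TR / multi-echo):
  `SI(TR) = A + C · (1 − e^(−TR/T1))` and `SI(TE) = A + C · e^(−TE/T2)`,
  fitted voxel-wise; edema and hemorrhage prolong the relaxation times.
* **DCE-MRI** with an albumin-binding contrast agent: the extended Tofts
  model `Ct(t) = vp·Cp(t) + Ktrans · (Cp ⊛ e^(−Ktrans·t/ve))(t)` with a
  population arterial input function yields the permeability surrogate
  `Ktrans`; the relative-enhancement curve yields AUC, maximum slope and
  peak enhancement.
* **ΔT1 = T1(pre) − T1(post)** quantifies interstitial retention of the
  agent, cross-validated ex vivo by **LA-ICP-MS** gadolinium maps
  (gelatin-standard calibration with weighted linear regression and
  3σ/10σ detection limits).
* A **Shapiro-Wilk-gated statistics layer** (t-test / Mann-Whitney U,
  ANOVA / Kruskal-Wallis, Pearson correlation) and a **PCA over ten fixed
  variables** (`ADC_mean, ADC_kurtosis, ADC_range, ADC_p90, delta_T1,
  Ktrans, AUC, slope_max, T1, T2`) discriminate the two phenotypes.

Because no per-voxel in-vivo ground truth exists, the package ships a
digital-phantom module that forward-simulates every acquisition above for
two constructed phenotypes (heterogeneous/metastatic-like with a growing
necrotic core vs. homogeneous/non-metastatic-like), so that each stage and
the whole pipeline can be validated by parameter recovery and by
reproduction of the qualitative group contrasts.

## Worked example

```r
library(phenomri)

truth <- make_phantom("heterogeneous_metastatic", day = 9, seed = 11)
truth
#> <phantom_truth> heterogeneous_metastatic, day 9, 32 x 32, seed 11
#>   tumor 123 voxels, necrotic fraction 0.122

series <- simulate_t1_series(truth, noise_sd = 5, seed = 11)
t1 <- fit_t1_map(series, truth$tumor_mask)
t1
#> <parameter_map> T1 [ms], 32 x 32, 123 valid voxels, range 1881 .. 2746

compute_feature_set(extract_roi_sample(t1, truth$tumor_mask))
#> <feature_set> n 123: mean 2115, skew 1.73, kurt 2.42, range 864.2,
#>   p90 2448, IQR 155.2, entropy 4.88 bits
```

The long T1 tail (positive skewness 1.7, excess kurtosis 2.4) is the
necrotic core; a homogeneous phantom gives near-zero skewness and a much narrower
range. A full study — 8 tumors per phenotype per day, all acquisitions,
gated statistics, per-day PCA — runs in a few seconds:

```r
report <- run_study(study_config(seed = 42))
report
#> <study_report> 48 tumors, 50 comparisons
#>   PC1 phenotype accuracy: day3 1.00, day6 1.00, day9 1.00
#>   deltaT1 ~ Gd: r = 0.9483, p = 1.447e-24
directional_contrasts(report$feature_table)
#>       Ktrans_higher_het     delta_T1_higher_het ADC_kurtosis_higher_het
#>                    TRUE                    TRUE                    TRUE
#>    ADC_range_higher_het      ADC_p90_higher_het           T1_higher_het
#>                    TRUE                    TRUE                    TRUE
#>          AUC_higher_hom    slope_max_higher_hom
#>                    TRUE                    TRUE
```

PC1 separates the phenotypes perfectly on every day, and all constructed
group-mean contrasts (higher Ktrans/ΔT1/T1 and ADC heterogeneity features
in the metastatic-like phenotype; higher AUC and maximum slope in the
non-metastatic-like phenotype) hold.

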
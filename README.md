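# tausynth

Synthesis of 3D tau-PET SUVR volumes from structural MRI and routine
subject covariates, with a full clinical-evaluation battery — an R
implementation of a covariate-modulated attention U-Net (CoMA-UNet)
pipeline for inferring tau pathology when PET is unavailable.

## The problem

Tau PET maps neurofibrillary-tangle burden in vivo and is the imaging
biomarker most tightly linked to cognition in Alzheimer's disease, but it
is costly and missing from most legacy datasets, whereas T1 MRI is nearly
universal. `tausynth` synthesizes a subject-specific tau-PET volume
`P̂ ∈ R^{p1×p2×p3}` from an MRI `M` in three stages:

1. **Tabular auxiliary estimators.** After KNN imputation
   (`k = round(√p)` neighbours, uniform weights), gradient-boosted
   regressors with a Gaussian (mean, log-SD) head predict per-ROI tau
   means `τ̂_r` and SDs `σ̂_r` plus the temporal meta-ROI composite
   (MetaTempTau); a boosted classifier predicts amyloid status `c`; a
   KNN regressor predicts MMSE.
2. **Conditionally decoded attention U-Net.** An encoder/decoder with
   additive attention gates on the skips, in which every decoder
   up-sampling convolution is a conditionally parameterized convolution —
   a softmax-routed mixture over expert kernels driven by the
   standardized conditioning vector (age, sex, education, predicted MMSE
   and MetaTempTau) — produces an initial prediction `Z`.
3. **Regional-tau prompt modulation.** A learned prompt `F` is adjusted
   per subject, `F̃_c = F + ConvBlocks(F_c ⊕ Ŝ ⊕ Γ̂)`, where `F_c` is
   selected by amyloid status and `Γ̂`, `Ŝ` carry the regional estimates
   painted into their ROI masks; the output is
   `P̂ = ReLU(Conv(Z ⊕ ConvBlocks(F̃_c ⊕ Z)))`.

Training minimizes an ROI-weighted MSE,
`L = (1/n) Σ_i (1/|V|) Σ_v w(v) (P_{i,v} − P̂_{i,v})²`, with AdamW,
reduce-on-plateau scheduling, early stopping, and five folds balanced for
meta-temporal tau and amyloid status. Evaluation covers regional Pearson
correlation (Corr_AVG), MAPE, MAE, SSIM, voxel-wise Cohen's d, diagnostic
ROC-AUC, longitudinal mixed-effects coupling, Steiger's Z contrasts with
Benjamini-Hochberg FDR control, proportional-odds Braak-stage regression,
and tertile-stratified spline trajectories.

Because the cohorts such models are trained on are access-restricted, the
package includes a synthetic brain-phantom generator
(`build_atlas`, `simulate_cohort`) reproducing the statistical structure
the analyses assume: Braak-ordered regional tau accumulation,
covariate-tau coupling (plasma p-tau217 tracks temporal tau, MMSE
anti-tracks neocortical tau, APOE shifts stage), tau-coupled atrophy in
the MRI, realistic covariate missingness, and longitudinal accumulation.
The network itself — including the 3D convolutions — is implemented in
base R on a small reverse-mode autodiff tape (see the methods vignette);
the same code path runs at test scale (16³) and full scale (128³).

## Worked example

```r
library(tausynth)

atlas  <- build_atlas(c(16, 16, 16), n_rois = 16, seed = 1)
params <- phantom_params(atlas)
cohort <- simulate_cohort(atlas, params, n = 60, seed = 2)

aux <- fit_cohort_auxiliary(cohort, atlas, rows = 1:40)
est <- predict_auxiliary(aux, cohort_covariates(cohort))

net <- coma_unet(atlas$grid, encoder_channels = c(6, 12, 24), seed = 3)
coma_train(net, cohort, est, atlas,
           config = train_config(max_epochs = 10), train_rows = 1:40)
print(net)
#> Covariate-modulated attention U-Net
#>   grid: 16 x 16 x 16; levels: 3 (channels 6/12/24)
#>   conditioning: condconv, dim 5, 4 experts; prompt bank: 2 x 4 channels
#>   parameters: 156,438
#>   trained: 10 epochs, best val loss 0.1267

synth <- predict(net, cohort, est, atlas, rows = 41:60)
fidelity_report(synth, lapply(cohort$subjects[41:60], `[[`, "tau"), atlas)
#> Synthetic tau PET fidelity (n = 20 subjects)
#>   Corr_AVG = 0.6138
#>   MAPE     = 19.19%
#>   MAE      = 0.2630 SUVR
#>   SSIM     = 0.7606
```

`Corr_AVG` is the mean across ROIs of the across-subject Pearson
correlation between synthetic and true regional SUVR — the headline
fidelity number (1 = perfect regional ranking of subjects). MAPE/MAE are
voxel-wise errors inside the brain mask on the SUVR scale, and SSIM is the
windowed structural-similarity index (1 = identical volumes). Ten epochs
on 40 phantom subjects already recover most of the between-subject
regional variance; on cohorts whose MRI carries no tau signal, the
conditioning-ablated variant (`coma_unet(..., ablate_conditioning =
TRUE)`) collapses to near-zero Corr_AVG while the full model does not —
the package's core demonstration that covariate conditioning, not the
MRI alone, carries the subject-specific tau signal.

A thin command-line interface wraps the same functions
(`inst/cli/tausynth simulate | aux | train | synthesize | evaluate |
crossval | downstream`).

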
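# dcenms

Pharmacokinetic analysis of dual gradient-echo (DGE) dynamic
contrast-enhanced MRI, for imaging scientists studying brain-tumor
microvasculature in small-animal models. The package covers the full
chain from raw paired-echo signals to vascular parameter maps:

1. **Concentration estimation.** The change in longitudinal relaxation
   rate ΔR1(t) — the contrast-agent concentration surrogate — and the
   local tip angle are inverted in closed form from the two spoiled
   gradient-echo signals; at echo-time ratio μ = 2 the estimate is exactly
   invariant to T2\* dynamics and receiver gain.
2. **Nested model selection (NMS).** Voxel-wise least-squares fits of
   three physiologically nested models — Model 1: C_t = v_p·C_aif/(1−Hct);
   Model 2 adds K^trans·∫C_aif (Patlak); Model 3 adds the back-flux kernel
   e^(−k_ep(t−λ)) (extended Patlak/Tofts) — with sequential F-tests at 95%
   confidence labeling each voxel by its number of estimable parameters
   (v_p; +K^trans; +k_ep, v_e = K^trans/k_ep).
3. **Population AIF.** A parametric bolus shape scaled so a normal
   reference region (caudate putamen analog) fits to exactly v_p = 1%,
   plus an exponential dispersion operator for robustness experiments.
4. **Adaptive models.** Raw-signal feature engineering (tail-normalized,
   down-sampled dual-echo profiles; 190 features at the 400-frame
   protocol) and four shallow neural networks trained by
   Levenberg–Marquardt — one NMS regressor/classifier with
   knowledge-based class-separation thresholds, three parameter
   regressors — validated by tenfold study-level nested cross-validation
   with rank-based ROC/AUC, Pearson r and adjusted R². Prediction needs
   no AIF.
5. **Digital phantom.** A rat-brain-like simulator (128×64×3, 400 frames
   at 1.55 s, bolus at frame 15 by default) with ground truth for every
   intermediate quantity, so each stage is testable without scanner data.

## Worked example

Simulate a compact phantom study, run the conventional arm, and train the
adaptive bundle on its own output:

```r
library(dcenms)

spec  <- compact_phantom_spec()          # 24 x 16 x 1, 300 frames, SNR 20
study <- make_phantom_study(spec, seed = 8)
res   <- analyze_study(study)            # dR1 + AIF normalization + NMS

res$aif
#> <aif_trace> 300 points over 463.4 s, peak 6.54 s^-1, hct 0.45,
#>   normalized (vp_ref = 0.01, scale = 6.539)
res$nms
#> <nms_fit> 232 voxels: Model 1 185 | Model 2 37 | Model 3 10 (alpha = 0.05)

glance(res$nms)
#> # A tibble: 1 x 8
#>   n_voxels n_model1 n_model2 n_model3 median_vp median_ktrans median_ve alpha
#>      <int>    <int>    <int>    <int>     <dbl>         <dbl>     <dbl> <dbl>
#> 1      232      185       37       10    0.0208        0.0262     0.131  0.05
```

The true whole-blood bolus peaks at 6 s⁻¹; the reference-normalized scale
(6.54 here) recovers it to within the reference region's noise, and the
model-choice counts track the phantom's generating regions (191 normal,
27 rim, 14 core in this draw) up to F-test noise at SNR 20.
`tidy(res$nms)` returns the per-voxel table (label, v_p, K^trans, k_ep,
v_e, per-model residuals); `autoplot(res$nms)` draws the maps.

Features and adaptive models:

```r
ft     <- featurize_study(study, grid = feature_grid(300, l1 = 20, step = 12))
tab    <- build_training_table(study, res$nms, study_id = 1,
                               grid = feature_grid(300, l1 = 20, step = 12))
bundle <- train_adaptive_bundle(tab, seed = 1)
bundle
#> <am_bundle> NMS net 10 hidden, PK nets 7 hidden;
#>   thresholds 1-2=1.255, 1-3=1.255, 2-3=1.256
#>   missing nets: ve
pred   <- predict_adaptive(bundle, ft)   # no AIF needed at prediction time
```

A single compact study contains only ~10 back-flux voxels — too few to
train the v_e regressor, so the bundle flags it absent; cohort-scale
training supplies that stratum. A cohort-level evaluation
(`make_cohort()` + `nested_cv()`) returns an
`ncv_report` whose `tidy()`/`glance()`/`autoplot()` methods give per-fold
and aggregate AUC, Pearson r and adjusted R².

A thin command-line wrapper over these functions ships in
`inst/cli/dcenms.R` (subcommands `simulate`, `estimate-dr1`, `fit-nms`,
`featurize`, `train-ams`, `predict`, `evaluate`).

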
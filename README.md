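# dce2tcm

Quantitative pharmacokinetic analysis of prostate dynamic contrast-enhanced
(DCE) MRI, comparing the standard Tofts model with a spatial two-tissue
compartment model (2TCM).

## What it does, for whom

DCE-MRI tracks a gadolinium bolus with repeated T1-weighted imaging. The
clinical standard fits each voxel's concentration curve with the Tofts
model,

    C(t) = Ktrans ∫₀ᵗ Cp(τ) e^{-(t-τ) kep} dτ,

extracting the transfer constant Ktrans (min⁻¹) and efflux rate
kep = Ktrans/ve. Tumors, however, mix a rapidly enhancing vascularized
fraction with slowly exchanging stroma inside single voxels, and one
compartment often fits poorly. The 2TCM adds a second exchanging
compartment,

    C(t) = ∫₀ᵗ Cp(τ) [K₁trans e^{-(t-τ) kep¹} + K₂trans e^{-(t-τ) kep²}] dτ,

fitted in the asymmetric parameterization K₂trans = ε·K₁trans,
kep² = kep¹ + λ (λ ≥ 0) so the optimum is unique, then relabeled so
K₁trans is always the larger amplitude. Because the Tofts model is the
ε = 0 special case, the 2TCM fit is seeded with the voxel's Tofts solution
and its RMSE can never be worse — the paired RMSE comparison then measures
what the second compartment genuinely explains.

The package is aimed at quantitative-MRI researchers: it provides VFA T1
mapping, nonlinear SPGR signal↔concentration conversion, AIF extraction
(Cp = Cb/(1 − Hct), Hct = 0.42), exact exponential-convolution forward
models, bounded multistart Levenberg–Marquardt fitting, parametric map
assembly, ROI statistics including a false-positive ROI selection rule
(cancer mean Ktrans minus one SD as cutoff), and the statistical battery
for model comparison (paired t-test, Pearson correlation, ANOVA + Tukey
HSD, ROC/AUC with Hanley–McNeil CIs, combined-parameter logistic
regression). A seeded digital phantom emulating the acquisition (60 frames
at 8.3 s, flip 10°, six-angle VFA) makes the whole chain testable without
patient data.

## Worked example

```r
library(dce2tcm)

spec <- phantomSpec(seed = 7)          # study-conditions phantom, 1% noise
ph   <- buildPhantom(spec)
ph$dynamic
#> DynamicSeries: 32x32x3 voxels, 60 frames (8.3 s/frame)
#>   TR = 4.60 ms, flip = 10.0 deg, 4 baseline frames

aif <- ph$groundTruth$aif
aif
#> AIF (synthetic): 60 frames, Hct = 0.42, peak Cp = 5.09 mM at t = 0.69 min

t1map <- fitVFAT1(ph$vfa, mask = ph$roiMasks > 0)
conc  <- signalToConcentration(ph$dynamic, t1map)
curve <- concentration(conc)[6, 6, 1, ]   # one cancer voxel

fitTofts(curve, aif)
#> KineticFit [tofts]: rmse = 0.0314 mM, converged = TRUE
#>    ktrans = 0.2421, kep = 0.6239, ve = 0.3881

fit2TCM(curve, aif)
#> KineticFit [2tcm]: rmse = 0.01925 mM, converged = TRUE
#>    k1trans = 0.2501, kep1 = 1.16, k2trans = 0.04357, kep2 = 0.1676,
#>    ve1 = 0.2156, ve2 = 0.26, eps = 5.74, lam = 0.9925
```

The voxel's ground truth is K₁trans = 0.25, kep¹ = 1.2, K₂trans = 0.05,
kep² = 0.2 min⁻¹: the single-compartment fit blurs the two pools into an
intermediate kep ≈ 0.62 with a 60% larger RMSE, while the 2TCM recovers
both compartments from the noisy curve. `runPipeline(pipelineConfig(),
"out/")` runs the same chain for every ROI voxel and writes parametric
maps (NIfTI), ROI summaries (CSV) and the statistics report (JSON).

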
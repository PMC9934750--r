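---
title: "Quantitative prostate DCE-MRI with a two-tissue compartment model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative prostate DCE-MRI with a two-tissue compartment model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dce2tcm)
```

## The problem

Dynamic contrast-enhanced (DCE) MRI follows a gadolinium bolus through
tissue with repeated T1-weighted imaging. In the prostate, the standard
quantitative analysis fits each voxel's concentration curve with the Tofts
model, a single well-mixed extravascular extracellular space (EES)
exchanging with plasma:

$$C(t) = K^{trans} \int_0^t C_p(\tau)\, e^{-(t-\tau)k_{ep}}\, d\tau,$$

where $K^{trans}$ (min$^{-1}$) is the plasma-to-EES volume transfer
constant, $k_{ep} = K^{trans}/v_e$ the efflux rate, $v_e$ the EES volume
fraction, and $C_p$ the arterial input function (AIF). Tumor tissue is
heterogeneous at the sub-voxel scale — a rapidly enhancing vascularized
fraction coexists with slowly exchanging stroma — and a single-compartment
fit can be visibly poor, biasing the extracted parameters.

This package implements, alongside the Tofts model, a spatial two-tissue
compartment model (2TCM) in which each voxel holds one fast and one slow
exchanging compartment:

$$C(t) = \int_0^t C_p(\tau)\left[K_1^{trans} e^{-(t-\tau)k_{ep}^1}
        + K_2^{trans} e^{-(t-\tau)k_{ep}^2}\right] d\tau.$$

The two-exponential sum is symmetric under swapping the compartment
labels, so the raw least-squares problem has two equivalent minima. For a
unique fit the model is rewritten in an asymmetric form,

$$C(t) = K_1^{trans} \int_0^t C_p(\tau)\, e^{-(t-\tau)k_{ep}^1}
        \left[1 + \epsilon\, e^{-(t-\tau)\lambda}\right] d\tau,$$

with $K_2^{trans} = \epsilon K_1^{trans}$, $k_{ep}^2 = k_{ep}^1 + \lambda$
and $\lambda \ge 0$ enforced in the optimizer. Since $\epsilon$ may exceed
1, either compartment can carry the larger amplitude; after fitting,
`canonicalize2TCM()` relabels so that $K_1^{trans}$ is always the larger
transfer constant with its paired efflux rate as $k_{ep}^1$, which makes
parameters comparable across voxels. At exactly equal amplitudes the
faster efflux rate takes the "1" label (a tie essentially never hit by
continuous data; the rule only pins down determinism).

Because the Tofts model is the $\epsilon = 0$ special case, the 2TCM is a
strict superset: with proper optimization its residual can never exceed
the Tofts residual. The package enforces this by seeding the 2TCM
multistart with the voxel's own Tofts solution at $\epsilon = 0$, so the
nesting inequality RMSE(2TCM) $\le$ RMSE(Tofts) holds by construction for
every fitted voxel, and the paired comparison of the two RMSE maps is a
meaningful check of how much the second compartment actually buys.

## From signal to concentration

The dynamic series is converted to concentration through the spoiled
gradient echo (SPGR) signal equation

$$S = M_0 \sin\alpha \frac{1 - E_1}{1 - E_1\cos\alpha},
  \qquad E_1 = e^{-TR/T_1},$$

inverted nonlinearly frame by frame rather than linearized. Pre-contrast
$T_{10}$ comes from a variable flip angle (VFA) acquisition at 3, 5, 10,
15, 20 and 30 degrees (TR 12 ms): the classic DESPOT1 regression of
$S/\sin\alpha$ on $S/\tan\alpha$ (slope $E_1$) gives the estimate, polished
by bounded Levenberg–Marquardt on the SPGR equation itself. Voxels whose
regression slope falls outside $(0,1)$ — all-zero or pathological signals —
are flagged invalid, never silently zeroed.

$M_0$ is calibrated per voxel from the average of the pre-contrast frames
(default: every frame before the bolus-arrival time, 4 frames at the
default settings) together with $T_{10}$. Each post-contrast frame is then
inverted for $E_1(t)$, and

$$C(t) = \frac{1/T_1(t) - 1/T_{10}}{r_1},$$

with relaxivity $r_1 = 5.5\ \mathrm{s^{-1}mM^{-1}}$ by default (a
gadobenate-class agent at 3 T). The relaxivity multiplies concentration
everywhere, so in round-trip validation its exact value cancels; for
absolute quantification on real data it should be set to the agent in use.
Frames whose signal leaves the invertible range of the SPGR equation
(e.g. negative magnitude after noise) are flagged `NA` for that frame only.

The AIF is the unweighted voxel mean of a blood ROI on the concentration
series, divided by $1 - \mathrm{Hct}$ with hematocrit 0.42 by default:
$C_p(t) = C_b(t)/(1-\mathrm{Hct})$. No partial-volume, inflow or dispersion
correction is applied.

## The convolution core

All forward models reduce to $\int_0^t C_p(\tau)e^{-k(t-\tau)}d\tau$.
`expConvolve()` treats the sampled $C_p$ as piecewise linear and integrates
each interval in closed form, chaining intervals through the exact
recursion $I_{i+1} = I_i e^{-k\Delta t} + a_i$ (a linear recurrence
evaluated by `stats::filter` on uniform grids). The result is exact for the
interpolant — there is no quadrature error to trade against the 8.3 s
frame spacing — and the small-$k\Delta t$ regime uses series expansions of
$(1-e^{-x})/x$ and $(1-e^{-x}(1+x))/x^2$ to avoid cancellation, so $k = 0$
degenerates smoothly to the cumulative trapezoid integral.

The validation suite compares this against a brute-force trapezoidal
convolution on a refined grid. One numerical subtlety is documented here
because it shapes the tests: a trapezoidal reference on a 100×-refined
grid carries its own $O(h^2)$ quadrature error, about $1.2\times10^{-6}k$
in relative terms at the bolus rise. Below $k \approx 0.8\ \mathrm{min^{-1}}$
that reference is converged beyond the $10^{-6}$ comparison tolerance and
is used directly; faster rates (up to $3\ \mathrm{min^{-1}}$) are checked
against a 1000×-refined reference at the same tolerance, where the
implementation agrees to $\sim 4\times10^{-8}$. The two-term (explicit
two-exponential) and factored (asymmetric) evaluations of the 2TCM are
also verified to agree to $10^{-12}$ on a thousand random parameter sets
— they differ only in parameter arithmetic, which is the point of the
check.

## Fitting

Per-curve fits are bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`, ftol/ptol $10^{-10}$, max 500 iterations) in
concentration space, the space in which the models are written. Bounds are
physiologically generous without flat tails: transfer constants in
$[0,5]\ \mathrm{min^{-1}}$, efflux rates in $[0,10]\ \mathrm{min^{-1}}$,
$\epsilon \in [0,100]$, $\lambda \in [0,10]\ \mathrm{min^{-1}}$.

The Tofts fit uses three fixed starts spanning slow to fast enhancement.
The 2TCM fit is seeded from the voxel's Tofts solution with five
deterministic starts: the exact Tofts point at $\epsilon=0$ (nesting
guarantee), a near-Tofts start with a small second pool, and three spread
starts covering slow-first/dominant-fast, balanced, and strongly
asymmetric configurations. Deterministic starts rather than random jitter
keep voxelwise maps bit-reproducible without threading RNG state through
the fitting layer. The best sum of squares wins; the convergence flag
reports the winning start's optimizer status. An all-zero curve
short-circuits to a zero-amplitude fit with zero RMSE, converged.

On the noiseless default phantom this recovers every kinetic parameter to
better than $10^{-10}$ relative, and a grid-search oracle confirms the
Tofts minimizer lands in the global basin.

## Parametric maps, ROIs and the false-positive rule

`fitVolume()` fits only the slices that carry ROIs, writing `NA` sentinels
elsewhere (never zero, which would masquerade as a fitted value). ROI
summaries are arithmetic means per parameter over the ROI voxels, ignoring
sentinels.

High-$K^{trans}$ tissue is not necessarily cancer. The false-positive
selection rule formalizes how such regions are picked for comparison: the
cutoff is the nearby cancer ROI's mean $K^{trans}$ minus `sdMultiplier`
sample standard deviations (default 1, configurable since the multiplier
is a free choice), and every candidate voxel at or above the cutoff is
selected, ties inclusive. By construction the selected ROI's mean
$K^{trans}$ is close to the cancer mean, which is what makes it a useful
foil: discrimination must then come from the other parameters (in
practice the fast $K_1^{trans}$).

## The statistical battery

The accompanying statistics mirror a standard model-comparison workflow:

* paired t-test on voxelwise RMSE of the two models (ROI-level pairing is
  available by aggregating first);
* Pearson correlation between Tofts and 2TCM parameters;
* one-way ANOVA with Tukey HSD (Tukey–Kramer for unequal $n$) across
  cancer / normal / false-positive classes;
* ROC analysis as the Mann–Whitney AUC with ties credited ½ and a
  Hanley–McNeil 95% confidence interval, clipped to $[0,1]$;
* binary logistic regression (maximum likelihood, intercept, no
  regularization) to combine parameters, scored by the in-sample linear
  predictor's AUC, with perfect separation flagged rather than hidden.

Standard tests delegate to base R (`t.test`, `cor.test`, `aov` +
`TukeyHSD`, `glm`): `glm`'s iteratively reweighted least squares *is* the
canonical logistic MLE, and the fit's score-vector norm is computed and
reported so convergence is checked against the gradient, not just the
deviance. The AUC and its Hanley–McNeil interval are computed directly
from ranks (no installed package provides that interval). Degenerate
inputs are defined, not crashed: identical paired vectors give $p = 1$;
constant nonzero differences are flagged; zero-variance correlation is
rejected explicitly.

## The digital phantom

No patient data ship with the package; every stage is exercised by a
seeded digital phantom whose defaults are the study conditions: 60 dynamic
frames at 8.3 s (8.3 min total), flip angle 10°, TR 4.6 ms, six-angle VFA
series at TR 12 ms, hematocrit 0.42, 32×32×3 voxel grid. The default
geometry places four rectangular regions on the first two slices — cancer,
normal tissue, a false-positive candidate, and a blood ROI carrying the
input function — leaving the third slice empty to exercise slice gating.

Ground-truth kinetics follow the qualitative ordering the analysis is
meant to detect: cancer has a dominant fast plus a slow compartment
($K_1^{trans} = 0.25$, $k_{ep}^1 = 1.2$, $K_2^{trans} = 0.05$,
$k_{ep}^2 = 0.2\ \mathrm{min^{-1}}$), normal tissue the same structure
with lower rates throughout (0.08 / 0.6 / 0.02 / 0.15), and the
false-positive region is a single-compartment tissue whose $K^{trans} =
0.22\ \mathrm{min^{-1}}$ sits near the cancer value with no strong fast
pool. These are generator defaults chosen to be physiologically plausible,
not measured claims. T1 values are 1.4 s for prostate tissue and 1.66 s
for blood.

The AIF is a parametric population bolus — a gamma-variate first pass
(shape 2, time scale 0.12 min, peak 5 mM) plus a saturating washout
plateau (1 mM, time constant 0.5 min), both starting at a configurable
bolus arrival of 30 s — because a patient-measured iliac-artery curve is
not publishable as code. Its closed-form integral (incomplete gamma plus
exponential) anchors the generator tests.

Noise is additive Gaussian on the magnitude signal by default, with a
Rician option ($\sqrt{(S+n_1)^2 + n_2^2}$). The default level,
`noiseSd = 1.5` at $M_0 = 1000$, is about 1% of the peak dynamic signal:
the SPGR signal at TR 4.6 ms / 10° is only a few percent of $M_0$, so this
corresponds to a pre-contrast tissue SNR near 20, typical of 3 T prostate
DCE. Above SNR 20 the Rician and Gaussian phantoms yield fitted parameters
differing by under 2%, so the Gaussian default is adequate outside the
low-SNR regime.

What the phantom does *not* emulate — and therefore what passing tests do
not establish about patient data — includes anatomically realistic
geometry, B1 inhomogeneity, motion, water–fat separation artifacts, AIF
dispersion and delay, and inter-voxel parameter heterogeneity within a
region (region curves are constant in the noiseless limit, which is
exactly what makes exact recovery a sharp test).

## Problem sizes and reproducibility

The shipped validation fits the full 32×32×3 phantom (216 tissue voxels,
60 frames) noiselessly and at the default noise level, runs 500-replicate
VFA noise studies, $10^4$-per-class binormal ROC simulations, and
20,000-draw permutation cross-checks — sizes chosen so the whole suite
runs on a laptop in a few minutes while still estimating every quantity
with comfortable Monte-Carlo margin. Every stochastic step is seeded;
`buildPhantom()` restores the caller's RNG state, and the pipeline writes
a manifest from which identical CSV outputs are regenerated byte for byte
(verified by checksum in the tests).

## Known limitations

* No plasma-volume ($v_p$) term: the implemented models contain none, so
  strongly vascularized voxels fold blood signal into the fast
  compartment.
* In-sample AUC for combined parameters (no cross-validation), appropriate
  for description, optimistic for prediction.
* The VFA fit assumes the nominal flip angles are achieved; no B1
  correction.
* File-mode ingestion expects NIfTI with water-only magnitude images;
  DICOM conversion and water–fat reconstruction are out of scope.
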
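---
title: "Methods: multimodal spectral classification of brain tumor tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal spectral classification of brain tumor tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliospec)
```

## The problem

Fiber-probe optical spectroscopy can discriminate glioma from normal brain
tissue without labels: Raman scattering reads out relative biochemical
composition (lipids, amino acids, nucleic acids, amide bands), diffuse
reflectance reads out hemoglobin oxygenation and scatterer size, and
fluorescence localizes an EGFP-labelled tumor. `gliospec` implements the
complete analysis chain for such measurements — preprocessing, univariate
(ratiometric/slope) classifiers, a PCA-LDA classifier driven by the area
under the ROC curve (auROC), stratified cross-validation, and multimodal
score fusion — together with a synthetic cohort generator that reproduces
the statistical structure the analysis assumes, so every stage is testable
without access to measured animal data.

## Preprocessing

Every recorded spectrum is first divided by the fiber-probe system
transmission (`correct_transmission`). Then:

* **Raman.** The broad NIR-fluorescence background is estimated by
  iterative sixth-order modified polynomial fitting
  (`remove_baseline_vancouver`): fit by least squares, compute the residual
  standard deviation `dev` of the working data about the fit, truncate
  values above `fit + dev`, and refit until the fitted curve changes by
  less than `tol` (default `1e-4` of the intensity scale, cap 100
  iterations). Points flagged as peaks by the first fit are excluded from
  subsequent fits. The `dev` term matters: without it the converged
  baseline tracks the *lower envelope* of the noise rather than its mean,
  biasing baselines low by roughly one noise standard deviation and
  inflating normalized band heights by several percent. The fit runs on the
  axis mapped affinely to $[-1, 1]$, so results are invariant to affine
  axis rescaling and the order-6 normal equations stay well conditioned.
  Negative corrected intensities are kept (so
  `baseline + corrected == input` exactly); a display-only floor is
  available. The corrected spectrum is normalized to the interpolated peak
  height at 1445 cm$^{-1}$ (CH$_2$/CH$_3$ deformations, dominated by
  lipids). Peak *height* rather than band area is used — the minimal
  reading when no integration window is specified — with an optional
  half-window average.
* **Reflectance.** Division by the lamp emission spectrum, normalization to
  the intensity at 570 nm (an oxy/deoxy-hemoglobin isosbestic point, which
  makes the normalization insensitive to oxygenation), and cropping to
  540–733 nm, the window free of EGFP absorption/emission contamination.
* **Fluorescence.** Transmission correction only.

Transmission correction is applied *before* baseline removal (physical
ordering: the instrument acts on the emitted light).

## The classifier

`fit_spectral_classifier` is the package's central fitting function and
returns a classed model object with the usual `print`, `summary`, `coef`,
`predict` and `plot` methods.

1. **PCA.** Mean-centered PCA of the preprocessed intensity matrix, keeping
   the first 15 components (deterministic sign convention: each loading's
   largest-magnitude element is positive).
2. **Component selection** (`select_pcs`). The selection criteria
   ("discriminates well on its own, and improves the combined classifier")
   are formalized as greedy forward selection: components are ranked by
   single-component auROC (after orientation); the best seeds the set, and
   each subsequent component is the one whose addition maximizes the
   trained random-search combination's auROC. The per-component auROCs are
   exposed so a user can override the selection (`pc_indices`).
3. **Random-search discriminant** (`random_search_lda`). Each iteration
   draws one coefficient per selected component uniformly in $[0, 100]$,
   scores every sample with the weighted sum of its PC scores, computes the
   auROC (the Mann–Whitney statistic: the fraction of (normal, tumor) pairs
   ordered correctly, ties 0.5), and keeps the best combination so far. The
   search stops after `stop_n = 500` consecutive non-improving draws.
   Because PC signs are arbitrary, each component is first oriented so its
   marginal auROC is $\ge 0.5$; the nonnegative coefficient range then
   spans the useful search directions. "PC loading" is interpreted as the
   per-spectrum projection coefficient (PC score), the only reading that
   yields one scalar score per spectrum.
4. **Operating threshold.** The ROC curve's suggested threshold maximizes
   Youden's $J = \text{sens} + \text{spec} - 1$ (ties broken toward higher
   specificity, then the higher threshold, and the cutoff is placed halfway
   into the score gap). Reported sensitivity/specificity are training-set
   values at this threshold.

Two deliberate design choices where the procedure was genuinely open:

* **Warm starts.** Before the random draws, each axis-aligned candidate
  (one feature at a time) is evaluated deterministically. This leaves the
  stop rule and best-so-far semantics untouched but guarantees the fused or
  combined classifier is never worse than its best single feature — a
  property the pure random search attains only with high probability.
* **Two stop rules.** The greedy selection runs many candidate searches
  whose purpose is only to *rank* candidates, so they use a smaller stop
  rule (`stop_n_select = 200`); the final model search uses the full
  `stop_n = 500`.

## Cross-validation and fusion

`kfold_cv` uses stratified folds (for 13 + 13 samples and $k = 4$:
per-class fold sizes 4, 3, 3, 3 — the closest stratified tiling of 13 by
4 folds). Component selection and the random search are retrained on the
training folds only; the held-out fold is scored with the trained
combination and its auROC recorded. PCA itself is fitted once on all
samples — the cross-validated quantity is the selection + discriminant
pipeline operating on a fixed 15-dimensional representation.
On label-independent data the held-out auROC averages 0.5 while the
training auROC is far above it; this overfitting gap is exactly why the
cross-validated numbers are the ones to trust, and it is asserted by the
test suite. Grouped (per-animal) stratification is not applied by default,
matching a per-sample fold description; per-animal random effects are
present in the synthetic cohort so a grouped variant can be studied.

`fuse_scores` reuses the identical random-search routine with per-modality
classifier scores as the features, yielding one fused score per sample.
Multimodal cross-validation shares one fold assignment across modalities:
per fold, each modality is retrained on the training folds, the fold-train
scores are fused, and the fused combination scores the held-out samples.

## Univariate scores

* `ratiometric_score`: intensity ratio between two axis positions
  (reflectance 570/690 nm; Raman 1450/985 and 1450/2030 cm$^{-1}$).
* `slope_score`: OLS slope of intensity vs wavelength over 625–730 nm,
  where the reduced scattering coefficient (hence nuclear size) shapes
  normalized reflectance.
* `egfp_peak_intensity`: the 510 nm EGFP emission peak relative to 660 nm
  tissue autofluorescence.

`correlate` provides the Fig-4-style linear fits (Pearson's $r$, $R^2$,
OLS slope/intercept), including the fixed-intercept variant in which only
the slope is fitted through a given intercept (the mean normal EGFP
readout) and $R^2$ is computed from residuals about that line.

## The synthetic cohort

`gen_cohort` emulates the study layout: 13 paired normal/tumor experiments
over 8 animals (round-robin, at most 3 sessions each), per-animal
multiplicative random intercepts, tumor radial size growing by
$\sim 280\ \mu m$ per session, and all modalities per experiment.
Generators are deterministic given the seed; `effect_scale = 0` makes the
two class-conditional distributions exactly identical (the null cohort
used to verify that cross-validated auROCs collapse to chance).

* **Raman** (600–2100 cm$^{-1}$, 2 cm$^{-1}$ steps — the sampling is an
  engineering choice; the instrument's true sampling is not documented):
  sums of Gaussian bands at 950, 1000, 1030, 1060, 1210, 1445, 1575, 1600,
  1650 and 2030 cm$^{-1}$ with class-dependent amplitudes relative to the
  1445 cm$^{-1}$ band (healthy higher at 950/1210, tumor higher at
  1650), a smooth positive polynomial NIR background (3× the band scale),
  per-band lognormal biological variation (`sdlog = 0.06`) and additive
  shot-like noise (sd $= 0.3\sqrt{I}$).
* **Reflectance** (400–733 nm, 1 nm):
  $\text{lamp}(\lambda)\,e^{-b\,\mu_c(\lambda)}\,(1 + m_c(\lambda - 584)_+)$
  where $\mu_c$ mixes hemoglobin-like oxy/deoxy pseudo-extinction curves by
  the class oxygen saturation (normal 0.85, tumor 0.45 — hypoxia). The two
  pseudo-extinction curves are constructed so they are *exactly* equal at
  452, 529, 545, 570 and 584 nm (their difference is a degree-5 polynomial
  with those roots, Gaussian-damped) and so the oxy curve peaks near 540
  and 575 nm; deoxy dominates above 584 nm, giving tumor its stronger
  600–730 nm relative absorption. Gaussian-sum curves are used instead of
  literature hemoglobin tables to keep the constraints exact by
  construction and the package download-free. The scattering trend enters
  as a hinge beyond the last isosbestic point so those equalities survive
  the class-dependent slope; the tumor slope is calibrated by root finding
  at construction so the realized noise-free 625–730 nm normal:tumor slope
  ratio equals the configured 2.6 exactly.
* **Fluorescence** (460–750 nm, 1 nm): an autofluorescence shape plus an
  EGFP Gaussian at 510 nm with amplitude linear in tumor size
  (0.004 relative units per µm), so the 510/660 readout increases
  monotonically with size.

Default effect sizes and noise levels were chosen once so that the default
cohort is clearly separable (cross-validated auROC $\gtrsim 0.9$); they are
engineering choices — the study's real-data auROC values (92/93/97%
training, 86/92/95% cross-validated, and the univariate 77/79/82/73%
values) were measured on an undeposited in-vivo dataset and are structural
templates, not reproduction targets. What passing tests demonstrate is that
the *machinery* behaves correctly: exact auROC computation, unbiased
baseline recovery, near-Fisher discriminant search, chance-level CV on null
data, and recovery of every constraint built into the generator. The
synthetic data deliberately omit several features of real spectra: cosmic
rays, wavelength-calibration drift, detector saturation, heteroscedastic
read noise, and any nonlinearity between tumor size and EGFP signal.

## Numerical choices

* auROC is computed from ranks (ties averaged), exactly the pair-counting
  statistic; the ROC trapezoid equals it to machine precision.
* The baseline fit solves the least-squares problem by QR on the rescaled
  Vandermonde basis; order-6 on $[-1, 1]$ is well within double precision.
* Degenerate inputs are explicit: single-class score sets, zero-variance
  PCA input and non-positive normalization references are errors;
  all-constant search features return auROC 0.5; non-convergent baselines
  return `converged = FALSE` rather than throwing.
* All stochastic stages take explicit seeds, derived deterministically from
  one master seed per study; identical seeds give bit-identical reports.

## Problem sizes used by the test suite

Tests run at the study's native scale (13 + 13 samples, 15 PCs, 4-fold
CV): 500-set ROC oracle checks, 100-spectrum baseline recovery, 100-seed
discriminant-vs-Fisher comparison, 50-seed null-cohort guard, 20-seed
end-to-end recovery, and a 60-draw-per-class band-height round trip (the
batch size keeps the Monte-Carlo error of the class mean near 1% so the 5%
round-trip bound genuinely measures preprocessing bias, not sampling
noise).

## Known limitations

* The Beer–Lambert-style reflectance model is a statistical stand-in, not
  radiative transfer; absolute intensities are arbitrary.
* Sensitivity/specificity are reported at the training-set Youden
  threshold; with 13 + 13 samples they are optimistic relative to the
  cross-validated auROC (which is the honest figure).
* The random search explores only nonnegative coefficients of
  sign-oriented features; suppression effects requiring opposite-sign
  coefficients of marginally concordant features are outside its search
  space (the Fisher comparison shows this costs little on realistic
  feature structures).
* No cosmic-ray despiking, wavelength calibration, or vendor file formats.
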
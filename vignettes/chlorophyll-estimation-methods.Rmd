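---
title: "Estimating canopy chlorophyll from hyperspectral imagery with spectral-textural feature combinations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating canopy chlorophyll from hyperspectral imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The estimation problem

Leaf chlorophyll content (LCC) of banana canopies, measured in SPAD units, is
a proxy for nitrogen and overall nutritional status. A UAV-mounted
hyperspectral camera observes each plot as a reflectance cube — here 164
bands between 350 and 1000 nm at ~4 nm spacing — while ground truth comes
from a modest number of SPAD-meter points (74 in the emulated design: 30 in
an early-stage plot, 44 in a fruit-development plot), each the average of
many readings over a cluster of plants.

`chlorotex` implements the full analysis from cube + point table to a
per-pixel chlorophyll map:

1. **Segmentation** — NDVI thresholding separates banana canopy from soil;
   only vegetation pixels feed every later step.
2. **Spectral features** — twenty vegetation indices (VIs), eleven built
   from blue/green/red/NIR bands and nine red-edge variants.
3. **Textural features** — the cube is PCA-transformed; eight Haralick
   statistics (MEA, VAR, HOM, CON, DIS, ENT, SEC, COR) are computed in
   sliding 3x3 gray-level co-occurrence windows on each of the first three
   component images, giving 24 texture features (TFs).
4. **ROI aggregation** — each ground point is represented by the mean of
   every feature over the masked-in pixels of its 50x50 window.
5. **Screening** — features are ranked against SPAD by |Pearson r| and by
   the maximal information coefficient (MIC); a strict 0.8 cutoff selects
   candidate predictors.
6. **Two-pair combination search** — every (VI, TF) pair is combined in
   ratio (`TF/VI`), normalized-difference (`(VI-TF)/(VI+TF)`) and
   difference (`VI-TF`) form — 160 combinations per form per PC image —
   and fitted linearly against SPAD.
7. **Multivariable models** — PLSR, adaptive regression splines, SVR and
   Gaussian process regression are compared across feature groups under
   10-fold cross-validation with pooled out-of-fold R2 and RMSE.
8. **Auxiliaries** — a red-edge band sweep (702-742 nm) locates the most
   informative red-edge wavelength; ethanol-extract absorbance equations and
   an exponential fit verify the SPAD calibration; the best model is applied
   per pixel to map chlorophyll.

Because the motivating field campaign's imagery is not publicly deposited,
the package ships a first-class synthetic scene generator
([`generate_scene()`]) with known per-pixel chlorophyll, so that every stage
is testable end to end and parameter-recovery claims can be validated
against ground truth.

## The synthetic scene generator

`scene_config()` defaults encode the emulated study conditions: a
300 x 650 px scene holding two plots of 50 px plant cells (6x5 and 6x8),
74 ground points split 30/44, chlorophyll 45-70 SPAD with the early plot in
the lower and the late plot in the upper sub-range, ~40% soil, and additive
band noise of 0.004 reflectance units.

**Leaf model.** Reflectance is an analytic curve: a visible baseline
(0.14) plus a logistic NIR ramp to 0.48 (the red edge, width 7 nm), minus
Gaussian absorption wells at 446, 550 and 682 nm. Chlorophyll acts twice:
well depth saturates as `lcc/(lcc + 30)`, and the ramp midpoint shifts
+0.25 nm per SPAD unit. This keeps the model dependency-free and
analytically checkable: red reflectance is provably monotone decreasing in
chlorophyll, and the inflection wavelength monotone increasing. A full
radiative-transfer model was deliberately avoided — the tests need closed-form
expectations more than spectro-physical fidelity.

**Why textures help, by construction.** Spectral retrieval at the plant
level is confounded by three realistic nuisance factors drawn per plant: a
leaf-structure factor scaling the absorption wells (sd 0.06), a red-edge
midpoint offset from canopy geometry (sd 0.8 nm), and a NIR scattering
amplitude (sd 0.08) with a spectral tilt (sd 0.15 per 100 nm). None of them
touches the scene's multiplicative brightness field, which is built as a
spatially autocorrelated field whose correlation with the chlorophyll field
equals `texture_corr` (default 0.6) and whose pixel-scale roughness
increases toward low chlorophyll (stressed canopies are more heterogeneous;
the roughness modulation is proportional to `texture_corr`, so an
uncorrelated brightness field carries no chlorophyll signal at all). The
brightness channel therefore carries information about chlorophyll that the
spectral channel cannot recover — the mean (MEA) texture reads the smooth
component and the contrast-type textures (CON, DIS, VAR, ENT) read the
roughness. This is the mechanism behind the package's reproduction of the
qualitative finding that VI+texture models beat VI-only models.

**Red-edge information center.** The ramp base (722.4 nm at zero SPAD,
+0.25 nm/SPAD) was chosen so that the signal-to-noise optimum of the
red-edge sweep — not the raw ramp midpoint, which sits a few nm higher —
falls at 730 nm for the default chlorophyll range. The spectral-tilt
nuisance penalizes bands on the NIR side of the midpoint (where the ramp is
nearly saturated and carries little chlorophyll signal), which is what gives
the sweep's R2 curve a genuine peak rather than a plateau.

**What the generator does not emulate.** No BRDF, shadows, atmosphere,
sensor PSF, or mosaicking artifacts; plant footprints are circles on a
grid; SPAD noise is Gaussian. Tests passing on these scenes demonstrate
that the pipeline's statistics and algorithms are correct and that its
qualitative conclusions follow from the stated mechanisms — they do not
certify performance on real UAV campaigns.

## Methodological choices

**Coordinates and ROIs.** Pixel coordinates are 1-based (row, col); readers
accept 0-based tables via `zero_based = TRUE`. An even 50-px window has no
center pixel: the convention is rows `[r-25, r+24]`, clipped at borders
(so a top-left corner point retains 25x25 = 625 pixels and a bottom-right
corner 26x26 = 676). ROI means use masked-in, finite pixels only; points
with empty ROIs are dropped and reported.

**Segmentation.** `derive_threshold()` scans every midpoint of the pooled
sorted NDVI sample of labelled pure-vegetation and pure-soil pixels and
minimizes the misclassification count, breaking ties toward the larger
threshold. "Vegetation" is the strict inequality `NDVI > t` — a pixel at
exactly the threshold is soil. Plot-specific thresholds (the emulated study
used 0.48 and 0.50) are supported via a plot raster; fixed thresholds can
be supplied in the pipeline config.

**Vegetation indices.** Three formula families printed ambiguously in this
literature are implemented in their canonical published forms: MSR uses the
square-root denominator `(N/R - 1)/sqrt(N/R + 1)`; the "modified
difference" family is the renormalized difference `(N - X)/sqrt(N + X)`;
the OSAVI family is `(1 + 0.16)(N - X)/(N + X + 0.16)`. RDVI is implemented
as the plain difference `Rnir - Rred`, exactly as this registry defines it,
and CI_green uses the 770/510 nm pair. Band slots resolve to the nearest
cube band (ties to the lower index) with the achieved offset recorded.

**Textures.** Gray levels default to G = 32 (the magnitude of MEA and VAR
depends on G, so it is exposed in the config); quantization is global
min-max binning over the scene's vegetation pixels so that ROI means are
comparable across points, and map-time quantization reuses the training
bounds. Co-occurrences accumulate the four distance-1 directions
symmetrically inside each 3x3 window; entropy uses log base 2; the Haralick
correlation is defined as 1 when a marginal variance vanishes. Textures are
computed per pixel and then ROI-averaged (the 3x3 window is chosen to
capture local detail); computing one GLCM per ROI would be the coarser
alternative. The sliding-window path is C++ (Rcpp) and is tested cell by
cell against a naive pairwise-counting oracle.

**MIC.** The estimator is the MINE-family statistic with equipartition of
one axis, dynamic-programming optimization of the other over clump
boundaries (superclumps capped at `c` times the column budget), grid sizes
bounded by `n^alpha`, and normalization by `log2(min(nx, ny))`; defaults
alpha = 0.6, c = 15. At small n the DP is verified against exhaustive grid
search. Different MINE implementations can disagree in the third decimal;
selection is thresholded, so this does not affect downstream behavior.

**Two-pair search.** The ratio form is `TF/VI` with the texture feature in
the numerator, as the combination method defines it. Non-finite
combinations are dropped per fit (never imputed) and fits retaining < 80%
of points are flagged. R2 is `1 - SS_res/SS_tot` and RMSE uses the 1/n
denominator. Ranking ties break lexicographically by (type, vi, tf) so
reports are deterministic.

**Cross-validation.** Folds are a seeded shuffle with round-robin
assignment (sizes differ by at most one; 74 points give four folds of 8 and
six of 7). Reported R2/RMSE are pooled out-of-fold — every point predicted
exactly once by a model that never saw it — which is stable at n = 74;
fold-wise values are also emitted. Standardization, inner hyperparameter
tuning (PLSR latent-variable count by inner 5-fold CV; SVR's C, gamma,
epsilon on a fixed grid) and spline/GPR fitting all happen strictly inside
the training folds; a shuffled-target test asserts the absence of leakage.
The default CV seed is 20240426 and is recorded with every result.

**Models.** PLSR is delegated to mixOmics (regression mode; with all
components it reproduces OLS, which is tested). The adaptive regression
splines are an additive piecewise-linear forward/backward implementation:
reflected hinge pairs added greedily up to 21 basis functions, then pruned
by GCV with penalty 2 per knot. SVR is e1071's epsilon-regression with an
RBF kernel. GPR is implemented in closed form with an isotropic RBF + noise
kernel; hyperparameters maximize the log marginal likelihood from five
seeded restarts around a median-distance initialization, and predictions
carry the full predictive standard deviation (latent + noise), validated by
a coverage test on draws from the model's own prior.

**SPAD verification.** Extract chlorophyll follows the 95%-ethanol
spectrophotometric equations `Ca = 13.95 A665 - 6.88 A649`,
`Cb = 24.96 A649 - 7.32 A665` (coefficients swappable for other solvents),
and the SPAD link is fitted as `LCC_lab = a exp(b SPAD)` by
Levenberg-Marquardt NLS initialized from the log-linear OLS fit.

## Problem sizes and determinism

The default synthetic scene is 300 x 650 px x 164 bands (~195k pixels);
unit tests use a 150 x 500 px scene with 24 points, and the acceptance
script generates five default scenes. All randomness flows through explicit
seeds into a private RNG stream that never perturbs the user's `.Random.seed`;
identical seeds reproduce scenes bit for bit.

## Known limitations

- The leaf model is qualitative; absolute index values are not comparable
  to field campaigns, and map ranges are validated against synthetic truth
  only.
- The texture advantage is generated by an explicit mechanism; real
  imagery may couple brightness and chlorophyll differently.
- MARS interactions (products of hinges) are not implemented; the additive
  form suffices for the feature sets used here.
- ENVI support covers BSQ/BIL float/integer cubes with wavelength headers;
  exotic interleaves or BIP files are out of scope.
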
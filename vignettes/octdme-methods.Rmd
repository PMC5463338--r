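---
title: "Classifying SD-OCT volumes for diabetic macular edema: methods and design"
author: "octdme"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying SD-OCT volumes for diabetic macular edema: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`octdme` implements a classical texture-based pipeline for deciding whether
a spectral-domain optical coherence tomography (SD-OCT) volume shows
diabetic macular edema (DME) or a normal macula. A volume is an ordered
stack of cross-sectional B-scans; the pipeline processes each B-scan
through four stages and then aggregates to a volume-level decision:

1. **Pre-processing** — speckle denoising, flattening of the retinal
   pigment epithelium (RPE), and cropping to a fixed anatomical window.
2. **Feature detection** — multiresolution local binary pattern (LBP) or
   histogram-of-oriented-gradients (HoG) descriptors on a 4-level Gaussian
   pyramid.
3. **Feature representation** — concatenated histograms, optionally
   PCA-reduced, optionally pooled per volume with a bag of visual words
   (BoW).
4. **Classification** — a per-B-scan classifier (linear SVM, RBF SVM, or
   random forest) with a majority vote across B-scans, or direct
   classification of the per-volume BoW histogram.

Evaluation uses leave-two-patients-out cross-validation on a class-balanced
cohort: each fold holds out one DME and one normal patient, and
volume-level sensitivity (SE) and specificity (SP) are accumulated over
folds.

Because no suitable clinical SD-OCT dataset is freely redistributable, the
package ships a synthetic phantom generator that emulates the statistical
structure the pipeline relies on. All tests and the worked examples run on
phantoms.

# Pre-processing

## Speckle model and denoising

Coherent imaging produces multiplicative speckle. The package models fully
developed speckle as per-pixel gamma gain with unit mean: for an image $x$
on $[0,1]$,

$$y = x \cdot g,\qquad g \sim \Gamma(L, L),\quad \mathbb E[g]=1,\
\operatorname{Var}(g)=1/L,$$

where $L$ is the classical "number of looks" (larger $L$ = weaker noise).
Phantom defaults use $L=4$ for denoiser stress-tests and $L=16$ for
classification experiments.

Six denoisers are implemented from their defining formulas, all with
symmetric (edge-inclusive) reflection at borders:

* **mean** and **median** over an odd $w\times w$ window;
* **Lee filter**: $\hat x = m + k\,(y - m)$ with local mean $m$, local
  variance $v$, $k = \max(0, v-\sigma^2)/v$, and the noise variance
  $\sigma^2$ estimated as the image-wide mean of local variances;
* **wavelet hard/soft thresholding**: an orthonormal Haar decomposition
  (2 levels by default) with detail coefficients thresholded hard
  ($c\,\mathbb 1[|c|>t]$) or soft ($\mathrm{sign}(c)\max(|c|-t,0)$) and the
  approximation band untouched. When no threshold is given, the universal
  threshold $t=\hat\sigma\sqrt{2\ln N}$ is used with $\hat\sigma$ from the
  median absolute deviation of the finest diagonal subband. The Haar
  transform is implemented in the package (exactly invertible for any
  image size, odd trailing samples carried through the approximation);
* **non-local means (NLM)**: $\hat x(i)=\sum_j w_{ij}y(j)/\sum_j w_{ij}$
  over an $s\times s$ search window with
  $w_{ij}=\exp(-\lVert P_i-P_j\rVert^2/h^2)$ on $p\times p$ patches.
  Defaults $p=3$, $s=9$, $h=0.5$: the bandwidth was fixed once so that the
  filter clearly improves PSNR at both $L=4$ and $L=16$ on phantoms
  without collapsing to the box mean.

A `PLUGIN` hook accepts any user function `f(img) -> img`, so external
denoisers (e.g. BM3D implementations) can be dropped into the pipeline
without changing anything downstream. PSNR is
$10\log_{10}(\mathrm{peak}^2/\mathrm{MSE})$ with the peak defaulting to the
declared intensity maximum.

## RPE flattening and cropping

The RPE is the brightest deep retinal band and serves as the anatomical
reference. Per column, a candidate RPE row is the argmax of the depth
profile smoothed with a 1-D Gaussian ($\sigma = 3$ px); columns whose
maximum is below 10% of the image maximum are dropped. A second-order
polynomial $r(x)=ax^2+bx+c$ is fitted to the candidates by RANSAC
(500 hypotheses of 3 points, inlier tolerance 3 rows, ties broken by lower
inlier squared error, final least-squares refit on the best consensus
set). Each column is then shifted **down by an integer** so the predicted
RPE lands on the deepest predicted row; integer shifts avoid interpolation
and therefore leave LBP codes intact, and vacated pixels are zero-filled.
The flattening reference is recomputed per B-scan with no cross-scan
smoothing.

Cropping keeps 325 px above the RPE row, the row itself, and 30 px below
(356 rows total) and a centered 340-px lateral window (left edge
$\lfloor(\mathrm{cols}-340)/2\rfloor$). The 356-row choice (rather than
355) is what makes the HoG descriptor sizes below come out exactly. If the
window extends above the image (shallow RPE, or phantoms smaller than the
clinical 1024-px depth), the missing rows are zero-padded and flagged.

# Feature detection

## Gaussian pyramid

Level 1 is the cropped B-scan; each next level is smoothed with the
separable binomial kernel $[1,4,6,4,1]/16$ and decimated to
$\lfloor n/2\rfloor$ by keeping even-indexed (0-based) rows/columns,
truncating any trailing odd sample. On the standard 356×340 window the
levels are 356×340, 178×170, 89×85, 44×42.

## LBP descriptors

For sampling pairs $(P,R)\in\{(8,1),(16,2),(24,3)\}$, each pixel compares
$P$ circular neighbors (bilinear interpolation; `>=` ties count as 1)
against the center, giving a $P$-bit code. Two mappings are provided:

* **riu2** (rotation-invariant uniform): codes with at most 2 circular
  transitions are bucketed by their count of ones, all others into one
  non-uniform bin — $P+2$ labels (10/18/26 for $P$=8/16/24);
* **u2** (uniform, not rotation invariant): $P(P-1)+3$ labels.

Per pyramid level the code image is split into non-overlapping patches and
each patch contributes an L1-normalized label histogram. The default
partition uses per-level grids 3×3, 2×2, 2×2, 1×1 — 18 patches across the
pyramid — giving descriptor lengths 180/324/468 for the three riu2
configurations. A fixed 32-px tiling mode is available behind a
configuration switch (it yields 140 patches on the standard window); the
18-patch grid is the default because it reproduces the published
per-B-scan descriptor sizes exactly, which are the only verifiable anchor
for the patch layout. Pixels within $R$ of the image border are excluded
from histograms.

## HoG descriptor

Per level: central-difference gradients (reflected borders); unsigned
orientation on $[0°,180°)$ split into 9 bins with magnitude-weighted
linear interpolation between adjacent bin centers; 4×4-px cells (floor
count, trailing pixels dropped); blocks of 2×2 cells stepped by one cell;
per-block L2 normalization with $\varepsilon=10^{-5}$. The per-level
length is $(\mathrm{cells}_r-1)(\mathrm{cells}_c-1)\cdot 36$:
266,112 / 63,468 / 15,120 / 3,240 on the four standard levels, 347,940
total. The "2×2 block with 1-px overlap" geometry is interpreted as
2×2-cell blocks at 1-cell stride — the only reading consistent with all
four per-level sizes.

`descriptor_length()` returns these lengths in closed form and every
extracted vector is checked against it.

# Feature representation

* **Histogram** — the concatenated per-B-scan descriptor as-is.
* **Histogram + PCA** — descriptors projected onto the top principal axes
  (SVD of the centered training matrix, component signs fixed so the
  largest-magnitude loading is positive). Defaults: 20 components for LBP,
  40 for HoG, clamped with a warning when a fold has fewer training
  B-scans.
* **Histogram + PCA + BoW** — a k-means codebook (k-means++ seeding, 10
  restarts, Lloyd iterations, 300 max) is learned on the PCA-reduced
  training B-scan vectors; each volume becomes the histogram of its
  B-scans' nearest-centroid assignments (ties to the lowest word index),
  summing to the volume's B-scan count. Codebook sizes 10/30/40/50 are the
  standard grid.

Within cross-validation the PCA and the codebook are always fitted on the
training patients only; fitting them on the full cohort would leak
information about held-out patients into the representation.

# Classification and evaluation

B-scans inherit their volume's label for training — ground truth exists
only at the volume level, which means some training B-scans of DME volumes
are effectively mislabeled (lesion-free slices). The phantom generator
therefore guarantees at least 75% of a DME volume's B-scans carry lesions,
comfortably above the one-half floor that majority voting needs.

Classifiers: linear SVM ($C=1$), RBF SVM ($C=1$,
$\gamma=1/\mathrm{dim}$), random forest (100 trees). Features are
standardized to the training fold's mean and variance before SVMs (not
before the forest); constant columns are left unscaled. The majority vote
declares a volume DME when at least half its B-scans are predicted
diseased — the exact-tie case counts as DME, favoring sensitivity in a
screening context. For the BoW representation the volume histogram is
classified directly.

`enumerate_ltpo_folds()` requires a balanced manifest and pairs the $i$-th
DME with the $i$-th normal patient in manifest order, so a 16+16 cohort
yields exactly 16 folds. `evaluate_pipeline()` accumulates the volume-level
confusion counts into SE $=\mathrm{TP}/(\mathrm{TP+FN})$ and SP
$=\mathrm{TN}/(\mathrm{TN+FP})$; `experiment_grid()` sweeps descriptors ×
representations × classifiers, including the combined configuration that
concatenates the two PCA-reduced descriptors (40 + 20 = 60 dimensions)
before classification.

# The phantom generator

Each synthetic B-scan is built from:

* a quadratic RPE curve $r(x)=ax^2+bx+c$ constrained to
  $[0.2,0.9]\cdot\mathrm{rows}$, rendered as a 7-px tent profile peaking
  at intensity 0.9 **on the curve** — so the per-column brightest pixel
  and the smoothed argmax used by the detector both sit on the generating
  curve (within rounding). Randomized volumes draw bowl-shaped curvature
  with the apex near the lateral center;
* piecewise-constant retinal bands above the RPE (default offsets 80/60/35
  px scaled by image height, intensities 0.45/0.30/0.50) and a 0.45
  choroid band below — the near-balanced shoulders keep the smoothed
  column maximum from drifting off the RPE peak;
* multiplicative gamma speckle as above;
* DME lesions. Severe DME presents as clusters of cystoid spaces, so a
  lesioned B-scan draws 8–16 dark intraretinal ellipses (semi-axes 5–14 px
  axially, 6–20 px laterally, centered 10–65 px above the RPE), each
  multiplying interior intensity by $1-\mathrm{contrast}$, plus
  (probability 0.5 each) one flat subretinal fluid pocket below the RPE
  and one focal thickening that displaces the inner bands upward. The
  cluster design matters: LBP is invariant to local mean and contrast, so
  a single dark blob is nearly invisible to it — the discriminative signal
  scales with total lesion boundary length, which a realistic cyst cluster
  provides. Lesion size/contrast ranges are package defaults, not
  calibrated against any clinical dataset.

DME volumes draw a per-volume lesion fraction uniformly in
$[0.75, 1]$ of their B-scans; normal volumes are lesion-free. All
randomness flows from one master seed through a deterministic
seed-derivation chain, so datasets are byte-reproducible.

What the phantom does **not** model: attenuation and shadowing under
fluid, the point-spread function, vessel shadows, motion artifacts,
vendor-specific intensity calibration, and anatomical variability beyond a
quadratic RPE. Passing the end-to-end test on phantoms demonstrates that
the pipeline's stages compose correctly and that the descriptors carry
lesion signal through cross-validated classification — it does not
establish clinical performance on real scans.

# Numerical choices and problem sizes

* Internal processing is double precision on $[0,1]$; files are written
  16-bit with round-half-even, so the read/write round trip is exact for
  16-bit data.
* Border handling is symmetric reflection everywhere (filters, gradients,
  pyramid smoothing, RPE profile smoothing).
* RANSAC resamples degenerate (duplicate-$x$) triples and is deterministic
  given its seed; k-means ties and nearest-centroid ties go to the lowest
  index; SVMs are deterministic; the random forest is seeded.
* Tests and examples use 256×512 phantom B-scans (the full 1024×512
  clinical geometry is supported but slower) and an 8+8-volume cohort with
  32 B-scans per volume for the end-to-end check; descriptor-geometry
  checks use the standard 356×340 window directly. At these sizes the
  whole suite runs in a few minutes on one core.
* The end-to-end configuration uses the mean filter (w = 5) as its
  denoiser: LBP codes are contrast-blind, so what matters is suppressing
  speckle texture, which a plain linear smoother does well at a fraction
  of NLM's cost. NLM remains the package-wide default denoiser.

# Known limitations

* The 18-patch LBP partition is a reverse-engineered stand-in for an
  unpublished layout; the 32-px tiling alternative is provided for
  comparison.
* Volume-level labels train B-scan classifiers; a volume with few diseased
  slices would defeat both training and the majority vote. Multiple
  instance learning would address this and is out of scope.
* Only the RPE is localized; no multi-layer segmentation is attempted.
* Phantom SE/SP numbers characterize the pipeline on synthetic data only.
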
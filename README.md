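# octdme

Automatic classification of spectral-domain optical coherence tomography
(SD-OCT) volumes as **diabetic macular edema (DME)** versus **normal**.

DME — retinal thickening with intraretinal cystoid spaces, hard exudates
and sometimes subretinal fluid — is a leading cause of vision loss in
diabetes, and SD-OCT is the imaging modality of choice for detecting it.
`octdme` implements a classical, fully inspectable texture pipeline for
volume-level screening, aimed at researchers who want a reproducible
baseline or a harness for studying individual pipeline stages
(denoising, flattening, descriptors, representations).

## The pipeline

Each B-scan (one cross-sectional slice of the volume) passes through:

1. **Denoising** — multiplicative speckle is modelled as gamma gain
   `g ~ Γ(L, L)` (unit mean, variance `1/L`). Implemented filters: mean,
   median, Lee (`x̂ = m + k(y − m)`, `k = max(0, v − σ²)/v`), wavelet
   hard/soft thresholding (orthonormal Haar, universal threshold
   `σ̂√(2 ln N)` by default), and non-local means
   (`w_ij = exp(−‖P_i − P_j‖²/h²)`), plus a plug-in hook for external
   denoisers.
2. **Flattening and cropping** — the retinal pigment epithelium (RPE) is
   localized per column (smoothed-profile argmax), fitted with a quadratic
   `r(x) = ax² + bx + c` by RANSAC, and each column is integer-shifted so
   the RPE is horizontal; the scan is cropped to 325 px above the RPE,
   30 px below, and a centered 340-px lateral window → a 356 × 340 patch.
3. **Descriptors** on a 4-level Gaussian pyramid —
   rotation-invariant uniform LBP (`riu2`, P+2 patterns: 10/18/26 for
   (P,R) = (8,1)/(16,2)/(24,3); per-B-scan lengths 180/324/468) or HoG
   (4×4-px cells, 2×2-cell blocks at 1-cell stride, 9 unsigned orientation
   bins; per-B-scan length 347,940).
4. **Representation** — raw histograms, PCA (20 components for LBP, 40
   for HoG), or a bag of visual words (k-means codebook over PCA-reduced
   B-scan vectors, one occurrence histogram per volume).
5. **Classification** — linear SVM / RBF SVM / random forest per B-scan
   with a majority vote over the volume (ties → DME), or direct
   classification of the per-volume BoW histogram.

Evaluation is leave-two-patients-out cross-validation (one DME + one
normal held out per fold) reporting volume-level sensitivity
`SE = TP/(TP+FN)` and specificity `SP = TN/(TN+FP)`.

Clinical SD-OCT datasets for this task are not publicly redistributable,
so the package includes a **synthetic phantom generator** (layered retina,
curved RPE, gamma speckle, cystoid/subretinal-fluid/thickening lesions)
that exercises every stage; see the methods vignette
(`vignettes/octdme-methods.Rmd`) for what the phantom does and does not
emulate.

## Worked example

Generate a small labelled phantom cohort, evaluate the LBP16-ri + PCA +
linear-SVM configuration, and benchmark the denoisers:

```r
library(octdme)

man <- make_phantom_dataset(n_dme = 4, n_normal = 4, out_dir = "phantoms",
                            rows = 256, cols = 512, scans_per_volume = 16,
                            lesion_contrast = 0.5, looks = 16, seed = 0)
man
#> <dataset_manifest> 8 volumes (DME: 4, NORMAL: 4)

cfg <- pipeline_config(denoiser = denoiser_spec("MEAN", window = 5),
                       descriptor = descriptor_config("LBP_RI", P = 16, R = 2),
                       representation = "HIST_PCA",
                       classifier = classifier_spec("LINEAR_SVM"),
                       seed = 0)
evaluate_pipeline(man, cfg)
#> <eval_report> SE = 75.0%  SP = 100.0%  (TP 3 / FN 1 / TN 4 / FP 0)
```

Each of the 4 folds trains on 6 volumes and predicts the 2 held-out ones;
at this miniature scale one DME volume is missed (SE = 75%) while all
normal volumes are recognized (SP = 100%). On the larger 8+8-volume,
32-scans-per-volume cohort used by the acceptance tests the same
configuration reaches SE = 100% / SP = 75%.

```r
img <- render_clean_bscan(phantom_spec(rows = 256, cols = 256,
                                       rpe_coeffs = c(0, 0, 160)))
benchmark_denoisers(list(img), looks = 4,
                    specs = list(MEAN = denoiser_spec("MEAN", window = 3),
                                 NLM  = denoiser_spec("NLM")),
                    seeds = 0:4)
#>   denoiser mean_psnr
#> 1    NOISY  17.15012
#> 2     MEAN  25.49530
#> 3      NLM  22.97786
```

Mean PSNR is computed against the clean phantom over 5 speckle draws at
L = 4; both filters comfortably beat the noisy baseline (~17 dB).

A thin command-line front end wrapping the same functions lives at
`inst/cli/octdme.R` (subcommands `simulate`, `preprocess`,
`bench-denoise`, `evaluate`).

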
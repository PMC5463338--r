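Package: octdme
Title: Classification of SD-OCT Retinal Volumes for Diabetic Macular Edema
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline that classifies spectral-domain optical
    coherence tomography (SD-OCT) volumes as diabetic macular edema (DME) or
    normal. Provides speckle denoising (mean, median, Lee, wavelet
    hard/soft thresholding, non-local means, plus a plug-in hook),
    RANSAC-fitted quadratic flattening of the retinal pigment epithelium,
    anatomical cropping, multiresolution local binary pattern (LBP) and
    histogram of oriented gradients (HoG) descriptors, Histogram / PCA /
    bag-of-visual-words representations, B-scan level classifiers with
    majority-vote volume decisions, and leave-two-patients-out evaluation.
    A synthetic phantom generator emulates layered retinal B-scans with
    multiplicative speckle and DME-type lesions so the whole pipeline can be
    exercised and tested without clinical data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    e1071,
    randomForest,
    tiff,
    png,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
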
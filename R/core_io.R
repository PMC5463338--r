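#' @useDynLib octdme, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef kmeans lm median quantile rgamma runif sd
#' @importFrom utils read.csv write.csv
NULL

VALID_LABELS <- c("DME", "NORMAL")

#' Construct a B-scan
#'
#' A B-scan is one 2-D cross-sectional OCT slice stored as a numeric matrix
#' with rows running along depth (axial, row 1 at the vitreous side) and
#' columns along the lateral dimension. Internally all processing is done in
#' floating point on the `[0, 1]` intensity scale.
#'
#' @param pixels numeric matrix of finite intensities.
#' @param range declared intensity range, `"unit"` (`[0, 1]`) or `"byte"`
#'   (`[0, 255]`).
#' @return the validated pixel matrix with class `bscan` and a `range`
#'   attribute.
#' @export
bscan <- function(pixels, range = c("unit", "byte")) {
  range <- match.arg(range)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("B-scan must have at least one row and one column")
  if (!all(is.finite(pixels)))
    stop("B-scan contains non-finite pixels")
  hi <- if (range == "unit") 1 else 255
  if (min(pixels) < 0 || max(pixels) > hi)
    stop(sprintf("pixel values outside declared range [0, %g]", hi))
  structure(pixels, class = c("bscan", "matrix"), range = range)
}

#' Construct an OCT volume
#'
#' An ordered stack of same-shape B-scans belonging to one patient, the unit
#' of diagnosis. Scan order is acquisition order and is preserved by every
#' transformation in the pipeline.
#'
#' @param scans list of numeric matrices (or `bscan` objects), all of
#'   identical dimensions.
#' @param patient_id character scalar.
#' @param label one of `"DME"`, `"NORMAL"`, `"UNKNOWN"`.
#' @return an object of class `oct_volume`.
#' @export
oct_volume <- function(scans, patient_id = "unknown", label = "UNKNOWN") {
  if (!is.list(scans) || length(scans) == 0L)
    stop("scans must be a non-empty list of matrices")
  scans <- lapply(scans, function(s) {
    if (inherits(s, "bscan")) s <- unclass(s)
    attributes(s)[setdiff(names(attributes(s)), "dim")] <- NULL
    if (!is.matrix(s) || !is.numeric(s)) stop("every scan must be a numeric matrix")
    s
  })
  d <- dim(scans[[1L]])
  ok <- vapply(scans, function(s) identical(dim(s), d), logical(1))
  if (!all(ok))
    stop(sprintf("scan %d has dimensions differing from scan 1", which(!ok)[1L]))
  label <- toupper(label)
  if (!label %in% c(VALID_LABELS, "UNKNOWN"))
    stop("label must be one of DME, NORMAL, UNKNOWN")
  structure(list(scans = scans, patient_id = as.character(patient_id),
                 label = label),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$scans[[1L]])
  cat(sprintf("<oct_volume> patient %s (%s): %d B-scans of %d x %d px\n",
              x$patient_id, x$label, length(x$scans), d[1L], d[2L]))
  invisible(x)
}

#' @export
dim.oct_volume <- function(x) c(length(x$scans), dim(x$scans[[1L]]))

#' Read an OCT volume from disk
#'
#' Supports multi-page grayscale TIFF stacks and directories of PNG slices
#' (slice order = lexicographic filename order). Pixels are returned on the
#' `[0, 1]` scale. A JSON sidecar (`<path>.meta.json`) written by
#' [write_volume()] restores `patient_id` and `label` when present.
#'
#' @param path TIFF file or PNG directory.
#' @param fmt `"auto"` (from the path), `"tiff"` or `"png_dir"`.
#' @return an [oct_volume()].
#' @export
read_volume <- function(path, fmt = c("auto", "tiff", "png_dir")) {
  fmt <- match.arg(fmt)
  if (fmt == "auto") fmt <- if (dir.exists(path)) "png_dir" else "tiff"
  if (fmt == "tiff") {
    if (!file.exists(path)) stop(sprintf("no such file: %s", path))
    pages <- tiff::readTIFF(path, all = TRUE)
    scans <- lapply(pages, drop_channels)
  } else {
    if (!dir.exists(path)) stop(sprintf("no such directory: %s", path))
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0L) stop(sprintf("no PNG slices in %s", path))
    scans <- lapply(files, function(f) drop_channels(png::readPNG(f)))
    d <- dim(scans[[1L]])
    for (i in seq_along(scans))
      if (!identical(dim(scans[[i]]), d))
        stop(sprintf("slice %s has inconsistent shape", basename(files[i])))
  }
  meta_path <- paste0(sub("/$", "", path), ".meta.json")
  pid <- tools::file_path_sans_ext(basename(path)); lab <- "UNKNOWN"
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    if (!is.null(meta$patient_id)) pid <- meta$patient_id
    if (!is.null(meta$label)) lab <- meta$label
  }
  oct_volume(scans, patient_id = pid, label = lab)
}

# collapse an RGB(A) array read by png/tiff to one grayscale channel
drop_channels <- function(a) {
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  a
}

#' Write an OCT volume to disk
#'
#' Writes a multi-page grayscale TIFF (or a directory of PNG slices) plus a
#' JSON sidecar carrying `patient_id` and `label`. TIFF pages are stored at
#' 16-bit depth (8-bit selectable), so the [read_volume()] round trip is
#' lossless for 8- and 16-bit data; PNG slices are 8-bit. Conversion uses
#' round-half-even.
#'
#' @param vol an [oct_volume()].
#' @param path destination file (TIFF) or directory (PNG).
#' @param fmt `"tiff"` or `"png_dir"`.
#' @param bits 8 or 16.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, fmt = c("tiff", "png_dir"), bits = 16L) {
  fmt <- match.arg(fmt)
  stopifnot(inherits(vol, "oct_volume"))
  if (length(vol$scans) == 0L) stop("cannot write a volume with no scans")
  if (fmt == "tiff") {
    ok <- tiff::writeTIFF(vol$scans, path, bits.per.sample = as.integer(bits))
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    nd <- max(3L, nchar(as.character(length(vol$scans) - 1L)))
    for (i in seq_along(vol$scans)) {
      f <- file.path(path, sprintf(paste0("b%0", nd, "d.png"), i - 1L))
      png::writePNG(vol$scans[[i]], f)  # 16-bit output for double input
    }
  }
  meta_path <- paste0(sub("/$", "", path), ".meta.json")
  jsonlite::write_json(list(patient_id = vol$patient_id, label = vol$label,
                            n_scans = length(vol$scans)),
                       meta_path, auto_unbox = TRUE)
  invisible(path)
}

#' Load a dataset manifest
#'
#' The manifest is a CSV with header `volume_path,patient_id,label` listing
#' one volume per row. Labels are normalized case-insensitively to
#' `DME`/`NORMAL`; `patient_id` must be unique per volume (one eye per
#' patient in this design).
#'
#' @param path CSV file.
#' @return a `data.frame` of class `dataset_manifest` with attributes
#'   `counts` (named label counts) and `base_dir`.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("volume_path", "patient_id", "label")
  if (!all(req %in% names(df)))
    stop("manifest must have columns volume_path, patient_id, label")
  df$label <- toupper(trimws(df$label))
  bad <- setdiff(unique(df$label), VALID_LABELS)
  if (length(bad) > 0L)
    stop(sprintf("unknown label(s) %s; allowed: %s",
                 paste(bad, collapse = ", "), paste(VALID_LABELS, collapse = ", ")))
  dup <- df$patient_id[duplicated(df$patient_id)]
  if (length(dup) > 0L)
    stop(sprintf("duplicate patient_id: %s", paste(unique(dup), collapse = ", ")))
  manifest_df(df, base_dir = dirname(path))
}

manifest_df <- function(df, base_dir = ".") {
  counts <- table(factor(df$label, levels = VALID_LABELS))
  structure(df, class = c("dataset_manifest", "data.frame"),
            counts = as.list(as.integer(counts)) |>
              stats::setNames(VALID_LABELS),
            base_dir = base_dir)
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cn <- attr(x, "counts")
  cat(sprintf("<dataset_manifest> %d volumes (DME: %d, NORMAL: %d)\n",
              nrow(x), cn$DME, cn$NORMAL))
  invisible(x)
}

#' Pipeline configuration
#'
#' Bundles every tunable of the classification pipeline with validated
#' defaults: the denoiser, the crop geometry (325 px above the RPE, 30 px
#' below, 340 px centered laterally), the 4-level pyramid, the descriptor,
#' the representation and the classifier.
#'
#' @param denoiser a [denoiser_spec()].
#' @param crop a [crop_geometry()].
#' @param pyramid_levels number of Gaussian pyramid levels.
#' @param descriptor a [descriptor_config()].
#' @param representation `"HIST"`, `"HIST_PCA"` or `"HIST_PCA_BOW"`.
#' @param pca_components PCA dimensionality (defaults: 20 for LBP, 40 for
#'   HoG descriptors; `NULL` picks by descriptor kind).
#' @param n_words bag-of-words codebook size.
#' @param classifier a [classifier_spec()].
#' @param seed integer master seed for every stochastic stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(denoiser = denoiser_spec("NLM"),
                            crop = crop_geometry(),
                            pyramid_levels = 4L,
                            descriptor = descriptor_config("LBP_RI", P = 16L, R = 2),
                            representation = c("HIST_PCA", "HIST", "HIST_PCA_BOW"),
                            pca_components = NULL,
                            n_words = 30L,
                            classifier = classifier_spec("LINEAR_SVM"),
                            seed = 0L) {
  representation <- match.arg(representation)
  if (is.null(pca_components))
    pca_components <- if (descriptor$kind == "HOG") 40L else 20L
  stopifnot(pyramid_levels >= 1L, pca_components >= 1L, n_words >= 2L)
  structure(list(denoiser = denoiser, crop = crop,
                 pyramid_levels = as.integer(pyramid_levels),
                 descriptor = descriptor, representation = representation,
                 pca_components = as.integer(pca_components),
                 n_words = as.integer(n_words),
                 classifier = classifier, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Deterministic derived seed for stage `k` of a run seeded with `seed`.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 9973) %% 2147483647)
}
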
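#' Synthetic SD-OCT phantom specification
#'
#' Describes one synthetic B-scan family: a dark vitreous background, a set
#' of bright horizontal retinal bands stacked at fixed offsets above a
#' quadratic retinal pigment epithelium (RPE) curve, and optional DME-type
#' lesions (intraretinal cystoid spaces, subretinal fluid pockets, focal
#' retinal thickening). The RPE band is the brightest structure in every
#' column, which is the anchor the flattening stage relies on.
#'
#' @param rows,cols image size in pixels (depth x lateral).
#' @param rpe_coeffs numeric `c(a, b, c)`: RPE row at lateral position `x`
#'   (0-based) is `a*x^2 + b*x + c`. Must stay within
#'   `[0.2*rows, 0.9*rows]`.
#' @param layer_offsets two-column matrix (`offset_px`, `intensity`): each
#'   band spans from `offset_px` above the RPE down to the next band, with
#'   the given intensity (all below the RPE intensity 0.9).
#' @param speckle_looks gamma speckle "number of looks" L; variance of the
#'   multiplicative gain is 1/L.
#' @param lesions list of lesions, each a list with `type` in
#'   `c("CYSTOID", "SUBRETINAL_FLUID", "THICKENING")`, `center = c(row, col)`
#'   (0-based), `axes = c(ar, ac)` ellipse semi-axes in px, and `contrast`
#'   in (0, 1] (fractional intensity reduction for fluid lesions, relative
#'   upward displacement for thickening).
#' @return a validated `phantom_spec` list.
#' @export
phantom_spec <- function(rows = 1024L, cols = 512L,
                         rpe_coeffs = c(0, 0, round(0.6 * rows)),
                         layer_offsets = default_layers(rows),
                         speckle_looks = 4,
                         lesions = list()) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  stopifnot(rows >= 8L, cols >= 8L, length(rpe_coeffs) == 3L,
            speckle_looks > 0)
  x <- 0:(cols - 1L)
  rpe <- rpe_coeffs[1] * x^2 + rpe_coeffs[2] * x + rpe_coeffs[3]
  if (any(rpe < 0.2 * rows) || any(rpe > 0.9 * rows))
    stop("RPE curve leaves the [0.2*rows, 0.9*rows] band")
  for (les in lesions) {
    stopifnot(les$type %in% c("CYSTOID", "SUBRETINAL_FLUID", "THICKENING"),
              length(les$center) == 2L, length(les$axes) == 2L,
              les$contrast > 0, les$contrast <= 1)
    if (les$center[1] < 0 || les$center[1] >= rows ||
        les$center[2] < 0 || les$center[2] >= cols)
      stop("lesion center outside image bounds")
    rpe_at <- rpe_coeffs[1] * les$center[2]^2 + rpe_coeffs[2] * les$center[2] +
      rpe_coeffs[3]
    if (les$type == "CYSTOID" && les$center[1] >= rpe_at)
      stop("CYSTOID lesion must lie above the RPE curve")
    if (les$type == "SUBRETINAL_FLUID" && les$center[1] <= rpe_at)
      stop("SUBRETINAL_FLUID lesion must lie below the RPE curve")
  }
  structure(list(rows = rows, cols = cols, rpe_coeffs = rpe_coeffs,
                 layer_offsets = layer_offsets,
                 speckle_looks = speckle_looks, lesions = lesions),
            class = "phantom_spec")
}

# Retinal band stack above the RPE, scaled to the image height: offsets in
# px above the RPE and band intensities. The RPE itself renders at 0.9.
default_layers <- function(rows) {
  sc <- rows / 256
  cbind(offset = round(c(80, 60, 35) * sc),
        intensity = c(0.45, 0.30, 0.50))
}

#' Render a noiseless phantom B-scan
#'
#' Draws the layered retina of a [phantom_spec()]: background at 0.05,
#' bands at the configured offsets above the quadratic RPE, the RPE band
#' itself (a 7-px tent profile peaking at 0.9 on the curve, the brightest
#' structure per column), a dimmer choroid below, then the lesions.
#' `x_shift` shifts the lateral
#' phase of the RPE curve so consecutive B-scans of a volume differ.
#'
#' @param spec a [phantom_spec()].
#' @param x_shift lateral phase offset in px.
#' @return a numeric matrix in `[0, 1]` (`rows` x `cols`).
#' @export
render_clean_bscan <- function(spec, x_shift = 0) {
  stopifnot(inherits(spec, "phantom_spec"))
  rows <- spec$rows; cols <- spec$cols
  x <- (0:(cols - 1L)) + x_shift
  a <- spec$rpe_coeffs[1]; b <- spec$rpe_coeffs[2]; cc <- spec$rpe_coeffs[3]
  rpe <- a * x^2 + b * x + cc
  rpe <- pmin(pmax(rpe, 0.2 * rows), 0.9 * rows)
  img <- matrix(0.05, rows, cols)
  rr <- matrix(0:(rows - 1L), rows, cols)          # 0-based row index grid
  rpe_m <- matrix(rpe, rows, cols, byrow = TRUE)

  # thickening lesions displace the inner layers upward locally
  disp <- matrix(0, rows, cols)
  for (les in spec$lesions) {
    if (les$type != "THICKENING") next
    cx <- les$center[2]; ac <- les$axes[2]
    bump <- les$contrast * les$axes[1] *
      pmax(0, 1 - ((x - x_shift - cx) / ac)^2)
    disp <- disp + matrix(bump, rows, cols, byrow = TRUE)
  }

  off <- spec$layer_offsets
  ord <- order(off[, 1], decreasing = TRUE)        # outermost band first
  off <- off[ord, , drop = FALSE]
  for (i in seq_len(nrow(off))) {
    top <- rpe_m - off[i, 1] - disp
    img[rr >= top & rr < rpe_m] <- off[i, 2]
  }
  # RPE band: a 7-px tent centered on the curve, peak 0.9 — the brightest
  # structure per column, with its single brightest pixel at round(rpe)
  d <- rr - rpe_m
  below <- d > 3 & d < 30
  img[below] <- 0.45                               # choroid
  sel <- abs(d) <= 3
  img[sel] <- 0.9 - 0.06 * abs(d[sel])

  cm <- matrix(0:(cols - 1L), rows, cols, byrow = TRUE)
  for (les in spec$lesions) {
    if (les$type == "THICKENING") next
    inside <- ((rr - les$center[1]) / les$axes[1])^2 +
      ((cm - les$center[2]) / les$axes[2])^2 <= 1
    img[inside] <- img[inside] * (1 - les$contrast)
  }
  pmin(pmax(img, 0), 1)
}

#' Add multiplicative gamma speckle
#'
#' Multiplies the image by i.i.d. gamma gain with shape `looks` and mean 1
#' (the fully-developed-speckle model; gain variance `1/looks`), then clips
#' to `[0, 1]`. Reproducible for a given seed.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param looks positive number of looks L.
#' @param seed integer seed.
#' @return speckled matrix, same shape.
#' @export
add_speckle <- function(img, looks, seed = 0L) {
  if (!is.numeric(looks) || looks <= 0) stop("looks must be > 0")
  if (min(img) < 0 || max(img) > 1) stop("img must lie in [0, 1]")
  g <- with_seed(seed, matrix(rgamma(length(img), shape = looks, rate = looks),
                              nrow(img), ncol(img)))
  pmin(pmax(img * g, 0), 1)
}

# Draw one random phantom_spec for a volume. DME volumes get lesions on a
# fraction >= lesion_frac of their B-scans (decided per scan downstream).
sample_phantom_spec <- function(rows, cols, dme, lesion_contrast, looks) {
  # curvature: bowl-shaped RPE, apex near the lateral center
  a <- runif(1, 0.5, 1.5) * 0.15 * rows / (cols / 2)^2
  x0 <- cols / 2 + runif(1, -0.1, 0.1) * cols
  c0 <- runif(1, 0.55, 0.72) * rows
  b <- -2 * a * x0
  cc <- c0 + a * x0^2
  # clamp so the curve stays in the legal band at the edges
  xs <- c(0, cols - 1)
  for (k in 1:10) {
    rr <- a * xs^2 + b * xs + cc
    if (all(rr >= 0.25 * rows & rr <= 0.85 * rows)) break
    a <- a * 0.7; b <- -2 * a * x0; cc <- c0 + a * x0^2
  }
  layers <- default_layers(rows)
  layers[, 2] <- pmin(0.8, layers[, 2] * runif(nrow(layers), 0.85, 1.15))
  phantom_spec(rows, cols, rpe_coeffs = c(a, b, cc), layer_offsets = layers,
               speckle_looks = looks, lesions = list())
}

# Random lesion set for one DME B-scan of a given spec: a cluster of
# cystoid spaces (severe DME presents as honeycombs of many cysts), plus
# optional subretinal fluid and focal thickening.
sample_lesions <- function(spec, lesion_contrast) {
  rows <- spec$rows; cols <- spec$cols
  sc <- rows / 256
  x <- 0:(cols - 1)
  rpe <- spec$rpe_coeffs[1] * x^2 + spec$rpe_coeffs[2] * x + spec$rpe_coeffs[3]
  lesions <- list()
  n_cyst <- sample(8:16, 1)
  for (i in seq_len(n_cyst)) {
    cx <- round(runif(1, 0.1, 0.9) * cols)
    cy <- round(rpe[cx + 1] - runif(1, 10, 65) * sc)
    cy <- min(max(cy, 1), rows - 2)
    lesions[[length(lesions) + 1L]] <-
      list(type = "CYSTOID", center = c(cy, cx),
           axes = c(runif(1, 5, 14) * sc, runif(1, 6, 20)),
           contrast = lesion_contrast)
  }
  if (runif(1) < 0.5) {
    cx <- round(runif(1, 0.25, 0.75) * cols)
    cy <- round(rpe[cx + 1] + runif(1, 8, 18) * sc)
    cy <- min(max(cy, 1), rows - 2)
    lesions[[length(lesions) + 1L]] <-
      list(type = "SUBRETINAL_FLUID", center = c(cy, cx),
           axes = c(runif(1, 5, 9) * sc, runif(1, 25, 70)),
           contrast = lesion_contrast)
  }
  if (runif(1) < 0.5) {
    cx <- round(runif(1, 0.25, 0.75) * cols)
    cy <- round(rpe[cx + 1] - 20 * sc)
    cy <- min(max(cy, 1), rows - 2)
    lesions[[length(lesions) + 1L]] <-
      list(type = "THICKENING", center = c(cy, cx),
           axes = c(runif(1, 10, 25) * sc, runif(1, 40, 100)),
           contrast = lesion_contrast)
  }
  lesions
}

#' Generate a synthetic labelled dataset on disk
#'
#' Writes `n_dme` DME and `n_normal` normal phantom volumes as TIFF stacks
#' plus a `manifest.csv`, emulating a two-class SD-OCT study. Each DME
#' volume has lesions on at least `lesion_frac` of its B-scans (default
#' 0.75, comfortably above the one-half floor that majority voting over
#' B-scans requires); normal volumes are lesion-free. RPE curvature, band
#' intensities and lesion geometry are randomized per volume from a single
#' seeded generator, so two calls with the same seed produce identical
#' datasets.
#'
#' @param n_dme,n_normal volume counts per class (>= 1).
#' @param out_dir output directory (created).
#' @param rows,cols B-scan size in px.
#' @param scans_per_volume B-scans per volume.
#' @param lesion_contrast fractional intensity reduction of fluid lesions.
#' @param looks gamma speckle looks L.
#' @param lesion_frac minimum fraction of lesioned B-scans per DME volume.
#' @param seed integer master seed.
#' @return the [load_manifest()]-style manifest (invisibly also written to
#'   `out_dir/manifest.csv`).
#' @export
make_phantom_dataset <- function(n_dme, n_normal, out_dir,
                                 rows = 256L, cols = 512L,
                                 scans_per_volume = 128L,
                                 lesion_contrast = 0.5, looks = 4,
                                 lesion_frac = 0.75, seed = 0L) {
  stopifnot(n_dme >= 1L, n_normal >= 1L, scans_per_volume >= 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  labels <- c(rep("DME", n_dme), rep("NORMAL", n_normal))
  n <- length(labels)
  paths <- character(n); pids <- character(n)
  with_seed(seed, {
    for (v in seq_len(n)) {
      pids[v] <- sprintf("P%03d", v)
      spec <- sample_phantom_spec(rows, cols, labels[v] == "DME",
                                  lesion_contrast, looks)
      n_min <- ceiling(lesion_frac * scans_per_volume)
      n_lesioned <- if (labels[v] == "DME")
        n_min + sample.int(scans_per_volume - n_min + 1L, 1L) - 1L else 0L
      lesioned <- rep(FALSE, scans_per_volume)
      if (n_lesioned > 0L)
        lesioned[sample.int(scans_per_volume, n_lesioned)] <- TRUE
      scans <- vector("list", scans_per_volume)
      for (s in seq_len(scans_per_volume)) {
        sp <- spec
        if (lesioned[s]) sp$lesions <- sample_lesions(spec, lesion_contrast)
        clean <- render_clean_bscan(sp, x_shift = (s - 1) * 0.5)
        scans[[s]] <- add_speckle(clean, looks,
                                  seed = derive_seed(seed, v * 100000 + s))
      }
      vol <- oct_volume(scans, patient_id = pids[v], label = labels[v])
      paths[v] <- file.path(out_dir, sprintf("%s.tiff", pids[v]))
      write_volume(vol, paths[v], fmt = "tiff")
    }
  })
  df <- data.frame(volume_path = basename(paths), patient_id = pids,
                   label = labels, stringsAsFactors = FALSE)
  write.csv(df, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest_df(df, base_dir = out_dir)
}
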
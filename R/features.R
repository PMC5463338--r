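#' Descriptor configuration
#'
#' Parameters of the per-B-scan texture/shape descriptor: rotation-invariant
#' uniform LBP (`LBP_RI`, riu2 mapping), uniform LBP without rotation
#' invariance (`LBP_NRI`, u2 mapping), or HoG. LBP descriptors pool code
#' histograms over a per-level grid of non-overlapping patches (default
#' grids 3x3 / 2x2 / 2x2 / 1x1 over the 4 pyramid levels, 18 patches in
#' total); a fixed-size tiling mode (`patch_mode = "tile"`, 32 px tiles) is
#' available as an alternative partition. HoG uses 4x4 px cells, 2x2-cell
#' blocks at 1-cell stride and 9 unsigned orientation bins.
#'
#' @param kind `"LBP_RI"`, `"LBP_NRI"` or `"HOG"`.
#' @param P,R LBP sampling points and radius; supported pairs (8,1), (16,2),
#'   (24,3).
#' @param levels pyramid levels.
#' @param partition list of per-level `c(grid_rows, grid_cols)` (grid mode).
#' @param patch_mode `"grid"` (default) or `"tile"`.
#' @param tile_px tile size for `patch_mode = "tile"`.
#' @return a `descriptor_config` list.
#' @export
descriptor_config <- function(kind = c("LBP_RI", "LBP_NRI", "HOG"),
                              P = 16L, R = 2,
                              levels = 4L,
                              partition = list(c(3L, 3L), c(2L, 2L),
                                               c(2L, 2L), c(1L, 1L)),
                              patch_mode = c("grid", "tile"),
                              tile_px = 32L) {
  kind <- match.arg(kind)
  patch_mode <- match.arg(patch_mode)
  if (kind != "HOG") {
    ok <- list(c(8, 1), c(16, 2), c(24, 3))
    if (!any(vapply(ok, function(p) all(p == c(P, R)), logical(1))))
      stop("supported (P, R) pairs: (8,1), (16,2), (24,3)")
    if (patch_mode == "grid") {
      if (length(partition) < levels) stop("partition must cover every level")
      if (any(unlist(partition) < 1L)) stop("patch grids must be positive")
    }
  }
  structure(list(kind = kind, P = as.integer(P), R = R,
                 levels = as.integer(levels), partition = partition,
                 patch_mode = patch_mode, tile_px = as.integer(tile_px)),
            class = "descriptor_config")
}

#' Gaussian image pyramid
#'
#' Level 1 is the input; each further level is smoothed with the separable
#' 5-tap binomial kernel `[1,4,6,4,1]/16` (symmetric-reflect borders) and
#' decimated by keeping even-indexed (0-based) rows/columns truncated to
#' `floor(n/2)`, so level `k` has dimensions `floor(dim / 2^(k-1))` exactly.
#'
#' @param img numeric matrix.
#' @param levels number of levels >= 1.
#' @return list of matrices, finest first.
#' @export
gaussian_pyramid <- function(img, levels = 4L) {
  stopifnot(levels >= 1L)
  img <- as_num_matrix(img)
  d <- dim(img) %/% (2^(levels - 1L))
  if (any(d < 8L))
    stop("input too small: coarsest pyramid level would be under 8 px")
  out <- vector("list", levels)
  out[[1L]] <- img
  k <- c(1, 4, 6, 4, 1) / 16
  for (l in seq_len(levels - 1L)) {
    sm <- sep_convolve(out[[l]], k)
    nr2 <- nrow(sm) %/% 2L; nc2 <- ncol(sm) %/% 2L
    out[[l + 1L]] <- sm[seq_len(nr2) * 2L - 1L, seq_len(nc2) * 2L - 1L,
                        drop = FALSE]
  }
  out
}

# separable convolution with symmetric-reflect borders
sep_convolve <- function(img, k) {
  half <- (length(k) - 1L) %/% 2L
  conv1 <- function(m) {           # along rows (down each column)
    n <- nrow(m)
    idx <- outer(seq_len(n), -half:half, `+`)
    idx[idx < 1L] <- 1L - idx[idx < 1L]
    idx[idx > n] <- 2L * n + 1L - idx[idx > n]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * m[idx[, j], , drop = FALSE]
    out
  }
  t(conv1(t(conv1(img))))
}

#' Number of LBP pattern labels
#'
#' Closed-form histogram length of the LBP mapping: `P + 2` for
#' rotation-invariant uniform codes (riu2) and `P(P-1) + 3` for uniform
#' codes without rotation invariance (u2).
#'
#' @param P sampling points >= 4.
#' @param variant `"RI"` or `"NRI"`.
#' @return integer label count.
#' @export
lbp_pattern_count <- function(P, variant = c("RI", "NRI")) {
  variant <- match.arg(variant)
  if (P < 4L) stop("P must be >= 4")
  if (variant == "RI") as.integer(P + 2L) else as.integer(P * (P - 1L) + 3L)
}

#' LBP code image
#'
#' For each pixel at least `R` away from the border, samples `P` neighbors
#' on the radius-`R` circle at angles `2 pi k / P` (bilinear interpolation;
#' exact grid values when the coordinates are integral within 1e-8),
#' thresholds against the center with `>=` (up to a `1e-12` interpolation
#' tolerance, so exact ties count as 1), and maps the `P`-bit code to
#' riu2 (`variant = "RI"`) or u2 (`"NRI"`) labels in
#' `0 ... lbp_pattern_count(P, variant) - 1`. Border pixels carry `NA`.
#'
#' @param img numeric matrix with both dimensions >= `2R + 1`.
#' @param P,R sampling points and radius.
#' @param variant `"RI"` or `"NRI"`.
#' @return integer matrix of labels (`NA` on the excluded border).
#' @export
lbp_code_image <- function(img, P = 8L, R = 1, variant = c("RI", "NRI")) {
  variant <- match.arg(variant)
  img <- as_num_matrix(img)
  if (nrow(img) < 2 * R + 1 || ncol(img) < 2 * R + 1)
    stop(sprintf("image must be at least %d px in both dimensions", 2 * R + 1))
  codes <- cpp_lbp_code(img, as.integer(P), as.numeric(R),
                        if (variant == "RI") 0L else 1L)
  codes[codes < 0L] <- NA_integer_
  codes
}

# L1-normalized label histogram of an LBP code patch (NA excluded)
lbp_patch_hist <- function(codes, n_labels) {
  v <- codes[!is.na(codes)]
  if (length(v) == 0L) stop("LBP patch contains no coded pixels")
  h <- tabulate(v + 1L, nbins = n_labels)
  h / sum(h)
}

# per-level patch windows (list of list(rows=, cols=) index vectors)
partition_windows <- function(nr, nc, config, level) {
  if (config$patch_mode == "grid") {
    g <- config$partition[[level]]
    gr <- g[1L]; gc <- g[2L]
    # floor-divided extents; leftover pixels land in the last cell
    rb <- c(seq(0L, by = nr %/% gr, length.out = gr), nr)
    cb <- c(seq(0L, by = nc %/% gc, length.out = gc), nc)
  } else {
    tp <- config$tile_px
    gr <- nr %/% tp; gc <- nc %/% tp
    if (gr < 1L || gc < 1L)
      stop("level too small for the configured tile size")
    rb <- seq(0L, by = tp, length.out = gr + 1L)
    cb <- seq(0L, by = tp, length.out = gc + 1L)
  }
  wins <- list()
  for (i in seq_len(length(rb) - 1L))
    for (j in seq_len(length(cb) - 1L))
      wins[[length(wins) + 1L]] <-
        list(rows = (rb[i] + 1L):rb[i + 1L], cols = (cb[j] + 1L):cb[j + 1L])
  wins
}

#' Multiresolution LBP descriptor
#'
#' Computes the LBP code image of every pyramid level, splits each level
#' into its configured non-overlapping patches, takes an L1-normalized
#' label histogram per patch and concatenates them in (level, row-major
#' patch) order. Length = total patches x [lbp_pattern_count()].
#'
#' @param pyramid list of matrices from [gaussian_pyramid()] (or a single
#'   matrix, taken as a 1-level pyramid).
#' @param config a [descriptor_config()] of kind `LBP_RI` or `LBP_NRI`.
#' @return numeric feature vector.
#' @export
lbp_descriptor <- function(pyramid, config = descriptor_config("LBP_RI")) {
  if (is.matrix(pyramid)) pyramid <- list(pyramid)
  stopifnot(config$kind %in% c("LBP_RI", "LBP_NRI"))
  variant <- if (config$kind == "LBP_RI") "RI" else "NRI"
  n_lab <- lbp_pattern_count(config$P, variant)
  levels <- min(config$levels, length(pyramid))
  out <- vector("list", levels)
  for (l in seq_len(levels)) {
    img <- pyramid[[l]]
    wins <- partition_windows(nrow(img), ncol(img), config, l)
    for (w in wins)
      if (length(w$rows) < 2 * config$R + 1 || length(w$cols) < 2 * config$R + 1)
        stop("patch smaller than the LBP support (2R + 1)")
    codes <- lbp_code_image(img, config$P, config$R, variant)
    out[[l]] <- unlist(lapply(wins, function(w)
      lbp_patch_hist(codes[w$rows, w$cols, drop = FALSE], n_lab)))
  }
  unlist(out)
}

#' Multiresolution HoG descriptor
#'
#' Per pyramid level: gradients by central differences (symmetric-reflect
#' borders); unsigned orientation binned into 9 bins over `[0, 180)` with
#' magnitude-weighted linear interpolation between adjacent bins; cell
#' histograms over 4x4 px cells (floor counts, trailing pixels dropped);
#' blocks of 2x2 cells stepped by 1 cell, each L2-normalized with
#' `eps = 1e-5`; blocks concatenated row-major, levels finest to coarsest.
#' Per-level length is `(cells_r - 1)(cells_c - 1) * 36`.
#'
#' @param pyramid list of matrices from [gaussian_pyramid()] (or a single
#'   matrix).
#' @param cell_px cell size in px.
#' @param n_bins orientation bins.
#' @return numeric feature vector.
#' @export
hog_descriptor <- function(pyramid, cell_px = 4L, n_bins = 9L) {
  if (is.matrix(pyramid)) pyramid <- list(pyramid)
  unlist(lapply(pyramid, hog_level, cell_px = cell_px, n_bins = n_bins))
}

hog_level <- function(img, cell_px = 4L, n_bins = 9L, eps = 1e-5) {
  img <- as_num_matrix(img)
  nr <- nrow(img); nc <- ncol(img)
  cr <- nr %/% cell_px; cc <- nc %/% cell_px
  if (cr < 2L || cc < 2L)
    stop("HoG needs at least 2 cells in each dimension")
  # central differences with symmetric-reflect borders
  up <- img[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  dn <- img[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
  lf <- img[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  rt <- img[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
  gy <- dn - up; gx <- rt - lf
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) * 180 / pi
  ang <- ang %% 180                        # unsigned orientation [0, 180)
  # magnitude split between the two nearest bin centers (i + 0.5) * width
  width <- 180 / n_bins
  t <- ang / width - 0.5
  b0 <- floor(t)
  frac <- t - b0
  b0 <- ((b0 %% n_bins) + n_bins) %% n_bins
  b1 <- (b0 + 1L) %% n_bins
  w0 <- mag * (1 - frac); w1 <- mag * frac
  # drop trailing pixels beyond full cells
  keep_r <- seq_len(cr * cell_px); keep_c <- seq_len(cc * cell_px)
  agg_r <- matrix(0, cr, cr * cell_px)
  agg_r[cbind(rep(seq_len(cr), each = cell_px), seq_len(cr * cell_px))] <- 1
  agg_c <- matrix(0, cc * cell_px, cc)
  agg_c[cbind(seq_len(cc * cell_px), rep(seq_len(cc), each = cell_px))] <- 1
  cells <- array(0, c(cr, cc, n_bins))
  for (b in seq_len(n_bins) - 1L) {
    wb <- (w0 * (b0 == b) + w1 * (b1 == b))[keep_r, keep_c, drop = FALSE]
    cells[, , b + 1L] <- agg_r %*% wb %*% agg_c
  }
  # 2x2-cell blocks at 1-cell stride; cell order within a block:
  # (i,j), (i,j+1), (i+1,j), (i+1,j+1)
  br <- cr - 1L; bc <- cc - 1L
  blocks <- array(0, c(br, bc, 4L * n_bins))
  blocks[, , seq_len(n_bins)]                <- cells[1:br, 1:bc, ]
  blocks[, , n_bins + seq_len(n_bins)]       <- cells[1:br, 2:cc, ]
  blocks[, , 2L * n_bins + seq_len(n_bins)]  <- cells[2:cr, 1:bc, ]
  blocks[, , 3L * n_bins + seq_len(n_bins)]  <- cells[2:cr, 2:cc, ]
  norms <- sqrt(apply(blocks^2, c(1, 2), sum) + eps^2)
  blocks <- blocks / array(norms, dim(blocks))
  # row-major blocks, contiguous 36-vectors
  as.numeric(aperm(blocks, c(3L, 2L, 1L)))
}

#' Expected descriptor length without computing features
#'
#' Closed-form length of the feature vector a [descriptor_config()] yields
#' on an input of the given size — the structural invariant every extracted
#' vector is checked against.
#'
#' @param config a [descriptor_config()].
#' @param dims input `c(rows, cols)` (before the pyramid).
#' @param cell_px,n_bins HoG geometry.
#' @return integer length.
#' @export
descriptor_length <- function(config, dims = c(356L, 340L),
                              cell_px = 4L, n_bins = 9L) {
  lv_dims <- lapply(seq_len(config$levels) - 1L,
                    function(k) dims %/% (2L^k))
  if (config$kind == "HOG") {
    total <- 0L
    for (d in lv_dims) {
      cr <- d[1L] %/% cell_px; cc <- d[2L] %/% cell_px
      if (cr < 2L || cc < 2L) stop("geometry yields fewer than 2 HoG cells")
      total <- total + (cr - 1L) * (cc - 1L) * 4L * n_bins
    }
    return(as.integer(total))
  }
  variant <- if (config$kind == "LBP_RI") "RI" else "NRI"
  n_lab <- lbp_pattern_count(config$P, variant)
  n_patches <- 0L
  for (l in seq_len(config$levels)) {
    d <- lv_dims[[l]]
    if (config$patch_mode == "grid") {
      g <- config$partition[[l]]
      if (d[1L] %/% g[1L] < 1L || d[2L] %/% g[2L] < 1L)
        stop("geometry yields an empty LBP patch grid")
      n_patches <- n_patches + g[1L] * g[2L]
    } else {
      k <- (d %/% config$tile_px)
      if (any(k < 1L)) stop("geometry yields zero LBP tiles")
      n_patches <- n_patches + k[1L] * k[2L]
    }
  }
  as.integer(n_patches * n_lab)
}

#' Extract the configured descriptor from one preprocessed B-scan
#'
#' Builds the Gaussian pyramid and dispatches on the descriptor kind.
#'
#' @param img preprocessed (cropped) numeric matrix.
#' @param config a [descriptor_config()].
#' @return numeric feature vector of length
#'   `descriptor_length(config, dim(img))`.
#' @export
extract_features <- function(img, config = descriptor_config("LBP_RI")) {
  pyr <- gaussian_pyramid(img, config$levels)
  if (config$kind == "HOG") hog_descriptor(pyr)
  else lbp_descriptor(pyr, config)
}

#' Per-B-scan feature matrix for a volume
#'
#' @param vol a preprocessed [oct_volume()].
#' @param config a [descriptor_config()].
#' @return numeric matrix, one row per B-scan in scan order.
#' @export
volume_features <- function(vol, config = descriptor_config("LBP_RI")) {
  rows <- lapply(vol$scans, extract_features, config = config)
  do.call(rbind, rows)
}
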
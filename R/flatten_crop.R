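#' Detect per-column RPE candidate points
#'
#' For each column of a (denoised) B-scan, the depth profile is smoothed
#' with a 1-D Gaussian (sigma = 3 px along depth) and the row of its
#' maximum is taken as the retinal pigment epithelium (RPE) candidate — the
#' RPE being the brightest band in a typical B-scan. Columns whose smoothed
#' maximum falls below `min_frac` of the image maximum are reported missing.
#'
#' @param img numeric matrix.
#' @param sigma Gaussian smoothing sigma in px (along depth).
#' @param min_frac column maxima below `min_frac * max(img)` are dropped.
#' @return data.frame with 0-based columns `x` and row positions `row`,
#'   containing only the non-missing columns.
#' @export
detect_rpe_candidates <- function(img, sigma = 3, min_frac = 0.1) {
  img <- as_num_matrix(img)
  half <- ceiling(3 * sigma)
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  # smooth each column along depth with symmetric-reflect borders
  nr <- nrow(img)
  idx <- outer(seq_len(nr), -half:half, `+`)
  idx[idx < 1L] <- 1L - idx[idx < 1L]
  idx[idx > nr] <- 2L * nr + 1L - idx[idx > nr]
  sm <- apply(img, 2, function(v) {
    m <- matrix(v[idx], nr)
    as.numeric(m %*% k)
  })
  sm <- matrix(sm, nr)
  peak <- max(sm)
  if (peak <= 0) stop("RPE detection failed: image is black")
  rows <- apply(sm, 2, which.max)
  vals <- sm[cbind(rows, seq_len(ncol(img)))]
  keep <- vals >= min_frac * peak
  if (!any(keep)) stop("RPE detection failed: no column above threshold")
  data.frame(x = which(keep) - 1L, row = rows[keep] - 1L)
}

#' RANSAC quadratic fit
#'
#' Robustly fits `row = a x^2 + b x + c` to candidate points by random
#' sample consensus: `n_iter` times, draw 3 points with distinct `x`, fit
#' the interpolating quadratic, and count points within `inlier_tol` rows.
#' The consensus set with the most inliers wins (ties broken by lower
#' inlier squared error); the returned model is the least-squares quadratic
#' refitted on that consensus set.
#'
#' @param x,row numeric vectors (0-based lateral position and row).
#' @param n_iter number of random hypotheses.
#' @param inlier_tol inlier residual tolerance in rows.
#' @param seed integer seed.
#' @return an `rpe_model` list: `coeffs = c(a, b, c)`, logical
#'   `inlier_mask`, and `inlier_fraction`.
#' @export
ransac_quadratic <- function(x, row, n_iter = 500L, inlier_tol = 3,
                             seed = 0L) {
  n <- length(x)
  stopifnot(length(row) == n)
  if (n < 3L) stop("RANSAC needs at least 3 points")
  fit_q <- function(idx) {
    X <- cbind(x[idx]^2, x[idx], 1)
    qr.solve(X, row[idx])
  }
  pred_q <- function(cf, xx) cf[1] * xx^2 + cf[2] * xx + cf[3]
  best <- NULL
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      idx <- sample.int(n, 3L)
      if (length(unique(x[idx])) < 3L) next     # degenerate sample: resample
      cf <- fit_q(idx)
      resid <- abs(row - pred_q(cf, x))
      inl <- resid <= inlier_tol
      ninl <- sum(inl)
      if (ninl < 3L) next
      sse <- sum(resid[inl]^2)
      if (is.null(best) || ninl > best$ninl ||
          (ninl == best$ninl && sse < best$sse))
        best <- list(inl = inl, ninl = ninl, sse = sse)
    }
  })
  if (is.null(best)) stop("RANSAC found no valid consensus set")
  X <- cbind(x[best$inl]^2, x[best$inl], 1)
  cf <- as.numeric(qr.solve(qr(X), row[best$inl]))
  structure(list(coeffs = cf, inlier_mask = best$inl,
                 inlier_fraction = best$ninl / n),
            class = "rpe_model")
}

#' @export
print.rpe_model <- function(x, ...) {
  cat(sprintf("<rpe_model> row = %.3g x^2 + %.3g x + %.3g (%.0f%% inliers)\n",
              x$coeffs[1], x$coeffs[2], x$coeffs[3],
              100 * x$inlier_fraction))
  invisible(x)
}

#' Predict RPE rows from a fitted model
#' @param model an `rpe_model`.
#' @param x 0-based lateral positions.
#' @return predicted 0-based rows.
#' @export
predict_rpe <- function(model, x) {
  cf <- model$coeffs
  cf[1] * x^2 + cf[2] * x + cf[3]
}

#' Flatten a B-scan along its RPE model
#'
#' Shifts each column down by the integer amount that brings the predicted
#' RPE row onto one common horizontal line — the deepest predicted RPE row
#' of the image. Vacated pixels are filled with 0; pixels shifted past the
#' bottom edge are dropped; the shape is preserved. Integer shifts (no
#' interpolation) keep local binary patterns intact.
#'
#' @param img numeric matrix.
#' @param model an `rpe_model` for this B-scan.
#' @return list with the flattened matrix `img` and the common 0-based RPE
#'   row `rpe_row`.
#' @export
flatten_bscan <- function(img, model) {
  img <- as_num_matrix(img)
  nr <- nrow(img); nc <- ncol(img)
  pred <- round(predict_rpe(model, 0:(nc - 1L)))
  if (mean(pred < 0 | pred >= nr) > 0.5)
    stop("flatten: predicted RPE outside the image for most columns")
  ref <- max(pred)
  shift <- ref - pred                      # >= 0, shift down
  out <- matrix(0, nr, nc)
  for (j in seq_len(nc)) {
    s <- shift[j]
    if (s >= nr) next
    src <- seq_len(nr - s)
    out[src + s, j] <- img[src, j]
  }
  list(img = out, rpe_row = as.integer(ref))
}

#' Crop geometry
#'
#' The fixed anatomical window extracted after flattening: `rows_above` px
#' above the RPE row, the RPE row itself, `rows_below` px below, and a
#' centered lateral window of `lateral_width` px.
#'
#' @param rows_above px above the RPE (default 325).
#' @param rows_below px below the RPE (default 30).
#' @param lateral_width centered lateral crop in px (default 340).
#' @return a `crop_geometry` list.
#' @export
crop_geometry <- function(rows_above = 325L, rows_below = 30L,
                          lateral_width = 340L) {
  stopifnot(rows_above >= 0L, rows_below >= 0L, lateral_width >= 1L)
  structure(list(rows_above = as.integer(rows_above),
                 rows_below = as.integer(rows_below),
                 lateral_width = as.integer(lateral_width)),
            class = "crop_geometry")
}

#' Crop a flattened B-scan around its RPE row
#'
#' Extracts rows `rpe_row - rows_above ... rpe_row + rows_below` (0-based,
#' inclusive; `rows_above + rows_below + 1` rows — 356 with the defaults)
#' and a centered lateral window whose 0-based left edge is
#' `floor((cols - lateral_width) / 2)`. Rows outside the source image are
#' zero-padded and flagged via the `padded_rows` attribute.
#'
#' @param img flattened numeric matrix.
#' @param rpe_row common 0-based RPE row from [flatten_bscan()].
#' @param geom a [crop_geometry()].
#' @return cropped matrix with attribute `padded_rows` (count of zero-filled
#'   rows).
#' @export
crop_bscan <- function(img, rpe_row, geom = crop_geometry()) {
  img <- as_num_matrix(img)
  nr <- nrow(img); nc <- ncol(img)
  if (geom$lateral_width > nc)
    stop(sprintf("lateral_width %d exceeds image width %d",
                 geom$lateral_width, nc))
  out_r <- geom$rows_above + geom$rows_below + 1L
  r0 <- rpe_row - geom$rows_above          # 0-based first source row
  rows <- r0 + 0:(out_r - 1L)
  c0 <- (nc - geom$lateral_width) %/% 2L
  cols <- c0 + seq_len(geom$lateral_width)
  out <- matrix(0, out_r, geom$lateral_width)
  valid <- rows >= 0L & rows < nr
  out[valid, ] <- img[rows[valid] + 1L, cols]
  attr(out, "padded_rows") <- sum(!valid)
  out
}

#' Preprocess one B-scan: denoise, flatten, crop
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param denoiser a [denoiser_spec()].
#' @param geom a [crop_geometry()].
#' @param ransac_iter,ransac_tol RANSAC settings.
#' @param seed seed for RANSAC sampling.
#' @return cropped, flattened, denoised matrix
#'   (`rows_above + rows_below + 1` x `lateral_width`).
#' @export
preprocess_bscan <- function(img, denoiser = denoiser_spec("NLM"),
                             geom = crop_geometry(),
                             ransac_iter = 500L, ransac_tol = 3,
                             seed = 0L) {
  dn <- apply_denoiser(img, denoiser)
  pts <- detect_rpe_candidates(dn)
  model <- ransac_quadratic(pts$x, pts$row, n_iter = ransac_iter,
                            inlier_tol = ransac_tol, seed = seed)
  fl <- flatten_bscan(dn, model)
  crop_bscan(fl$img, fl$rpe_row, geom)
}

#' Preprocess a whole volume
#'
#' Runs [preprocess_bscan()] on every B-scan, preserving scan order.
#'
#' @param vol an [oct_volume()].
#' @inheritParams preprocess_bscan
#' @return an [oct_volume()] of cropped scans.
#' @export
preprocess_volume <- function(vol, denoiser = denoiser_spec("NLM"),
                              geom = crop_geometry(), seed = 0L) {
  scans <- lapply(seq_along(vol$scans), function(i) {
    s <- preprocess_bscan(vol$scans[[i]], denoiser, geom,
                          seed = derive_seed(seed, i))
    attr(s, "padded_rows") <- NULL
    s
  })
  oct_volume(scans, patient_id = vol$patient_id, label = vol$label)
}
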
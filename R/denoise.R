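#' Denoiser specification
#'
#' Names one of the implemented speckle filters together with its
#' parameters, or wraps an arbitrary user-supplied function (`PLUGIN`) so
#' external denoisers can be dropped into the pipeline.
#'
#' @param name one of `"MEAN"`, `"MEDIAN"`, `"LEE"`, `"WAVELET_HARD"`,
#'   `"WAVELET_SOFT"`, `"NLM"`, `"IDENTITY"`, `"PLUGIN"`.
#' @param window odd window size (mean/median/Lee).
#' @param t wavelet threshold; `NULL` selects the universal threshold
#'   `sigma_hat * sqrt(2 log N)` with `sigma_hat` from the MAD of the finest
#'   diagonal subband.
#' @param levels wavelet decomposition levels.
#' @param patch,search odd NLM patch and search-window sizes.
#' @param h NLM bandwidth (> 0).
#' @param fn plugin function `function(img) -> img` (PLUGIN only).
#' @return a `denoiser_spec` list.
#' @export
denoiser_spec <- function(name = c("NLM", "MEAN", "MEDIAN", "LEE",
                                   "WAVELET_HARD", "WAVELET_SOFT",
                                   "IDENTITY", "PLUGIN"),
                          window = 5L, t = NULL, levels = 2L,
                          patch = 3L, search = 9L, h = 0.5, fn = NULL) {
  name <- match.arg(name)
  check_window(window); check_window(patch); check_window(search)
  if (!is.null(t) && t < 0) stop("threshold t must be >= 0")
  if (h <= 0) stop("NLM bandwidth h must be > 0")
  if (name == "PLUGIN" && !is.function(fn))
    stop("PLUGIN denoiser requires a function fn(img)")
  structure(list(name = name, window = as.integer(window), t = t,
                 levels = as.integer(levels), patch = as.integer(patch),
                 search = as.integer(search), h = h, fn = fn),
            class = "denoiser_spec")
}

check_window <- function(w) {
  if (w %% 2L != 1L || w < 3L) stop(sprintf("window size %d must be odd and >= 3", w))
  invisible(w)
}

#' Apply a denoiser to a B-scan
#'
#' @param img numeric matrix.
#' @param spec a [denoiser_spec()].
#' @return denoised matrix, same shape.
#' @export
apply_denoiser <- function(img, spec) {
  switch(spec$name,
    MEAN         = mean_filter(img, spec$window),
    MEDIAN       = median_filter(img, spec$window),
    LEE          = lee_filter(img, spec$window),
    WAVELET_HARD = wavelet_threshold(img, "HARD", spec$t, spec$levels),
    WAVELET_SOFT = wavelet_threshold(img, "SOFT", spec$t, spec$levels),
    NLM          = nlm_filter(img, spec$patch, spec$search, spec$h),
    IDENTITY     = img,
    PLUGIN       = spec$fn(img))
}

#' Mean filter
#'
#' Replaces each pixel by the mean of its `w x w` neighborhood with
#' symmetric-reflect border padding.
#'
#' @param img numeric matrix.
#' @param w odd window size >= 3.
#' @return filtered matrix.
#' @export
mean_filter <- function(img, w = 3L) {
  check_window(w)
  cpp_mean_filter(as_num_matrix(img), as.integer(w))
}

#' Median filter
#'
#' As [mean_filter()] with median aggregation.
#' @inheritParams mean_filter
#' @export
median_filter <- function(img, w = 3L) {
  check_window(w)
  cpp_median_filter(as_num_matrix(img), as.integer(w))
}

#' Lee local-statistics filter
#'
#' The adaptive filter `out = m + k * (img - m)` with local window mean `m`
#' and variance `v`, gain `k = max(0, v - sigma2) / v` (0 where `v = 0`),
#' and the noise variance `sigma2` estimated as the image-wide mean of the
#' local variances. Flat regions shrink to their local mean while
#' high-variance structures (edges, the RPE band) are preserved.
#'
#' @inheritParams mean_filter
#' @export
lee_filter <- function(img, w = 5L) {
  check_window(w)
  st <- cpp_local_stats(as_num_matrix(img), as.integer(w))
  m <- st$mean; v <- st$var
  sigma2 <- mean(v)
  k <- ifelse(v > 0, pmax(0, v - sigma2) / v, 0)
  m + k * (img - m)
}

#' Non-local means filter
#'
#' `out(i) = sum_j w(i,j) img(j) / sum_j w(i,j)` over the `s x s` search
#' window, with `w(i,j) = exp(-||patch_i - patch_j||^2 / h^2)` on `p x p`
#' patches (symmetric-reflect borders).
#'
#' @param img numeric matrix.
#' @param p odd patch size.
#' @param s odd search-window size.
#' @param h bandwidth (> 0).
#' @export
nlm_filter <- function(img, p = 3L, s = 9L, h = 0.5) {
  check_window(p); check_window(s)
  if (h <= 0) stop("h must be > 0")
  cpp_nlm_filter(as_num_matrix(img), as.integer(p), as.integer(s), h)
}

as_num_matrix <- function(img) {
  if (inherits(img, "bscan")) img <- unclass(img)
  storage.mode(img) <- "double"
  img
}

# ---- orthonormal Haar 2-D wavelet transform -------------------------------
# Single-level analysis along rows then columns; odd trailing samples are
# carried through untouched (kept in the approximation part) so any image
# size reconstructs exactly.

haar_fwd_1d <- function(v) {
  n <- length(v)
  m <- n %/% 2L
  i <- seq_len(m) * 2L
  lo <- (v[i - 1L] + v[i]) / sqrt(2)
  hi <- (v[i - 1L] - v[i]) / sqrt(2)
  tail <- if (n %% 2L == 1L) v[n] else numeric(0)
  list(lo = c(lo, tail), hi = hi)
}

haar_inv_1d <- function(lo, hi) {
  m <- length(hi)
  v <- numeric(2L * m)
  i <- seq_len(m) * 2L
  v[i - 1L] <- (lo[seq_len(m)] + hi) / sqrt(2)
  v[i]      <- (lo[seq_len(m)] - hi) / sqrt(2)
  c(v, lo[-seq_len(m)])
}

haar_fwd_2d <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  # rows direction (along each column)
  tmp_lo <- apply(img, 2, function(v) haar_fwd_1d(v)$lo)
  tmp_hi <- apply(img, 2, function(v) haar_fwd_1d(v)$hi)
  tmp_lo <- matrix(tmp_lo, ncol = nc); tmp_hi <- matrix(tmp_hi, ncol = nc)
  split2 <- function(mat) {
    ll <- t(apply(mat, 1, function(v) haar_fwd_1d(v)$lo))
    hh <- t(apply(mat, 1, function(v) haar_fwd_1d(v)$hi))
    if (nrow(mat) == 1L) { ll <- matrix(ll, 1); hh <- matrix(hh, 1) }
    list(lo = ll, hi = hh)
  }
  a <- split2(tmp_lo); d <- split2(tmp_hi)
  list(LL = a$lo, LH = a$hi, HL = d$lo, HH = d$hi,
       nr = nr, nc = nc)
}

haar_inv_2d <- function(dec) {
  merge2 <- function(lo, hi) {
    t(vapply(seq_len(nrow(lo)),
             function(i) haar_inv_1d(lo[i, ], hi[i, ]),
             numeric(ncol(lo) + ncol(hi))))
  }
  tmp_lo <- merge2(dec$LL, dec$LH)
  tmp_hi <- merge2(dec$HL, dec$HH)
  nr_hi <- nrow(tmp_hi)
  out <- vapply(seq_len(ncol(tmp_lo)),
                function(j) haar_inv_1d(tmp_lo[, j], tmp_hi[, j]),
                numeric(dec$nr))
  matrix(out, dec$nr, dec$nc)
}

#' Wavelet-domain threshold denoising
#'
#' Multi-level orthonormal Haar decomposition; the detail subbands are hard-
#' (`c * 1[|c| > t]`) or soft- (`sign(c) * max(|c| - t, 0)`) thresholded
#' while the approximation band is left untouched, then the image is
#' reconstructed. With `t = NULL` the universal threshold
#' `sigma_hat * sqrt(2 log N)` is used, `sigma_hat = MAD(HH_1) / 0.6745`
#' estimated from the finest diagonal subband.
#'
#' @param img numeric matrix.
#' @param mode `"HARD"` or `"SOFT"`.
#' @param t threshold >= 0, or `NULL` for the universal threshold.
#' @param levels decomposition depth >= 1.
#' @return reconstructed matrix, original shape.
#' @export
wavelet_threshold <- function(img, mode = c("HARD", "SOFT"), t = NULL,
                              levels = 2L) {
  mode <- match.arg(mode)
  if (!is.null(t) && t < 0) stop("t must be >= 0")
  stopifnot(levels >= 1L)
  img <- as_num_matrix(img)
  decs <- vector("list", levels)
  cur <- img
  for (l in seq_len(levels)) {
    decs[[l]] <- haar_fwd_2d(cur)
    cur <- decs[[l]]$LL
  }
  if (is.null(t)) {
    hh <- decs[[1L]]$HH
    sigma <- median(abs(hh - median(hh))) / 0.6745
    t <- sigma * sqrt(2 * log(length(img)))
  }
  thr <- function(cmat) {
    if (mode == "HARD") cmat * (abs(cmat) > t)
    else sign(cmat) * pmax(abs(cmat) - t, 0)
  }
  for (l in seq_len(levels))
    for (band in c("LH", "HL", "HH"))
      decs[[l]][[band]] <- thr(decs[[l]][[band]])
  rec <- decs[[levels]]$LL
  for (l in rev(seq_len(levels))) {
    decs[[l]]$LL <- rec
    rec <- haar_inv_2d(decs[[l]])
  }
  rec
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(peak^2 / MSE)` in dB; `Inf` when the images are identical.
#'
#' @param ref,test same-shape numeric matrices.
#' @param peak signal peak (default 1, the internal intensity scale).
#' @return PSNR in dB.
#' @export
psnr <- function(ref, test, peak = 1) {
  if (!identical(dim(ref), dim(test))) stop("psnr: shape mismatch")
  mse <- mean((ref - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Benchmark denoisers on speckled phantoms
#'
#' For each clean image and seed, draws gamma speckle at `looks` L, runs
#' every denoiser, and averages PSNR against the clean reference. The noisy
#' baseline is reported as row `"NOISY"`.
#'
#' @param clean_images list of numeric matrices in `[0, 1]`.
#' @param looks speckle looks L.
#' @param specs named list of [denoiser_spec()]s.
#' @param seeds integer vector of seeds (one speckle draw each).
#' @return data.frame with columns `denoiser`, `mean_psnr`.
#' @export
benchmark_denoisers <- function(clean_images, looks, specs, seeds = 0:4) {
  stopifnot(length(clean_images) >= 1L, length(seeds) >= 1L)
  rows <- c("NOISY", names(specs))
  acc <- stats::setNames(numeric(length(rows)), rows)
  n <- 0L
  for (img in clean_images) {
    for (sd in seeds) {
      noisy <- add_speckle(img, looks, seed = sd)
      acc[["NOISY"]] <- acc[["NOISY"]] + psnr(img, noisy)
      for (nm in names(specs))
        acc[[nm]] <- acc[[nm]] + psnr(img, apply_denoiser(noisy, specs[[nm]]))
      n <- n + 1L
    }
  }
  data.frame(denoiser = rows, mean_psnr = as.numeric(acc) / n,
             stringsAsFactors = FALSE)
}
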
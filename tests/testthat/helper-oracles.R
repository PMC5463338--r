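# Brute-force reference implementations used as independent oracles.
# All use the same documented conventions as the package (symmetric
# edge-inclusive reflection, >= LBP threshold) but are written as plain
# loops with no shared code.

reflect1 <- function(i, n) {
  # 1-based symmetric reflection
  while (i < 1L || i > n) {
    if (i < 1L) i <- 1L - i
    if (i > n) i <- 2L * n + 1L - i
  }
  i
}

oracle_window <- function(img, r, c, w) {
  h <- w %/% 2L
  vals <- numeric(w * w)
  k <- 0L
  for (dr in -h:h) for (dc in -h:h) {
    k <- k + 1L
    vals[k] <- img[reflect1(r + dr, nrow(img)), reflect1(c + dc, ncol(img))]
  }
  vals
}

oracle_mean_filter <- function(img, w) {
  out <- img
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img)))
    out[r, c] <- mean(oracle_window(img, r, c, w))
  out
}

oracle_median_filter <- function(img, w) {
  out <- img
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img)))
    out[r, c] <- median(oracle_window(img, r, c, w))
  out
}

oracle_lee_filter <- function(img, w) {
  nr <- nrow(img); nc <- ncol(img)
  m <- img; v <- img
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    win <- oracle_window(img, r, c, w)
    m[r, c] <- mean(win)
    v[r, c] <- mean((win - mean(win))^2)
  }
  sigma2 <- mean(v)
  k <- ifelse(v > 0, pmax(0, v - sigma2) / v, 0)
  m + k * (img - m)
}

oracle_nlm_filter <- function(img, p, s, h) {
  nr <- nrow(img); nc <- ncol(img)
  ph <- p %/% 2L; sh <- s %/% 2L
  patch <- function(r, c) {
    vals <- numeric(p * p); k <- 0L
    for (dr in -ph:ph) for (dc in -ph:ph) {
      k <- k + 1L
      vals[k] <- img[reflect1(r + dr, nr), reflect1(c + dc, nc)]
    }
    vals
  }
  out <- img
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    pi <- patch(r, c)
    wsum <- 0; acc <- 0
    for (dr in -sh:sh) for (dc in -sh:sh) {
      r2 <- r + dr; c2 <- c + dc
      pj <- patch(r2, c2)
      wgt <- exp(-sum((pi - pj)^2) / h^2)
      wsum <- wsum + wgt
      acc <- acc + wgt * img[reflect1(r2, nr), reflect1(c2, nc)]
    }
    out[r, c] <- acc / wsum
  }
  out
}

# per-pixel LBP oracle (riu2 / u2), same sampling conventions, plain loops
oracle_lbp_code <- function(img, P, R, variant = "RI") {
  nr <- nrow(img); nc <- ncol(img)
  Ri <- ceiling(R - 1e-8)
  out <- matrix(NA_integer_, nr, nc)
  for (r in (Ri + 1):(nr - Ri)) {
    for (c in (Ri + 1):(nc - Ri)) {
      bits <- integer(P)
      for (k in 0:(P - 1)) {
        ang <- 2 * pi * k / P
        yy <- r - R * sin(ang); xx <- c + R * cos(ang)
        if (abs(yy - round(yy)) < 1e-8) yy <- round(yy)
        if (abs(xx - round(xx)) < 1e-8) xx <- round(xx)
        y0 <- floor(yy); x0 <- floor(xx)
        val <- if (yy == y0 && xx == x0) img[y0, x0] else {
          ty <- yy - y0; tx <- xx - x0
          (1 - ty) * (1 - tx) * img[y0, x0] +
            (1 - ty) * tx * img[y0, x0 + 1] +
            ty * (1 - tx) * img[y0 + 1, x0] +
            ty * tx * img[y0 + 1, x0 + 1]
        }
        bits[k + 1] <- as.integer(val >= img[r, c] - 1e-12)
      }
      U <- sum(bits != bits[c(2:P, 1)])
      ones <- sum(bits)
      out[r, c] <- if (variant == "RI") {
        if (U <= 2) ones else P + 1L
      } else {
        if (U == 0) {
          if (ones == 0) 0L else P * (P - 1L) + 1L
        } else if (U == 2) {
          prev <- bits[c(P, 1:(P - 1))]
          rot <- which(bits == 1L & prev == 0L)[1] - 1L
          1L + (ones - 1L) * P + rot
        } else P * (P - 1L) + 2L
      }
    }
  }
  out
}

with_seed_test <- function(seed, code) withr::with_seed(seed, code)

# small deterministic phantom used across tests
test_phantom <- function(rows = 256L, cols = 512L, a = 2e-4, b = -0.1,
                         c0 = 170, lesions = list()) {
  phantom_spec(rows = rows, cols = cols, rpe_coeffs = c(a, b, c0),
               lesions = lesions)
}
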
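#' Fit a PCA model
#'
#' Mean-centered principal axes by descending explained variance, computed
#' by singular value decomposition of the centered training matrix. Signs
#' are fixed so each component's largest-magnitude loading is positive,
#' making the fit deterministic.
#'
#' @param X numeric matrix (rows = samples).
#' @param n_components number of components (<= `min(n_samples, n_features)`).
#' @return a `pca_model` list: `mean`, `components`
#'   (`n_components x n_features`), `explained_variance` fractions.
#' @export
fit_pca <- function(X, n_components) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n_components > n)
    stop("n_components must not exceed the number of samples")
  if (n_components > p)
    stop("n_components must not exceed the feature dimension")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = 0, nv = n_components)
  comps <- t(sv$v)
  # sign convention: largest-|loading| entry positive
  for (i in seq_len(nrow(comps))) {
    j <- which.max(abs(comps[i, ]))
    if (comps[i, j] < 0) comps[i, ] <- -comps[i, ]
  }
  var_all <- sv$d^2
  structure(list(mean = mu, components = comps,
                 n_components = as.integer(n_components),
                 explained_variance = var_all[seq_len(n_components)] /
                   sum(var_all)),
            class = "pca_model")
}

#' Project data through a fitted PCA model
#'
#' @param model a [fit_pca()] model.
#' @param X numeric matrix with the training feature dimension.
#' @return `nrow(X) x n_components` score matrix.
#' @export
transform_pca <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$mean))
    stop(sprintf("feature dimension %d does not match the model (%d)",
                 ncol(X), length(model$mean)))
  sweep(X, 2L, model$mean) %*% t(model$components)
}

# squared Euclidean distances between rows of A and rows of B
cross_dist2 <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, `+`) - 2 * A %*% t(B)
  pmax(d2, 0)
}

# k-means++ seeding
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  i <- sample.int(n, 1L)
  centers[1L, ] <- X[i, ]
  d2 <- cross_dist2(X, centers[1L, , drop = FALSE])[, 1L]
  for (j in seq_len(k - 1L) + 1L) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    i <- sample.int(n, 1L, prob = p)
    centers[j, ] <- X[i, ]
    d2 <- pmin(d2, cross_dist2(X, centers[j, , drop = FALSE])[, 1L])
  }
  centers
}

#' Fit a bag-of-words codebook
#'
#' k-means (Lloyd iterations, max 300, tolerance 1e-6 on centroid movement)
#' with k-means++ initialization and 10 restarts, keeping the restart with
#' the lowest within-cluster inertia. Deterministic for a given seed.
#'
#' @param X numeric matrix of training B-scan vectors (rows = samples).
#' @param n_words codebook size (>= 2, <= `nrow(X)`).
#' @param seed integer seed.
#' @param restarts number of k-means++ restarts.
#' @return a `codebook` list: `centroids` (`n_words x dim`), `inertia`,
#'   `seed`.
#' @export
fit_codebook <- function(X, n_words, seed = 0L, restarts = 10L) {
  X <- as.matrix(X)
  if (n_words < 2L) stop("n_words must be >= 2")
  if (nrow(X) < n_words)
    stop("need at least n_words training samples")
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      init <- kmeanspp_init(X, n_words)
      km <- suppressWarnings(
        kmeans(X, centers = init, iter.max = 300L, algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  structure(list(centroids = unname(best$centers),
                 n_words = as.integer(n_words),
                 inertia = best$tot.withinss, seed = as.integer(seed)),
            class = "codebook")
}

#' Encode a volume as a visual-word occurrence histogram
#'
#' Assigns each B-scan vector to its nearest centroid (Euclidean distance,
#' ties to the lowest word index) and accumulates counts, yielding one
#' `n_words`-length histogram per volume that sums to the B-scan count.
#'
#' @param codebook a [fit_codebook()] codebook.
#' @param X numeric matrix of the volume's B-scan vectors.
#' @return integer count vector of length `n_words`.
#' @export
encode_volume <- function(codebook, X) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(codebook$centroids))
    stop("feature dimension does not match the codebook")
  d2 <- cross_dist2(X, codebook$centroids)
  assign <- apply(d2, 1L, which.min)      # which.min takes the lowest index
  tabulate(assign, nbins = codebook$n_words)
}
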
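#' Classifier specification
#'
#' @param kind `"LINEAR_SVM"`, `"RBF_SVM"` or `"RF"`.
#' @param C SVM cost (> 0).
#' @param gamma RBF kernel width; `NULL` uses `1 / feature_dim` at fit time.
#' @param n_trees random-forest size (>= 1).
#' @param seed integer seed (random forest and any stochastic fitting).
#' @param standardize standardize features to train-fold mean/variance
#'   before fitting (applied for SVMs by default, not for RF).
#' @return a `classifier_spec` list.
#' @export
classifier_spec <- function(kind = c("LINEAR_SVM", "RBF_SVM", "RF"),
                            C = 1, gamma = NULL, n_trees = 100L,
                            seed = 0L, standardize = NULL) {
  kind <- match.arg(kind)
  stopifnot(C > 0, is.null(gamma) || gamma > 0, n_trees >= 1L)
  if (is.null(standardize)) standardize <- kind != "RF"
  structure(list(kind = kind, C = C, gamma = gamma,
                 n_trees = as.integer(n_trees), seed = as.integer(seed),
                 standardize = isTRUE(standardize)),
            class = "classifier_spec")
}

#' Train a B-scan level classifier
#'
#' Fits the configured classifier to feature vectors whose labels are
#' inherited from their volume (`DME` positive, `NORMAL` negative). SVM
#' features are standardized to the training mean/variance (constant
#' columns are left unscaled); the same transform is applied at prediction.
#'
#' @param spec a [classifier_spec()].
#' @param X numeric matrix (rows = samples).
#' @param y character/factor labels in `{DME, NORMAL}`.
#' @return a `bscan_classifier` with a `predict` method returning labels.
#' @export
train_bscan_classifier <- function(spec, X, y) {
  X <- as.matrix(X)
  y <- factor(as.character(y), levels = c("DME", "NORMAL"))
  if (any(is.na(y))) stop("labels must be DME or NORMAL")
  if (nlevels(droplevels(y)) < 2L)
    stop("training set must contain both classes")
  center <- rep(0, ncol(X)); scale <- rep(1, ncol(X))
  if (spec$standardize) {
    center <- colMeans(X)
    s <- apply(X, 2L, sd)
    scale <- ifelse(s > 0, s, 1)
    X <- sweep(sweep(X, 2L, center), 2L, scale, "/")
  }
  fit <- with_seed(spec$seed, switch(spec$kind,
    LINEAR_SVM = e1071::svm(X, y, kernel = "linear", cost = spec$C,
                            scale = FALSE),
    RBF_SVM = e1071::svm(X, y, kernel = "radial", cost = spec$C,
                         gamma = if (is.null(spec$gamma)) 1 / ncol(X)
                                 else spec$gamma,
                         scale = FALSE),
    RF = randomForest::randomForest(X, y, ntree = spec$n_trees)))
  structure(list(spec = spec, fit = fit, center = center, scale = scale),
            class = "bscan_classifier")
}

#' @export
predict.bscan_classifier <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (object$spec$standardize)
    X <- sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
  as.character(stats::predict(object$fit, X))
}

#' Majority-vote volume decision
#'
#' A volume is called `DME` when at least half of its B-scan predictions
#' are diseased: strictly more than `n/2` diseased B-scans is DME, and the
#' exact tie `n/2` is also called DME (favoring sensitivity in a screening
#' setting).
#'
#' @param predictions character vector of per-B-scan labels.
#' @return list with `label` and `diseased_count`.
#' @export
majority_vote <- function(predictions) {
  if (length(predictions) == 0L) stop("majority_vote: no predictions")
  k <- sum(predictions == "DME")
  n <- length(predictions)
  list(label = if (k >= n / 2) "DME" else "NORMAL", diseased_count = k)
}

#' Enumerate leave-two-patients-out folds
#'
#' Requires a class-balanced manifest (equal DME and normal counts `n`);
#' fold `i` holds out the `i`-th DME and `i`-th normal patient in manifest
#' order, training on the remaining `2n - 2` volumes — `n` folds in total
#' (16 for the canonical 16 + 16 design).
#'
#' @param manifest a [load_manifest()] data.frame.
#' @return list of folds, each `list(test_idx, train_idx, held_out)`.
#' @export
enumerate_ltpo_folds <- function(manifest) {
  dme <- which(manifest$label == "DME")
  nrm <- which(manifest$label == "NORMAL")
  if (length(dme) != length(nrm))
    stop("leave-two-patients-out requires equal DME and NORMAL counts")
  lapply(seq_along(dme), function(i) {
    test <- c(dme[i], nrm[i])
    list(test_idx = test,
         train_idx = setdiff(seq_len(nrow(manifest)), test),
         held_out = manifest$patient_id[test])
  })
}

#' Evaluation report
#'
#' @param tp,fn,tn,fp volume-level confusion counts.
#' @return an `eval_report` with sensitivity `se = tp / (tp + fn)` and
#'   specificity `sp = tn / (tn + fp)`.
#' @export
eval_report <- function(tp, fn, tn, fp) {
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 se = tp / (tp + fn), sp = tn / (tn + fp)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> SE = %.1f%%  SP = %.1f%%  (TP %d / FN %d / TN %d / FP %d)\n",
              100 * x$se, 100 * x$sp, x$tp, x$fn, x$tn, x$fp))
  invisible(x)
}

#' Build a per-volume feature store for a manifest
#'
#' Loads every volume, runs preprocessing (denoise, RANSAC flatten, crop)
#' and descriptor extraction once, returning the per-B-scan feature
#' matrices so that several representations/classifiers can be evaluated
#' without recomputing. Manifest paths are resolved against the manifest's
#' base directory.
#'
#' @param manifest a [load_manifest()] manifest.
#' @param config a [pipeline_config()].
#' @param verbose print progress.
#' @return list (one per manifest row) of `list(features, label,
#'   patient_id)`.
#' @export
compute_feature_store <- function(manifest, config = pipeline_config(),
                                  verbose = FALSE) {
  base <- attr(manifest, "base_dir") %||% "."
  lapply(seq_len(nrow(manifest)), function(i) {
    p <- manifest$volume_path[i]
    if (!file.exists(p)) p <- file.path(base, manifest$volume_path[i])
    if (!file.exists(p) && !dir.exists(p))
      stop(sprintf("missing volume for manifest entry %s: %s",
                   manifest$patient_id[i], manifest$volume_path[i]))
    if (verbose) message("preprocessing ", manifest$patient_id[i])
    vol <- read_volume(p)
    pp <- preprocess_volume(vol, denoiser = config$denoiser,
                            geom = config$crop,
                            seed = derive_seed(config$seed, i))
    list(features = volume_features(pp, config$descriptor),
         label = manifest$label[i], patient_id = manifest$patient_id[i])
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a pipeline configuration by leave-two-patients-out CV
#'
#' For every fold the representation (PCA and, for the bag-of-words mode,
#' the codebook) and the classifier are fitted on the training patients
#' only, then the two held-out volumes are predicted: per-B-scan
#' classification with a majority vote for the `HIST` and `HIST_PCA`
#' representations, direct volume-histogram classification for
#' `HIST_PCA_BOW`. Confusion counts are accumulated over folds.
#'
#' @param manifest a [load_manifest()] manifest.
#' @param config a [pipeline_config()].
#' @param store optional precomputed [compute_feature_store()] result.
#' @param verbose print per-fold progress.
#' @return an [eval_report()] with a `folds` attribute of per-fold details.
#' @export
evaluate_pipeline <- function(manifest, config = pipeline_config(),
                              store = NULL, verbose = FALSE) {
  if (is.null(store)) store <- compute_feature_store(manifest, config, verbose)
  folds <- enumerate_ltpo_folds(manifest)
  tp <- fn <- tn <- fp <- 0L
  fold_log <- vector("list", length(folds))
  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    if (verbose) message("fold ", fi, ": holding out ",
                         paste(fold$held_out, collapse = ", "))
    train <- store[fold$train_idx]
    test <- store[fold$test_idx]
    Xtr <- do.call(rbind, lapply(train, `[[`, "features"))
    ytr <- unlist(lapply(train, function(v)
      rep(v$label, nrow(v$features))))
    pca <- NULL
    if (config$representation != "HIST") {
      k <- min(config$pca_components, nrow(Xtr) - 1L, ncol(Xtr))
      if (k < config$pca_components)
        warning(sprintf("PCA components clamped to %d (training size)", k))
      pca <- fit_pca(Xtr, k)
      Xtr <- transform_pca(pca, Xtr)
    }
    cls_seed <- derive_seed(config$seed, 1000L + fi)
    spec <- config$classifier; spec$seed <- cls_seed
    preds <- character(2L); counts <- rep(NA_integer_, 2L)
    if (config$representation == "HIST_PCA_BOW") {
      cb <- fit_codebook(Xtr, min(config$n_words, nrow(Xtr)),
                         seed = derive_seed(config$seed, 2000L + fi))
      # one occurrence histogram per training volume
      Htr <- t(vapply(train, function(v)
        encode_volume(cb, transform_pca(pca, v$features)),
        numeric(cb$n_words)))
      yv <- vapply(train, `[[`, "", "label")
      clf <- train_bscan_classifier(spec, Htr, yv)
      for (j in 1:2) {
        h <- encode_volume(cb, transform_pca(pca, test[[j]]$features))
        preds[j] <- predict(clf, matrix(h, nrow = 1L))
      }
    } else {
      clf <- train_bscan_classifier(spec, Xtr, ytr)
      for (j in 1:2) {
        Xte <- test[[j]]$features
        if (!is.null(pca)) Xte <- transform_pca(pca, Xte)
        mv <- majority_vote(predict(clf, Xte))
        preds[j] <- mv$label; counts[j] <- mv$diseased_count
      }
    }
    for (j in 1:2) {
      truth <- test[[j]]$label
      if (truth == "DME") {
        if (preds[j] == "DME") tp <- tp + 1L else fn <- fn + 1L
      } else {
        if (preds[j] == "NORMAL") tn <- tn + 1L else fp <- fp + 1L
      }
    }
    fold_log[[fi]] <- list(held_out = fold$held_out, predicted = preds,
                           truth = vapply(test, `[[`, "", "label"),
                           diseased_count = counts)
  }
  rep <- eval_report(tp, fn, tn, fp)
  attr(rep, "folds") <- fold_log
  rep
}

#' Run a grid of pipeline configurations
#'
#' Exp1 evaluates per-B-scan classification: every descriptor under the
#' `HIST` and `HIST_PCA` representations plus the combined
#' HoG-PCA + LBP-PCA configuration (the two PCA-reduced vectors
#' concatenated before classification), for each classifier. Exp2
#' evaluates direct volume classification via `HIST_PCA_BOW` over the
#' configured codebook sizes. Returns one row per configuration with SE,
#' SP and confusion counts.
#'
#' @param manifest a [load_manifest()] manifest.
#' @param config base [pipeline_config()] (crop/denoiser/seed).
#' @param descriptors named list of [descriptor_config()]s.
#' @param classifiers named list of [classifier_spec()]s.
#' @param representations character subset of
#'   `c("HIST", "HIST_PCA", "HIST_PCA_BOW")`.
#' @param combine optional character vector of two descriptor names whose
#'   PCA-reduced vectors are concatenated (`HIST_PCA` only).
#' @param words codebook sizes for `HIST_PCA_BOW`.
#' @param stores optional named list of precomputed feature stores (one per
#'   descriptor).
#' @param verbose print progress.
#' @return data.frame: descriptor, representation, classifier, words, se,
#'   sp, tp, fn, tn, fp.
#' @export
experiment_grid <- function(manifest, config = pipeline_config(),
                            descriptors = list(
                              lbp16_ri = descriptor_config("LBP_RI", 16L, 2)),
                            classifiers = list(
                              linear_svm = classifier_spec("LINEAR_SVM")),
                            representations = c("HIST", "HIST_PCA"),
                            combine = NULL,
                            words = c(10L, 30L, 40L, 50L),
                            stores = NULL, verbose = FALSE) {
  if (is.null(stores)) {
    stores <- lapply(descriptors, function(d) {
      cfg <- config; cfg$descriptor <- d
      compute_feature_store(manifest, cfg, verbose)
    })
  }
  rows <- list()
  add_row <- function(desc, rep_name, cls, w, r) {
    rows[[length(rows) + 1L]] <<- data.frame(
      descriptor = desc, representation = rep_name, classifier = cls,
      words = if (is.null(w)) NA_integer_ else w,
      se = r$se, sp = r$sp, tp = r$tp, fn = r$fn, tn = r$tn, fp = r$fp,
      stringsAsFactors = FALSE)
  }
  for (rep_name in intersect(representations, c("HIST", "HIST_PCA"))) {
    for (dn in names(descriptors)) {
      for (cn in names(classifiers)) {
        cfg <- config
        cfg$descriptor <- descriptors[[dn]]
        cfg$representation <- rep_name
        cfg$classifier <- classifiers[[cn]]
        cfg$pca_components <- if (descriptors[[dn]]$kind == "HOG") 40L else 20L
        r <- evaluate_pipeline(manifest, cfg, store = stores[[dn]])
        add_row(dn, rep_name, cn, NULL, r)
      }
    }
    if (rep_name == "HIST_PCA" && !is.null(combine)) {
      for (cn in names(classifiers)) {
        cfg <- config
        cfg$classifier <- classifiers[[cn]]
        r <- evaluate_combined(manifest, cfg,
                               stores[[combine[1L]]], stores[[combine[2L]]],
                               descriptors[[combine[1L]]],
                               descriptors[[combine[2L]]])
        add_row(paste(combine, collapse = "+"), "HIST_PCA", cn, NULL, r)
      }
    }
  }
  if ("HIST_PCA_BOW" %in% representations) {
    for (dn in names(descriptors)) {
      for (cn in names(classifiers)) {
        for (w in words) {
          cfg <- config
          cfg$descriptor <- descriptors[[dn]]
          cfg$representation <- "HIST_PCA_BOW"
          cfg$classifier <- classifiers[[cn]]
          cfg$n_words <- as.integer(w)
          cfg$pca_components <- if (descriptors[[dn]]$kind == "HOG") 40L else 20L
          r <- evaluate_pipeline(manifest, cfg, store = stores[[dn]])
          add_row(dn, "HIST_PCA_BOW", cn, w, r)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Evaluate a combined-descriptor configuration
#'
#' Leave-two-patients-out evaluation where two descriptors are each
#' PCA-reduced on the training fold (40 components for HoG, 20 for LBP)
#' and the reduced vectors are concatenated before per-B-scan
#' classification with majority voting — the combined-feature protocol.
#'
#' @param manifest a [load_manifest()] manifest.
#' @param config base [pipeline_config()] (classifier and seed are used).
#' @param store_a,store_b [compute_feature_store()] results for the two
#'   descriptors, same manifest order.
#' @param desc_a,desc_b the two [descriptor_config()]s.
#' @return an [eval_report()].
#' @export
evaluate_combined <- function(manifest, config, store_a, store_b,
                              desc_a, desc_b) {
  folds <- enumerate_ltpo_folds(manifest)
  ka <- if (desc_a$kind == "HOG") 40L else 20L
  kb <- if (desc_b$kind == "HOG") 40L else 20L
  tp <- fn <- tn <- fp <- 0L
  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    Xa <- do.call(rbind, lapply(store_a[fold$train_idx], `[[`, "features"))
    Xb <- do.call(rbind, lapply(store_b[fold$train_idx], `[[`, "features"))
    ytr <- unlist(lapply(store_a[fold$train_idx], function(v)
      rep(v$label, nrow(v$features))))
    ka_f <- min(ka, nrow(Xa) - 1L, ncol(Xa))
    kb_f <- min(kb, nrow(Xb) - 1L, ncol(Xb))
    pa <- fit_pca(Xa, ka_f); pb <- fit_pca(Xb, kb_f)
    Xtr <- cbind(transform_pca(pa, Xa), transform_pca(pb, Xb))
    spec <- config$classifier
    spec$seed <- derive_seed(config$seed, 3000L + fi)
    clf <- train_bscan_classifier(spec, Xtr, ytr)
    for (j in fold$test_idx) {
      Xte <- cbind(transform_pca(pa, store_a[[j]]$features),
                   transform_pca(pb, store_b[[j]]$features))
      pred <- majority_vote(predict(clf, Xte))$label
      truth <- store_a[[j]]$label
      if (truth == "DME") {
        if (pred == "DME") tp <- tp + 1L else fn <- fn + 1L
      } else {
        if (pred == "NORMAL") tn <- tn + 1L else fp <- fp + 1L
      }
    }
  }
  eval_report(tp, fn, tn, fp)
}
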
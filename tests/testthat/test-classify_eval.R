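make_manifest <- function(n_dme, n_normal) {
  octdme:::manifest_df(data.frame(
    volume_path = sprintf("v%02d.tiff", seq_len(n_dme + n_normal)),
    patient_id = sprintf("P%02d", seq_len(n_dme + n_normal)),
    label = c(rep("DME", n_dme), rep("NORMAL", n_normal)),
    stringsAsFactors = FALSE))
}

test_that("leave-two-patients-out enumerates one fold per patient pair", {
  man <- make_manifest(16, 16)
  folds <- enumerate_ltpo_folds(man)
  expect_length(folds, 16L)
  for (i in seq_along(folds)) {
    f <- folds[[i]]
    expect_length(f$test_idx, 2L)
    expect_setequal(man$label[f$test_idx], c("DME", "NORMAL"))
    expect_length(f$train_idx, 30L)
    expect_length(intersect(f$test_idx, f$train_idx), 0L)
  }
  # every DME patient held out exactly once
  held <- vapply(folds, function(f) f$test_idx[1], numeric(1))
  expect_setequal(held, 1:16)

  small <- enumerate_ltpo_folds(make_manifest(2, 2))
  expect_length(small, 2L)
  expect_length(small[[1]]$train_idx, 2L)
  expect_error(enumerate_ltpo_folds(make_manifest(3, 2)), "equal")
})

test_that("classifiers separate blobs and are seed-deterministic", {
  set.seed(51)
  X <- rbind(matrix(rnorm(80, mean = 0), 40, 2),
             matrix(rnorm(80, mean = 8), 40, 2))
  y <- rep(c("DME", "NORMAL"), each = 40)
  for (kind in c("LINEAR_SVM", "RBF_SVM", "RF")) {
    spec <- classifier_spec(kind, seed = 5L)
    clf <- train_bscan_classifier(spec, X, y)
    expect_equal(mean(predict(clf, X) == y), 1.0)
    clf2 <- train_bscan_classifier(spec, X, y)
    expect_identical(predict(clf2, X), predict(clf, X))
  }
  expect_error(train_bscan_classifier(classifier_spec("RF"), X,
                                      rep("DME", 80)), "both classes")
})

test_that("random forest held-out accuracy does not degrade with more trees", {
  set.seed(52)
  accs <- sapply(1:10, function(s) {
    Xtr <- rbind(matrix(rnorm(60, 0, 1.5), 30, 2),
                 matrix(rnorm(60, 2, 1.5), 30, 2))
    Xte <- rbind(matrix(rnorm(60, 0, 1.5), 30, 2),
                 matrix(rnorm(60, 2, 1.5), 30, 2))
    y <- rep(c("DME", "NORMAL"), each = 30)
    vapply(c(1L, 10L, 100L), function(nt) {
      clf <- train_bscan_classifier(classifier_spec("RF", n_trees = nt,
                                                    seed = s), Xtr, y)
      mean(predict(clf, Xte) == y)
    }, numeric(1))
  })
  means <- rowMeans(accs)
  expect_true(all(diff(means) > -0.02))   # non-decreasing in expectation
})

test_that("majority vote uses the strict-majority rule with DME ties", {
  expect_equal(majority_vote(rep(c("DME", "NORMAL"), c(70, 58)))$label, "DME")
  expect_equal(majority_vote(rep(c("DME", "NORMAL"), c(64, 64)))$label, "DME")
  expect_equal(majority_vote(rep("NORMAL", 128))$label, "NORMAL")
  expect_equal(majority_vote(rep(c("DME", "NORMAL"), c(63, 65)))$label,
               "NORMAL")
  expect_equal(majority_vote(c("DME"))$diseased_count, 1L)
  expect_error(majority_vote(character(0)), "no predictions")
})

test_that("SE/SP arithmetic follows the confusion-count definitions", {
  r <- eval_report(tp = 14, fn = 2, tn = 14, fp = 2)
  expect_equal(100 * r$se, 87.5)
  expect_equal(100 * r$sp, 87.5)
  expect_equal(eval_report(8, 0, 8, 0)$se, 1)
  expect_equal(eval_report(8, 0, 0, 8)$sp, 0)
})

# A tiny synthetic feature store lets the CV loop be exercised without the
# image pipeline: class-shifted Gaussian vectors per "volume".
toy_store <- function(man, dim = 6L, n_scans = 10L, shift = 3, seed = 60) {
  with_seed_test(seed, lapply(seq_len(nrow(man)), function(i) {
    mu <- if (man$label[i] == "DME") shift else 0
    list(features = matrix(rnorm(n_scans * dim, mean = mu), n_scans, dim),
         label = man$label[i], patient_id = man$patient_id[i])
  }))
}

test_that("pipeline evaluation aggregates folds for every representation", {
  man <- make_manifest(4, 4)
  st <- toy_store(man)
  for (rep_mode in c("HIST", "HIST_PCA", "HIST_PCA_BOW")) {
    cfg <- pipeline_config(representation = rep_mode, pca_components = 3L,
                           n_words = 4L,
                           classifier = classifier_spec("LINEAR_SVM"),
                           seed = 1L)
    r <- evaluate_pipeline(man, cfg, store = st)
    expect_s3_class(r, "eval_report")
    expect_equal(r$tp + r$fn, 4L)   # counts partition the volumes
    expect_equal(r$tn + r$fp, 4L)
    expect_equal(r$se, 1)           # well-separated toy classes
    expect_equal(r$sp, 1)
  }
})

test_that("fold training never sees the held-out volumes", {
  man <- make_manifest(3, 3)
  st <- toy_store(man, shift = 2)
  cfg <- pipeline_config(representation = "HIST_PCA", pca_components = 3L,
                         seed = 2L)
  # corrupting a held-out volume's features must not change the model
  # fitted in its own fold: the prediction for the OTHER held-out volume of
  # that fold (same model, untouched features) stays identical
  st2 <- st
  st2[[1]]$features <- st2[[1]]$features + 100
  r1 <- evaluate_pipeline(man, cfg, store = st)
  r2 <- evaluate_pipeline(man, cfg, store = st2)
  f1 <- attr(r1, "folds"); f2 <- attr(r2, "folds")
  # volume 1 is held out in fold 1; its partner's prediction there is
  # produced by the fold-1 model, which must not have seen volume 1
  expect_identical(f1[[1]]$predicted[2], f2[[1]]$predicted[2])
  expect_identical(f1[[1]]$diseased_count[2], f2[[1]]$diseased_count[2])
})

test_that("experiment grid emits one row per configuration", {
  man <- make_manifest(3, 3)
  descs <- list(d1 = descriptor_config("LBP_RI", 8L, 1),
                d2 = descriptor_config("LBP_RI", 16L, 2))
  sts <- list(d1 = toy_store(man, dim = 6L, seed = 61),
              d2 = toy_store(man, dim = 8L, seed = 62))
  cls <- list(lin = classifier_spec("LINEAR_SVM"),
              rf = classifier_spec("RF", n_trees = 20L))
  tab <- suppressWarnings(
    experiment_grid(man, pipeline_config(seed = 3L),
                    descriptors = descs, classifiers = cls,
                    representations = c("HIST", "HIST_PCA", "HIST_PCA_BOW"),
                    combine = c("d1", "d2"), words = c(3L, 4L),
                    stores = sts))
  # HIST: 2x2, HIST_PCA: 2x2 + combined 2, BOW: 2 desc x 2 cls x 2 words
  expect_equal(nrow(tab), 4L + 4L + 2L + 8L)
  expect_true(all(tab$tp + tab$fn == 3L))
  expect_true(all(tab$se >= 0 & tab$se <= 1))
  combined <- tab[tab$descriptor == "d1+d2", ]
  expect_equal(nrow(combined), 2L)
  # deterministic rerun
  tab2 <- suppressWarnings(
    experiment_grid(man, pipeline_config(seed = 3L),
                    descriptors = descs, classifiers = cls,
                    representations = c("HIST", "HIST_PCA", "HIST_PCA_BOW"),
                    combine = c("d1", "d2"), words = c(3L, 4L),
                    stores = sts))
  expect_identical(tab, tab2)
})
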
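test_that("pyramid dimensions follow floor-halving with the 5-tap kernel", {
  img <- matrix(runif(356 * 340), 356, 340)
  pyr <- gaussian_pyramid(img, 4L)
  expect_equal(lapply(pyr, dim),
               list(c(356L, 340L), c(178L, 170L), c(89L, 85L), c(44L, 42L)))
  expect_identical(pyr[[1]], img)
  # constant image stays constant at every level
  cpyr <- gaussian_pyramid(matrix(0.6, 64, 64), 4L)
  for (l in cpyr) expect_lt(max(abs(l - 0.6)), 1e-12)
  expect_identical(gaussian_pyramid(img, 1L), list(img))
  expect_error(gaussian_pyramid(matrix(0, 16, 16), 4L), "too small")
})

test_that("LBP pattern counts follow the riu2 / u2 closed forms", {
  expect_equal(lbp_pattern_count(8, "RI"), 10L)
  expect_equal(lbp_pattern_count(16, "RI"), 18L)
  expect_equal(lbp_pattern_count(24, "RI"), 26L)
  expect_equal(lbp_pattern_count(4, "RI"), 6L)
  expect_equal(lbp_pattern_count(8, "NRI"), 8L * 7L + 3L)
  expect_error(lbp_pattern_count(3), ">= 4")
})

test_that("LBP code images match the brute-force oracle", {
  set.seed(31)
  for (cfg in list(list(P = 8L, R = 1), list(P = 16L, R = 2))) {
    d <- 2 * ceiling(cfg$R) + 10
    img <- matrix(runif(d * d), d, d)
    for (variant in c("RI", "NRI")) {
      got <- lbp_code_image(img, cfg$P, cfg$R, variant)
      want <- oracle_lbp_code(img, cfg$P, cfg$R, variant)
      expect_identical(got, want)
    }
  }
  # constant image: all neighbors >= center -> all-ones pattern, one class
  cst <- matrix(0.4, 9, 9)
  codes <- lbp_code_image(cst, 8L, 1, "RI")
  expect_true(all(codes[2:8, 2:8] == 8L))
  expect_true(all(is.na(codes[1, ])))
  expect_error(lbp_code_image(matrix(0, 2, 2), 8L, 1), "at least")
})

test_that("riu2 histograms are rotation invariant within tolerance", {
  set.seed(32)
  base <- matrix(runif(16 * 16), 16, 16)
  # smooth a little so bilinear sampling artifacts stay small
  img <- mean_filter(base, 3L)
  rot <- t(img)[ncol(img):1, ]            # 90 degree rotation
  h <- function(m) {
    codes <- lbp_code_image(m, 8L, 1, "RI")
    tab <- tabulate(codes[!is.na(codes)] + 1L, nbins = 10L)
    tab / sum(tab)
  }
  expect_lt(sum(abs(h(img) - h(rot))), 0.02)
})

test_that("LBP descriptor lengths reproduce the printed per-config sizes", {
  d <- c(356L, 340L)
  expect_equal(descriptor_length(descriptor_config("LBP_RI", 8L, 1), d), 180L)
  expect_equal(descriptor_length(descriptor_config("LBP_RI", 16L, 2), d), 324L)
  expect_equal(descriptor_length(descriptor_config("LBP_RI", 24L, 3), d), 468L)
  # single 1x1 patch at one level: one histogram
  cfg1 <- descriptor_config("LBP_RI", 8L, 1, levels = 1L,
                            partition = list(c(1L, 1L)))
  expect_equal(descriptor_length(cfg1, c(64L, 64L)), 10L)
  # extracted vectors match the closed form exactly
  set.seed(33)
  img <- matrix(runif(128 * 128), 128, 128)
  pyr <- gaussian_pyramid(img, 4L)
  for (cfg in list(descriptor_config("LBP_RI", 8L, 1),
                   descriptor_config("LBP_NRI", 8L, 1))) {
    v <- lbp_descriptor(pyr, cfg)
    expect_length(v, descriptor_length(cfg, c(128L, 128L)))
    expect_true(all(v >= 0))
    # 18 patch histograms, each L1-normalized
    expect_equal(sum(v), 18, tolerance = 1e-9)
  }
  # constant input: every patch histogram is one-hot
  vc <- lbp_descriptor(gaussian_pyramid(matrix(0.2, 128, 128), 4L),
                       descriptor_config("LBP_RI", 8L, 1))
  expect_equal(sum(vc), 18)
  expect_setequal(unique(vc), c(0, 1))
})

test_that("32-px tiling mode partitions levels by fixed tiles", {
  cfg <- descriptor_config("LBP_RI", 8L, 1, patch_mode = "tile",
                           tile_px = 32L)
  # 356x340: levels give 11x10 + 5x5 + 2x2 + 1x1 = 140 tiles
  expect_equal(descriptor_length(cfg, c(356L, 340L)), 140L * 10L)
  set.seed(34)
  # two levels of a 128x128 input: 4x4 + 2x2 = 20 tiles
  cfg2 <- descriptor_config("LBP_RI", 8L, 1, levels = 2L,
                            patch_mode = "tile", tile_px = 32L)
  img <- matrix(runif(128 * 128), 128, 128)
  v <- lbp_descriptor(gaussian_pyramid(img, 2L), cfg2)
  expect_length(v, 20L * 10L)
  expect_length(v, descriptor_length(cfg2, c(128L, 128L)))
})

test_that("HoG per-level lengths reproduce the printed sizes", {
  expect_equal(length(octdme:::hog_level(matrix(runif(356 * 340), 356, 340))),
               266112L)
  sizes <- c(266112L, 63468L, 15120L, 3240L)
  pyr_dims <- list(c(356L, 340L), c(178L, 170L), c(89L, 85L), c(44L, 42L))
  for (i in 2:4) {
    d <- pyr_dims[[i]]
    expect_equal(length(octdme:::hog_level(matrix(runif(prod(d)), d[1], d[2]))),
                 sizes[i])
  }
  expect_equal(descriptor_length(descriptor_config("HOG"), c(356L, 340L)),
               347940L)
  # minimal geometry: an 8x8 image is a single 36-long block
  v8 <- hog_descriptor(matrix(runif(64), 8, 8))
  expect_length(v8, 36L)
  expect_error(octdme:::hog_level(matrix(0, 7, 8)), "2 cells")
})

test_that("HoG blocks are L2-normalized and orientation binning is sound", {
  set.seed(35)
  img <- matrix(runif(40 * 40), 40, 40)
  v <- octdme:::hog_level(img)
  blocks <- matrix(v, nrow = 36L)
  norms <- sqrt(colSums(blocks^2))
  expect_true(all(norms <= 1 + 1e-6))
  expect_true(all(v >= 0))
  # pure vertical edge: energy concentrated in the horizontal-gradient bins
  edge <- matrix(0, 24, 24); edge[, 13:24] <- 1
  ve <- octdme:::hog_level(edge)
  binsum <- rowSums(matrix(ve, nrow = 9L))
  # gradient is horizontal -> unsigned orientation 0 -> bins 1 and 9 (0 deg
  # lies half-way between the centers of the last and first bin)
  expect_gt(binsum[1] + binsum[9], 0.98 * sum(binsum))
})

test_that("extract_features honors the length contract for every config", {
  set.seed(36)
  img <- matrix(runif(96 * 96), 96, 96)
  for (cfg in list(descriptor_config("LBP_RI", 8L, 1),
                   descriptor_config("LBP_RI", 16L, 2),
                   descriptor_config("LBP_NRI", 16L, 2),
                   descriptor_config("HOG"))) {
    expect_length(extract_features(img, cfg),
                  descriptor_length(cfg, dim(img)))
  }
})
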
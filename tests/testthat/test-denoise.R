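test_that("spatial filters match their brute-force oracles", {
  set.seed(21)
  img <- matrix(runif(16 * 16), 16, 16)
  for (w in c(3L, 5L)) {
    expect_lt(max(abs(mean_filter(img, w) - oracle_mean_filter(img, w))),
              1e-10)
    expect_identical(median_filter(img, w), oracle_median_filter(img, w))
    expect_lt(max(abs(lee_filter(img, w) - oracle_lee_filter(img, w))),
              1e-10)
  }
  img12 <- matrix(runif(12 * 12), 12, 12)
  expect_lt(max(abs(nlm_filter(img12, 3L, 5L, 0.4) -
                      oracle_nlm_filter(img12, 3L, 5L, 0.4))), 1e-10)
})

test_that("filters preserve constant images and basic identities", {
  cst <- matrix(0.37, 9, 11)
  expect_equal(mean_filter(cst, 3), cst)
  expect_equal(median_filter(cst, 3), cst)
  expect_equal(lee_filter(cst, 5), cst)
  expect_equal(nlm_filter(cst, 3, 5, 0.2), cst)
  expect_lt(max(abs(wavelet_threshold(cst, "SOFT", 0.0, 2) - cst)), 1e-8)

  # 3x3 with center 9: mean over the window is 1 everywhere after reflect
  m <- matrix(0, 3, 3); m[2, 2] <- 9
  expect_equal(mean_filter(m, 3)[2, 2], 1)
  # single salt pixel removed by the median
  s <- matrix(0.2, 7, 7); s[4, 4] <- 1
  expect_equal(median_filter(s, 3)[4, 4], 0.2)
  # window validation
  expect_error(mean_filter(cst, 4), "odd")
})

test_that("NLM with huge bandwidth tends to the search-window box mean", {
  set.seed(22)
  img <- matrix(runif(14 * 14), 14, 14)
  out <- nlm_filter(img, 3L, 7L, h = 1e6)
  box <- oracle_mean_filter(img, 7L)
  expect_lt(max(abs(out - box)), 1e-6)
})

test_that("Lee filter keeps strong edges while flattening smooth areas", {
  img <- matrix(0.1, 24, 24); img[, 13:24] <- 0.9
  set.seed(23)
  img <- pmin(pmax(img + matrix(rnorm(24 * 24, sd = 0.02), 24, 24), 0), 1)
  out <- lee_filter(img, 5L)
  edge_contrast <- mean(out[, 15:24]) - mean(out[, 1:10])
  orig_contrast <- mean(img[, 15:24]) - mean(img[, 1:10])
  expect_gt(edge_contrast, 0.9 * orig_contrast)
  # interior smooth region variance shrinks
  expect_lt(sd(out[6:19, 3:8]), sd(img[6:19, 3:8]))
})

test_that("wavelet thresholding applies the hard/soft rules and inverts", {
  # threshold rules on scalars (detail coefficients)
  soft <- function(c, t) sign(c) * pmax(abs(c) - t, 0)
  hard <- function(c, t) c * (abs(c) > t)
  expect_equal(soft(5, 2), 3); expect_equal(soft(-1, 2), 0)
  expect_equal(hard(5, 2), 5); expect_equal(hard(1.9, 2), 0)

  set.seed(24)
  for (d in list(c(32L, 32L), c(33L, 17L), c(64L, 48L))) {
    m <- matrix(runif(prod(d)), d[1], d[2])
    expect_lt(max(abs(wavelet_threshold(m, "HARD", 0, 2) - m)), 1e-8)
    expect_lt(max(abs(wavelet_threshold(m, "SOFT", 0, 3) - m)), 1e-8)
  }
  # soft with t > 0 shrinks detail energy, preserving shape
  m <- matrix(runif(32 * 32), 32, 32)
  out <- wavelet_threshold(m, "SOFT", 0.5, 2)
  expect_equal(dim(out), dim(m))
  expect_lt(sd(out), sd(m))
  expect_error(wavelet_threshold(m, "SOFT", -1), ">= 0")
})

test_that("psnr follows the closed form and is symmetric", {
  a <- matrix(100, 10, 10); b <- a + 16
  expect_equal(psnr(a, b, peak = 255), 10 * log10(255^2 / 256),
               tolerance = 1e-12)
  expect_equal(psnr(a, b, peak = 255), psnr(b, a, peak = 255))
  expect_identical(psnr(a, a), Inf)
  expect_error(psnr(a, matrix(0, 9, 10)), "shape")
})

test_that("every implemented denoiser improves PSNR over speckle at L = 4", {
  img <- render_clean_bscan(test_phantom(rows = 128L, cols = 128L, c0 = 80))
  specs <- list(MEAN = denoiser_spec("MEAN", window = 3L),
                MEDIAN = denoiser_spec("MEDIAN", window = 3L),
                LEE = denoiser_spec("LEE", window = 5L),
                WAVELET_HARD = denoiser_spec("WAVELET_HARD"),
                WAVELET_SOFT = denoiser_spec("WAVELET_SOFT"),
                NLM = denoiser_spec("NLM"))
  tab <- benchmark_denoisers(list(img), looks = 4, specs, seeds = 0:4)
  base <- tab$mean_psnr[tab$denoiser == "NOISY"]
  for (nm in names(specs))
    expect_gt(tab$mean_psnr[tab$denoiser == nm], base)
  # identity denoiser reproduces the baseline, reruns are identical
  tab2 <- benchmark_denoisers(list(img), looks = 4,
                              list(ID = denoiser_spec("IDENTITY")), seeds = 0:2)
  expect_equal(tab2$mean_psnr[tab2$denoiser == "ID"],
               tab2$mean_psnr[tab2$denoiser == "NOISY"])
  expect_identical(tab, benchmark_denoisers(list(img), 4, specs, seeds = 0:4))
})

test_that("plugin denoisers slot into the dispatch", {
  sp <- denoiser_spec("PLUGIN", fn = function(img) img * 0 + mean(img))
  img <- matrix(runif(25), 5, 5)
  expect_equal(apply_denoiser(img, sp), matrix(mean(img), 5, 5))
  expect_error(denoiser_spec("PLUGIN"), "function")
})
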
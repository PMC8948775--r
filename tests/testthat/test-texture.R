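test_that("min-max normalization maps in-mask endpoints and ignores shifts", {
  img <- matrix(110, 64, 64)
  mask <- matrix(0, 64, 64); mask[20:40, 20:40] <- 1
  img[20, 20] <- 10; img[40, 40] <- 210
  img[1, 1] <- 0; img[64, 64] <- 255  # background extremes must not matter
  q <- normalize_grayscale(img, mask, levels = 64)
  expect_identical(q[20, 20], 0L)
  expect_identical(q[40, 40], 63L)
  expect_true(all(is.na(q[mask == 0])))
  q2 <- normalize_grayscale(img + 50, mask, levels = 64)
  expect_identical(q, q2)

  qc <- normalize_grayscale(matrix(42, 64, 64), matrix(1, 64, 64))
  expect_true(all(qc == 0L))
})

test_that("horizontal checkerboard gives exactly 1 bit; constant gives 0", {
  q <- as_quantized(outer(rep(1, 8), 0:7) %% 2, 2)
  e <- glcm_entropy(q, glcm_config(levels = 2, angles = 0))
  expect_identical(e$entropy, 1)
  p <- e$glcm[[1]]
  expect_equal(p[1, 2], 0.5); expect_equal(p[2, 1], 0.5)

  qc <- as_quantized(matrix(0, 8, 8), 2)
  expect_identical(glcm_entropy(qc, glcm_config(levels = 2))$entropy, 0)
})

test_that("GLCM entropy equals the brute-force pair-enumeration oracle", {
  set.seed(42)
  offsets <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  for (i in 1:50) {
    q <- as_quantized(matrix(sample(0:7, 64, replace = TRUE), 8, 8), 8)
    e <- glcm_entropy(q, glcm_config(levels = 8))
    expect_lt(abs(e$entropy - oracle_glcm_entropy(q, offsets)), 1e-10)
    for (p in e$glcm) expect_lt(abs(sum(p) - 1), 1e-12)
  }
})

test_that("mask-restricted GLCM only pairs pixels that are both inside", {
  set.seed(7)
  for (i in 1:10) {
    q <- matrix(sample(0:3, 144, replace = TRUE), 12, 12)
    q[matrix(runif(144) < 0.3, 12, 12)] <- NA  # background
    q <- as_quantized(q, 4)
    e <- glcm_entropy(q, glcm_config(levels = 4))
    o <- oracle_glcm_entropy(q, list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L),
                                     c(-1L, -1L)))
    expect_lt(abs(e$entropy - o), 1e-10)
  }
})

test_that("entropy is invariant under gray-level permutation", {
  set.seed(3)
  q <- as_quantized(matrix(sample(0:15, 400, replace = TRUE), 20, 20), 16)
  perm <- sample(0:15)
  qp <- as_quantized(matrix(perm[q + 1], 20, 20), 16)
  cfg <- glcm_config(levels = 16)
  expect_equal(glcm_entropy(q, cfg)$entropy, glcm_entropy(qp, cfg)$entropy,
               tolerance = 1e-12)
})

test_that("symmetric entropy is identical for opposite offsets", {
  set.seed(5)
  q <- as_quantized(matrix(sample(0:7, 256, replace = TRUE), 16, 16), 8)
  e0 <- glcm_entropy(q, glcm_config(levels = 8, angles = 0))
  e180 <- glcm_entropy(q, glcm_config(levels = 8, angles = 180))
  expect_equal(e0$entropy, e180$entropy, tolerance = 1e-12)
})

test_that("entropy rises monotonically with noise on a smooth phantom", {
  mean_entropy <- vapply(c(2, 6, 12), function(sigma) {
    mean(vapply(1:20, function(s) {
      ph <- make_phantom(image_size = 128, base_radius = 40,
                         noise_sigma = sigma, seed = s)
      q <- normalize_grayscale(ph$image, ph$truth$mask)
      glcm_entropy(q)$entropy
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_entropy) > 0))
})

test_that("gray statistics match direct summation", {
  q <- matrix(NA_integer_, 8, 8); q[1, 1] <- 0L; q[1, 2] <- 63L
  gs <- gray_statistics(q)
  expect_equal(unname(gs["mean_gray"]), 31.5)
  expect_equal(unname(gs["gray_std"]), 31.5)

  set.seed(9)
  q2 <- matrix(sample(0:63, 400, replace = TRUE), 20, 20)
  q2[matrix(runif(400) < 0.25, 20, 20)] <- NA
  gs2 <- gray_statistics(q2)
  v <- c()
  for (i in 1:20) for (j in 1:20) if (!is.na(q2[i, j])) v <- c(v, q2[i, j])
  expect_equal(unname(gs2["mean_gray"]), sum(v) / length(v))
  expect_equal(unname(gs2["gray_std"]),
               sqrt(sum((v - mean(v))^2) / length(v)))
})

test_that("entropy errors when the mask admits no pixel pairs", {
  q <- matrix(NA_integer_, 8, 8); q[1, 1] <- 0L
  attr(q, "levels") <- 4L
  expect_error(glcm_entropy(q, glcm_config(levels = 4)), "pairs")
})

test_that("texture LUT rendering is deterministic and 16-binned", {
  ph <- make_phantom(image_size = 128, base_radius = 40, seed = 4)
  q <- normalize_grayscale(ph$image, ph$truth$mask)
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  render_texture_lut(q, f1)
  render_texture_lut(q, f2)
  expect_identical(readBin(f1, "raw", 1e6), readBin(f2, "raw", 1e6))
  arr <- render_texture_lut(q)
  cols <- unique(apply(matrix(arr, ncol = 3), 1, paste, collapse = ","))
  expect_lte(length(cols), 17)  # 16 LUT colors + background
})
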
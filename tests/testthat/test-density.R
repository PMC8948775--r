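test_that("filled disk has unit occupancy inside and zero beyond the rim", {
  m <- disk_mask(256, 100)
  prof <- density_profile(m, ring_width = 2)
  inner <- prof$rings$outer_radius <= 98
  expect_true(all(prof$rings$density[inner] > 0.99))
  beyond <- prof$rings$inner_radius >= 102
  expect_true(all(prof$rings$density[beyond] == 0))
})

test_that("density profile matches the per-pixel binning oracle exactly", {
  set.seed(21)
  for (i in 1:10) {
    m <- matrix(as.integer(runif(32 * 32) < 0.4), 32, 32)
    m[16, 16] <- 1L
    ctr <- c(15.5, 15.5)
    prof <- density_profile(m, centroid = ctr, ring_width = 2)
    oracle <- oracle_ring_occupancy(m, ctr, 2)
    k <- nrow(prof$rings)
    expect_equal(prof$rings$density, oracle$occupancy[seq_len(k)],
                 tolerance = 0)
    expect_equal(prof$rings$n_foreground, oracle$fg[seq_len(k)],
                 ignore_attr = TRUE)
    expect_equal(prof$rings$n_pixels, oracle$total[seq_len(k)],
                 ignore_attr = TRUE)
  }
})

test_that("Core Threshold sits at the rim of a solid disk", {
  m <- disk_mask(256, 100)
  ct <- core_threshold(density_profile(m, ring_width = 2))
  expect_lte(abs(ct - 100), 2)
})

test_that("Core Threshold finds the solid core under a sparse halo", {
  # solid core of radius 50, sparse attached tendrils out to 120
  ph <- make_phantom(image_size = 280, base_radius = 120,
                     core_radius_fraction = 50 / 120, fragmentation = 0.6,
                     seed = 13)
  prof <- density_profile(ph$truth$mask, ring_width = 2)
  ct <- core_threshold(prof)
  expect_lte(abs(ct - 50), 2)
  # halo rings really are sparse
  halo <- prof$rings$inner_radius >= 54 & prof$rings$outer_radius <= 110
  expect_true(all(prof$rings$density[halo] < 0.5))
})

test_that("fully fragmented spheroid gets CT = 0 and percore = 0", {
  # scattered debris: a disk thinned to ~40% occupancy everywhere
  set.seed(5)
  m <- disk_mask(256, 80) * matrix(as.integer(runif(256^2) < 0.4), 256, 256)
  prof <- density_profile(m, centroid = c(127.5, 127.5))
  expect_true(max(prof$rings$density) < 0.95)
  ct <- core_threshold(prof)
  expect_identical(ct, 0)
  dm <- density_map(m, ct, centroid = c(127.5, 127.5))
  expect_identical(dm$percore, 0)
  expect_identical(dm$core_area, 0L)
})

test_that("percore recovery within 3 points of generator truth over 20 seeds", {
  errs <- vapply(1:20, function(s) {
    ph <- make_phantom(image_size = 280, base_radius = 120,
                       core_radius_fraction = 50 / 120, fragmentation = 0.6,
                       seed = s)
    dm <- spheroid_density(ph$truth$mask)
    abs(dm$percore - ph$truth$true_percore)
  }, numeric(1))
  expect_lt(max(errs), 3)
})

test_that("core and edge areas partition the mask exactly", {
  set.seed(33)
  for (i in 1:8) {
    ph <- make_phantom(image_size = 128, base_radius = 40,
                       n_protrusions = i %% 5, protrusion_amplitude = 0.25,
                       seed = i)
    m <- ph$truth$mask
    for (ct in c(0, 10, 25, 60)) {
      dm <- density_map(m, ct)
      expect_identical(dm$core_area + dm$edge_area, sum(m))
      expect_equal(dm$percore,
                   100 * dm$core_area / (dm$core_area + dm$edge_area))
    }
  }
})

test_that("percore is monotonically non-decreasing in CT", {
  for (s in 1:10) {
    ph <- make_phantom(image_size = 128, base_radius = 40,
                       n_protrusions = 6, protrusion_amplitude = 0.3,
                       seed = s)
    pc <- vapply(seq(0, 60, by = 5),
                 function(ct) density_map(ph$truth$mask, ct)$percore,
                 numeric(1))
    expect_true(all(diff(pc) >= 0))
  }
})

test_that("solid disk with CT at the rim is nearly all core", {
  dm <- density_map(disk_mask(256, 100), 100)
  expect_gte(dm$percore, 98)
})

test_that("off-mask centroid warns but still yields a profile", {
  m <- matrix(0L, 128, 128); m[10:30, 10:30] <- 1L
  expect_warning(prof <- density_profile(m, centroid = c(100, 100)),
                 "bounding box")
  expect_gt(nrow(prof$rings), 0)
  expect_error(density_profile(matrix(0L, 64, 64)), "empty")
})

test_that("density map rendering uses the fixed palette deterministically", {
  ph <- make_phantom(image_size = 128, base_radius = 40, seed = 2)
  dm <- spheroid_density(ph$truth$mask)
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  render_density_map(dm, f1); render_density_map(dm, f2)
  expect_identical(readBin(f1, "raw", 1e6), readBin(f2, "raw", 1e6))
  # edge-only map uses exactly two palette entries
  arr <- render_density_map(density_map(ph$truth$mask, 0))
  cols <- unique(apply(matrix(arr, ncol = 3), 1, paste, collapse = ","))
  expect_identical(length(cols), 2L)
})
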
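test_that("phantoms are fully determined by their seed", {
  a <- make_phantom(n_protrusions = 5, protrusion_amplitude = 0.3,
                    fragmentation = 0.3, seed = 17)
  b <- make_phantom(n_protrusions = 5, protrusion_amplitude = 0.3,
                    fragmentation = 0.3, seed = 17)
  c <- make_phantom(n_protrusions = 5, protrusion_amplitude = 0.3,
                    fragmentation = 0.3, seed = 18)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("degenerate star (no protrusions) is a rasterized disk", {
  ph <- make_phantom(base_radius = 70, n_protrusions = 0,
                     protrusion_amplitude = 0, noise_sigma = 0, seed = 1)
  expect_identical(ph$truth$mask, disk_mask(256, 70, ph$truth$centroid))
  expect_identical(ph$truth$true_n_protrusions, 0L)
  expect_equal(ph$truth$true_percore, 100)
})

test_that("fragmentation bookkeeping: detached specks are image-only", {
  f <- 0.5
  ph <- make_phantom(base_radius = 60, core_radius_fraction = 0.5,
                     fragmentation = f, noise_sigma = 0, seed = 3)
  solid <- make_phantom(base_radius = 60, core_radius_fraction = 0.5,
                        fragmentation = 0, noise_sigma = 0, seed = 3)
  core <- pi * 30^2
  halo <- solid$truth$true_area - core
  # main component = core + kept halo fraction
  expect_equal(ph$truth$true_area, core + (1 - f) * halo, tolerance = 0.02)
  expect_one_component(ph$truth$mask)
  expect_gt(ph$truth$n_speck_pixels, 0)
  # specks appear in the image but never in the truth mask
  halo_int <- ph$image$pixels == 160
  expect_gt(sum(halo_int & ph$truth$mask == 0), 0)
})

test_that("phantom spec invariants are enforced", {
  expect_error(make_phantom(base_radius = 200, image_size = 256), "base_radius")
  expect_error(make_phantom(fragmentation = 1), "fragmentation")
  expect_error(make_phantom(core_radius_fraction = 1.5), "core_radius")
  expect_error(make_phantom(background_intensity = 300), "bit depth")
  expect_error(make_timecourse("growth", n_timepoints = 1), "n_timepoints")
  expect_error(make_timecourse("melt"))
})

test_that("growth trend: area strictly up, percore stable within 2 points", {
  tc <- make_timecourse("growth", 4, seed = 5)
  area <- vapply(tc, function(p) p$truth$true_area, numeric(1))
  pc <- vapply(tc, function(p) p$truth$true_percore, numeric(1))
  expect_true(all(diff(area) > 0))
  expect_lt(max(pc) - min(pc), 2 * 2)
  expect_lt(max(abs(pc - pc[1])), 2)
})

test_that("collapse trend: area strictly down; disruption: percore strictly down, area up", {
  tcc <- make_timecourse("collapse", 3, seed = 5)
  expect_true(all(diff(vapply(tcc, function(p) p$truth$true_area,
                              numeric(1))) < 0))
  tcd <- make_timecourse("disruption", 3, seed = 5)
  expect_true(all(diff(vapply(tcd, function(p) p$truth$true_percore,
                              numeric(1))) < 0))
  expect_true(all(diff(vapply(tcd, function(p) p$truth$true_area,
                              numeric(1))) > 0))
})

test_that("timecourses are reproducible for identical (scenario, seed)", {
  a <- make_timecourse("disruption", 3, seed = 9)
  b <- make_timecourse("disruption", 3, seed = 9)
  for (i in seq_along(a))
    expect_identical(a[[i]]$image$pixels, b[[i]]$image$pixels)
})

test_that("full pipeline recovers area and percore of default phantoms", {
  cfg <- run_config()
  for (s in 1:20) {
    ph <- make_phantom(seed = s)
    rec <- suppressWarnings(analyze_image(ph$image, config = cfg))
    expect_lt(abs(rec$shape$area_px2 - ph$truth$true_area) /
                ph$truth$true_area, 0.03)
    expect_lt(abs(rec$density$percore - ph$truth$true_percore), 3)
  }
})

test_that("full pipeline counts protrusions exactly on star phantoms", {
  cfg <- run_config()
  ks <- rep(c(4L, 6L, 9L, 12L), 5)
  for (s in 1:20) {
    ph <- make_phantom(n_protrusions = ks[s], protrusion_amplitude = 0.3,
                       seed = s)
    rec <- suppressWarnings(analyze_image(ph$image, config = cfg))
    expect_lt(abs(rec$shape$area_px2 - ph$truth$true_area) /
                ph$truth$true_area, 0.03)
    expect_identical(rec$boundary$n_maxima, ks[s])
  }
})

test_that("synthetic dataset folders are ready to scan", {
  root <- withr::local_tempdir()
  write_synthetic_dataset(root, "growth", n_wells = 2, n_timepoints = 2,
                          seed = 1)
  ds <- scan_dataset(root)
  expect_equal(nrow(ds), 4)
  expect_setequal(unique(ds$well), c("w1", "w2"))
  truth <- utils::read.csv(file.path(root, "growth_truth.csv"))
  expect_equal(nrow(truth), 4)
  expect_true(all(c("true_area", "true_percore") %in% names(truth)))
})
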
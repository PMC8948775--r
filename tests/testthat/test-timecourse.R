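test_that("day-0 normalization is a plain ratio anchored at 100", {
  expect_equal(normalize_to_day0(c(200, 300), c(0, 7)), c(100, 150))
  expect_equal(normalize_to_day0(200, 0), 100)
  expect_equal(normalize_to_day0(c(200, 60), c(0, 14)), c(100, 30))
  # baseline is the earliest timepoint regardless of input order
  expect_equal(normalize_to_day0(c(300, 200), c(7, 0)), c(150, 100))
  expect_error(normalize_to_day0(c(NA, 1), c(0, 1)), "NA")
})

test_that("disruption statistic reproduces hand arithmetic", {
  r0 <- list(area = 100, percore = 60, entropy = 4)
  r1 <- list(area = 150, percore = 40, entropy = 5)
  d <- spheroid_disruption(r0, r1)
  expect_identical(d$disruption, ((150 - 100) / (40 - 60)) * 1)
  expect_identical(d$disruption, -2.5)
  expect_true(d$defined)
  expect_equal(d$delta_area, 50)
  expect_equal(d$delta_percore, -20)
  expect_equal(d$alpha, 1)
})

test_that("zero entropy change gives zero disruption; zero percore change is undefined", {
  r0 <- list(area = 100, percore = 60, entropy = 4)
  expect_identical(
    spheroid_disruption(r0, list(area = 150, percore = 40, entropy = 4))$disruption,
    0)
  d <- spheroid_disruption(r0, list(area = 150, percore = 60, entropy = 5))
  expect_false(d$defined)
  expect_true(is.na(d$disruption))
})

test_that("sign(disruption) = sign(dArea) * sign(dPercore) * sign(alpha) on a random grid", {
  set.seed(101)
  for (i in 1:1000) {
    a0 <- runif(1, 50, 200); at <- runif(1, 50, 200)
    p0 <- runif(1, 5, 95); pt <- runif(1, 5, 95)
    e0 <- runif(1, 1, 8); et <- runif(1, 1, 8)
    d <- spheroid_disruption(list(area = a0, percore = p0, entropy = e0),
                             list(area = at, percore = pt, entropy = et))
    expected <- (at - a0) / (pt - p0) * (et - e0)
    expect_equal(d$disruption, expected)
    if (at != a0 && pt != p0 && et != e0)
      expect_identical(sign(d$disruption),
                       sign(at - a0) * sign(pt - p0) * sign(et - e0))
  }
})

test_that("disruption is antisymmetric under swapping the two areas", {
  r0 <- list(area = 120, percore = 70, entropy = 3)
  r1 <- list(area = 80, percore = 50, entropy = 5)
  d1 <- spheroid_disruption(r0, r1)$disruption
  d2 <- spheroid_disruption(list(area = 80, percore = 70, entropy = 3),
                            list(area = 120, percore = 50, entropy = 5))$disruption
  expect_equal(d1, -d2)
})

test_that("the inverted-ratio form agrees in sign and inverts the ratio", {
  r0 <- list(area = 100, percore = 60, entropy = 4)
  r1 <- list(area = 150, percore = 40, entropy = 5)
  d <- spheroid_disruption(r0, r1, form = "percore_over_area")
  expect_identical(d$disruption, (-20 / 50) * 1)
  expect_identical(sign(d$disruption),
                   sign(spheroid_disruption(r0, r1)$disruption))
})

test_that("death-mode phenotypes follow the area/entropy trend rules", {
  expect_identical(classify_death_mode(100, 150, 4, 5.2), "disruption")
  expect_identical(classify_death_mode(100, 60, 4, 3.0), "collapse")
  expect_identical(classify_death_mode(100, 150, 4, 4.0), "growth")
  # within the 5% stability band counts as stable
  expect_identical(classify_death_mode(100, 150, 4, 4.19), "growth")
  expect_identical(classify_death_mode(100, 150, 4, 4.21), "disruption")
  expect_identical(classify_death_mode(100, 60, 4, 4.0), "indeterminate")
  expect_identical(classify_death_mode(100, 100, 4, 4.0), "indeterminate")
})

test_that("power-law viability fit recovers noiseless parameters", {
  a <- 2e-6; b <- 0.5
  x <- seq(40, 160, length.out = 12)
  tab <- data.frame(condition = "c", well = paste0("w", 1:12), timepoint = 7,
                    normalized_area = x)
  via <- data.frame(condition = "c", well = paste0("w", 1:12), timepoint = 7,
                    viability = a * x^1.5 + b)
  res <- suppressWarnings(correlate_viability(tab, via))  # zero-residual lm
  expect_lt(abs(res$fit$a - a) / a, 1e-9)
  expect_lt(abs(res$fit$b - b) / b, 1e-9)
  expect_lt(res$fit$se_a, 1e-12)
  expect_equal(res$n, 12)
})

test_that("collinear pairs give pearson r of exactly 1", {
  tab <- data.frame(condition = "c", well = paste0("w", 1:5), timepoint = 7,
                    normalized_area = c(10, 20, 30, 40, 50))
  via <- data.frame(condition = "c", well = paste0("w", 1:5), timepoint = 7,
                    viability = 0.3 + 0.01 * c(10, 20, 30, 40, 50))
  expect_equal(correlate_viability(tab, via)$pearson_r, 1)
})

test_that("two pairs refuse the fit but still report correlation", {
  tab <- data.frame(condition = "c", well = c("w1", "w2"), timepoint = 7,
                    normalized_area = c(10, 20))
  via <- data.frame(condition = "c", well = c("w1", "w2"), timepoint = 7,
                    viability = c(0.2, 0.4))
  expect_warning(res <- correlate_viability(tab, via), "refused")
  expect_null(res$fit)
  expect_equal(res$pearson_r, 1)
})

test_that("unmatched viability wells are excluded with a warning", {
  tab <- data.frame(condition = "c", well = paste0("w", 1:4), timepoint = 7,
                    normalized_area = c(10, 20, 30, 40))
  via <- data.frame(condition = "c", well = c("w1", "w2", "w3", "w9"),
                    timepoint = 7, viability = c(1, 2, 3, 4))
  expect_warning(res <- correlate_viability(tab, via), "w9")
  expect_equal(res$n, 3)
})

test_that("disruption table pairs every later timepoint against day 0", {
  mk <- function(well, tp, area, percore, entropy) {
    structure(list(
      ref = image_ref("x.tif", "Ctr", well, tp),
      shape = list(area_px2 = area),
      density = list(percore = percore),
      texture = list(entropy = entropy)), class = "spheroid_record")
  }
  recs <- list(mk("w1", 0, 100, 60, 4), mk("w1", 7, 150, 40, 5),
               mk("w1", 14, 200, 30, 6),
               mk("w2", 0, 100, 50, 4), mk("w2", 7, 80, 70, 3))
  tab <- disruption_table(recs)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$t0, c(0, 0, 0))
  expect_equal(tab$t, c(7, 14, 7))
  expect_equal(tab$disruption[1], -2.5)
  # normalized-area variant rescales but keeps the sign
  tabn <- disruption_table(recs, use_normalized_area = TRUE)
  expect_equal(sign(tabn$disruption), sign(tab$disruption))
  expect_equal(tabn$disruption[1], ((150 - 100) / 100 * 100) / (40 - 60) * 1)
})
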
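#' Generate a single spheroid phantom with known ground truth
#'
#' Draws a bright-field-like spheroid: a star-cosine boundary
#' \eqn{r(\theta) = R\,(1 + a\cos k\theta)} enclosing a lighter halo around a
#' dark dense core disk, on a bright background, with additive Gaussian noise.
#' The star-cosine boundary gives an exact protrusion-count truth; all other
#' truth values (area, dense-core percentage) follow from the analytic
#' geometry, so every analysis stage can be validated without experimental
#' data.
#'
#' `fragmentation` emulates a disaggregating spheroid: a fraction `f` of the
#' halo (the region outside the core disk) is removed, the remainder kept as
#' radial tendrils still 4-connected to the core, and the removed pixel count
#' is scattered into detached specks painted into the *image* only — the truth
#' mask excludes them, mirroring what largest-component segmentation should
#' recover.
#'
#' The truth core is the *dense* region of the mask — the radius out to which
#' ring occupancy stays at/above `tau` by construction: the full star interior
#' radius \eqn{R(1 + a\cos(\pi\tau))} when the halo is solid, or the core disk
#' when fragmentation has made the halo sparser than `tau`. This matches the
#' occupancy-based definition of the core used by [core_threshold()].
#'
#' @param image_size Side length in pixels (square image).
#' @param base_radius Mean boundary radius \eqn{R} in pixels; must be smaller
#'   than `image_size / 2`.
#' @param core_radius_fraction Dark core disk radius as a fraction of
#'   `base_radius`.
#' @param n_protrusions Number of boundary lobes \eqn{k} (0 = disk).
#' @param protrusion_amplitude Lobe amplitude \eqn{a} as a fraction of
#'   `base_radius`.
#' @param core_intensity,halo_intensity,background_intensity Gray levels; the
#'   defaults depend on `polarity` (dark core on bright background for
#'   `"dark_on_bright"`).
#' @param noise_sigma Additive Gaussian noise standard deviation (gray
#'   levels).
#' @param polarity `"dark_on_bright"` (bright-field) or `"bright_on_dark"`
#'   (fluorescence-like).
#' @param fragmentation Fraction in `[0, 1)` of halo pixels removed and
#'   scattered as detached specks.
#' @param n_tendrils Number of radial tendrils carrying the surviving halo
#'   when `fragmentation > 0`.
#' @param bit_depth 8 or 16.
#' @param tau Occupancy criterion used for the truth core bookkeeping
#'   (matches the default of [core_threshold()]).
#' @param seed Integer seed; fully determines the output.
#' @return A list with elements `image` (a [spheroid_image()]) and `truth`, a
#'   list holding `mask` and `core_mask` (0/1 matrices), `true_area` (px^2),
#'   `true_percore` (percent), `true_n_protrusions`, `true_ct_radius` (px),
#'   `centroid` (0-based row/col) and `n_speck_pixels`.
#' @examples
#' ph <- make_phantom(n_protrusions = 5, protrusion_amplitude = 0.3, seed = 1)
#' ph$truth$true_n_protrusions
#' @export
make_phantom <- function(image_size = 256, base_radius = 60,
                         core_radius_fraction = 0.5,
                         n_protrusions = 0, protrusion_amplitude = 0,
                         core_intensity = NULL, halo_intensity = NULL,
                         background_intensity = NULL, noise_sigma = 8,
                         polarity = c("dark_on_bright", "bright_on_dark"),
                         fragmentation = 0, n_tendrils = 12,
                         bit_depth = 8, tau = 0.95, seed = 1) {
  polarity <- match.arg(polarity)
  if (base_radius >= image_size / 2)
    stop("base_radius must be smaller than image_size / 2")
  if (fragmentation < 0 || fragmentation >= 1)
    stop("fragmentation must be in [0, 1)")
  if (core_radius_fraction < 0 || core_radius_fraction > 1)
    stop("core_radius_fraction must be in [0, 1]")
  if (n_protrusions < 0 || protrusion_amplitude < 0 ||
      protrusion_amplitude >= 1)
    stop("invalid protrusion settings")
  maxval <- 2^bit_depth - 1
  defaults <- if (polarity == "dark_on_bright") {
    c(core = 60, halo = 160, background = 220) * (maxval / 255)
  } else {
    c(core = 200, halo = 120, background = 30) * (maxval / 255)
  }
  core_intensity <- core_intensity %||% defaults[["core"]]
  halo_intensity <- halo_intensity %||% defaults[["halo"]]
  background_intensity <- background_intensity %||% defaults[["background"]]
  if (any(c(core_intensity, halo_intensity, background_intensity) < 0) ||
      any(c(core_intensity, halo_intensity, background_intensity) > maxval))
    stop("intensities must lie within the bit depth")

  set.seed(as.integer(seed))
  n <- as.integer(image_size)
  center <- c((n - 1) / 2, (n - 1) / 2)
  dr <- (seq_len(n) - 1) - center[1]
  dc <- (seq_len(n) - 1) - center[2]
  dist <- sqrt(outer(dr^2, dc^2, `+`))
  theta <- atan2(outer(rep(1, n), dc), outer(dr, rep(1, n)))

  a <- protrusion_amplitude
  k <- as.integer(n_protrusions)
  r_boundary <- if (k > 0 && a > 0) {
    base_radius * (1 + a * cos(k * theta))
  } else {
    matrix(base_radius, n, n)
  }
  star <- dist <= r_boundary
  core_r <- core_radius_fraction * base_radius
  core_disk <- star & (dist <= core_r)

  halo <- star & !core_disk
  specks <- matrix(FALSE, n, n)
  if (fragmentation > 0) {
    # keep n_tendrils angular wedges covering a (1 - f) fraction of the halo
    frac <- (n_tendrils * (theta + pi) / (2 * pi)) %% 1
    kept_halo <- halo & (frac < (1 - fragmentation))
    n_removed <- sum(halo) - sum(kept_halo)
    mask <- core_disk | kept_halo
    # scatter detached single-cell debris into the image (not the truth
    # mask): sparse (<= 2% of the background) and kept >= 6 px away from the
    # spheroid so debris can never merge into the main component under the
    # default closing radius
    r_max <- max(r_boundary)
    region <- which(dist > r_max + 6 & dist < (n - 1) / 2)
    n_specks <- min(n_removed, round(0.02 * length(region)))
    if (length(region) > 0 && n_specks > 0) {
      specks[sample(region, n_specks)] <- TRUE
    }
  } else {
    mask <- star
  }
  mask <- largest_component(mask)  # guard: tendril geometry keeps this a no-op

  # truth core: dense region at occupancy criterion tau
  halo_dense <- fragmentation == 0 || (1 - fragmentation) >= tau
  true_ct <- if (!halo_dense) {
    core_r
  } else if (k > 0 && a > 0) {
    base_radius * (1 + a * cos(pi * tau))
  } else {
    base_radius
  }
  core_mask <- matrix(as.integer(mask > 0 & dist <= true_ct), n, n)

  img <- matrix(background_intensity, n, n)
  img[mask > 0] <- halo_intensity
  img[core_disk & mask > 0] <- core_intensity
  img[specks] <- halo_intensity
  if (noise_sigma > 0) img <- img + stats::rnorm(n * n, 0, noise_sigma)
  img <- matrix(pmin(pmax(round(img), 0), maxval), n, n)

  truth <- list(
    mask = mask, core_mask = core_mask,
    true_area = sum(mask), true_percore = 100 * sum(core_mask) / sum(mask),
    true_n_protrusions = if (a > 0) k else 0L,
    true_ct_radius = true_ct, centroid = center,
    n_speck_pixels = sum(specks))
  list(image = spheroid_image(img, bit_depth = bit_depth), truth = truth)
}

#' Generate a synthetic spheroid timecourse with known trends
#'
#' Produces a sequence of phantoms emulating the three canonical fates of a
#' treated spheroid:
#' \describe{
#'   \item{growth}{the spheroid expands (radius +10\% per step) with constant
#'     noise and core proportion — area rises, texture entropy stays stable.}
#'   \item{collapse}{the spheroid compacts (radius −10\% per step) while its
#'     core fraction rises and noise falls — area and entropy both decrease,
#'     the necrotic-core-like death mode.}
#'   \item{disruption}{the mass disaggregates: radius and fragmentation grow,
#'     the dense core shrinks, noise rises — area and entropy increase while
#'     the core percentage drops.}
#' }
#' All truth trends are monotone by construction.
#'
#' @param scenario `"growth"`, `"collapse"` or `"disruption"`.
#' @param n_timepoints Number of timepoints (>= 2).
#' @param seed Integer seed; fully determines the sequence.
#' @param base_radius Day-0 mean radius in pixels.
#' @return A list of length `n_timepoints`; each element is the
#'   [make_phantom()] output plus a `timepoint` field (0, 1, 2, ...).
#' @export
make_timecourse <- function(scenario = c("growth", "collapse", "disruption"),
                            n_timepoints = 3, seed = 1, base_radius = 60) {
  scenario <- match.arg(scenario)
  if (n_timepoints < 2) stop("n_timepoints must be >= 2")
  ts <- seq_len(n_timepoints) - 1
  par <- switch(scenario,
    growth = list(
      radius = base_radius * 1.10^ts, amplitude = rep(0.15, n_timepoints),
      k = 5L, core_frac = rep(0.55, n_timepoints),
      sigma = rep(8, n_timepoints), frag = rep(0, n_timepoints)),
    collapse = list(
      radius = base_radius * 0.90^ts, amplitude = rep(0.10, n_timepoints),
      k = 4L, core_frac = pmin(0.85, 0.50 + 0.10 * ts),
      sigma = pmax(1, 10 * 0.55^ts), frag = rep(0, n_timepoints)),
    disruption = list(
      radius = base_radius * 1.25^ts, amplitude = rep(0.20, n_timepoints),
      k = 6L, core_frac = pmax(0.15, 0.60 - 0.15 * ts),
      sigma = pmin(30, 8 * 1.45^ts), frag = pmin(0.85, 0.25 * ts)))
  # one image size for the whole sequence, wide enough for the largest frame
  need <- 2 * (max(par$radius) * (1 + max(par$amplitude)) + 24)
  size <- max(256L, as.integer(2 * ceiling(need / 2)))
  lapply(seq_len(n_timepoints), function(i) {
    ph <- make_phantom(
      image_size = size, base_radius = par$radius[i],
      core_radius_fraction = par$core_frac[i],
      n_protrusions = par$k, protrusion_amplitude = par$amplitude[i],
      noise_sigma = par$sigma[i], fragmentation = par$frag[i],
      seed = as.integer(seed) * 1000L + i)
    ph$timepoint <- ts[i]
    ph
  })
}

#' Write a ready-to-analyze synthetic dataset folder
#'
#' Renders one or more wells of a [make_timecourse()] scenario to disk in the
#' layout [scan_dataset()] expects (`<out>/<scenario>/<well>_d<t>.png`),
#' together with a `truth.csv` of generator ground truth and a `manifest.yaml`
#' recording the seeds.
#'
#' @param out Output folder (created if absent).
#' @param scenario Passed to [make_timecourse()].
#' @param n_wells Number of replicate wells.
#' @param n_timepoints Timepoints per well.
#' @param seed Integer master seed; well `w` uses `seed + w - 1`.
#' @return Invisibly, the condition folder path.
#' @export
write_synthetic_dataset <- function(out, scenario = "growth", n_wells = 2,
                                    n_timepoints = 3, seed = 1) {
  cond_dir <- file.path(out, scenario)
  dir.create(cond_dir, recursive = TRUE, showWarnings = FALSE)
  truth_rows <- list()
  for (w in seq_len(n_wells)) {
    tc <- make_timecourse(scenario, n_timepoints, seed = seed + w - 1L)
    for (ph in tc) {
      stem <- sprintf("w%d_d%d", w, ph$timepoint)
      png::writePNG(ph$image$pixels / 255,
                    file.path(cond_dir, paste0(stem, ".png")))
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        condition = scenario, well = sprintf("w%d", w),
        timepoint = ph$timepoint, true_area = ph$truth$true_area,
        true_percore = ph$truth$true_percore,
        true_n_protrusions = ph$truth$true_n_protrusions)
    }
  }
  utils::write.csv(do.call(rbind, truth_rows),
                   file.path(out, paste0(scenario, "_truth.csv")),
                   row.names = FALSE)
  yaml::write_yaml(list(scenario = scenario, n_wells = n_wells,
                        n_timepoints = n_timepoints, seed = seed),
                   file.path(out, paste0(scenario, "_manifest.yaml")))
  invisible(cond_dir)
}
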
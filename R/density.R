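#' Radial density profile over concentric rings
#'
#' Bins every image pixel into half-open annuli `[r, r + ring_width)` around
#' the spheroid centroid and reports per-ring density: by default the
#' *occupancy* (fraction of the ring's pixels, clipped to the image, that are
#' mask foreground), or the mean in-mask intensity (scaled to `[0, 1]`) with
#' `metric = "mean_intensity"`. The profile ends at the first ring with zero
#' occupancy or at the image corner distance, whichever comes first.
#'
#' @param mask A [spheroid_mask()] or binary matrix.
#' @param centroid 0-based `(row, col)`; defaults to the mask centroid. A
#'   centroid outside the mask bounding box triggers a warning but the
#'   profile is still computed.
#' @param ring_width Ring width in pixels (default 2).
#' @param metric `"occupancy"` (default) or `"mean_intensity"`.
#' @param image Intensity image, required for `metric = "mean_intensity"`.
#' @return A list of class `density_profile`: `rings` (data frame with
#'   `inner_radius`, `outer_radius`, `density`, `n_pixels`, `n_foreground`),
#'   `ring_width`, `centroid`, `metric`.
#' @export
density_profile <- function(mask, centroid = NULL, ring_width = 2,
                            metric = c("occupancy", "mean_intensity"),
                            image = NULL) {
  metric <- match.arg(metric)
  m <- as_mask_matrix(mask)
  if (!any(m > 0)) stop("empty mask has no density profile")
  if (is.null(centroid)) centroid <- mask_centroid(m)
  idx <- which(m > 0, arr.ind = TRUE)
  bbox <- c(range(idx[, 1]) - 1, range(idx[, 2]) - 1)
  if (centroid[[1]] < bbox[1] || centroid[[1]] > bbox[2] ||
      centroid[[2]] < bbox[3] || centroid[[2]] > bbox[4])
    warning("centroid lies outside the mask bounding box", call. = FALSE)
  dist <- pixel_distances(nrow(m), ncol(m), centroid)
  bin <- floor(dist / ring_width) + 1L
  nb <- max(bin)
  total <- tabulate(bin, nbins = nb)
  fg <- tabulate(bin[m > 0], nbins = nb)
  density <- ifelse(total > 0, fg / total, 0)
  if (metric == "mean_intensity") {
    if (is.null(image)) stop("metric 'mean_intensity' needs the image")
    x <- as_image_matrix(image)
    s <- tapply(x[m > 0], bin[m > 0], sum)
    isum <- numeric(nb)
    isum[as.integer(names(s))] <- s
    mx <- max(x[m > 0])
    density <- ifelse(fg > 0 & mx > 0, (isum / pmax(fg, 1)) / mx, 0)
  }
  # truncate at the first empty ring (inclusive)
  first_zero <- which(fg == 0)
  last <- if (length(first_zero)) min(first_zero) else nb
  keep <- seq_len(last)
  structure(list(
    rings = data.frame(
      inner_radius = (keep - 1) * ring_width,
      outer_radius = keep * ring_width,
      density = density[keep], n_pixels = total[keep],
      n_foreground = fg[keep]),
    ring_width = ring_width, centroid = centroid, metric = metric),
    class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("<density_profile %d rings of %g px (%s)>\n",
              nrow(x$rings), x$ring_width, x$metric))
  invisible(x)
}

#' Core Threshold: radius separating dense core from invasive edge
#'
#' The Core Threshold (CT) is the outer radius of the last ring in the
#' *initial* run of rings whose density is at least `tau`: walking outward
#' from the centroid, the core ends where ring density first drops below the
#' criterion. Starting the run at the innermost ring prevents detached dense
#' fragments further out from inflating the core. If the first ring already
#' fails, CT = 0 (an all-edge, fully fragmented spheroid).
#'
#' @param profile A [density_profile()].
#' @param tau Density criterion in (0, 1), default 0.95.
#' @return CT radius in pixels (>= 0).
#' @export
core_threshold <- function(profile, tau = 0.95) {
  stopifnot(inherits(profile, "density_profile"), tau > 0, tau < 1)
  dens <- profile$rings$density
  if (length(dens) == 0L) return(0)
  below <- which(dens < tau)
  run <- if (length(below)) min(below) - 1L else length(dens)
  if (run == 0L) return(0)
  profile$rings$outer_radius[run]
}

#' Core/edge density map and core percentage
#'
#' Labels every in-mask pixel as core (distance to centroid <= `ct`) or
#' edge, and reports the core percentage `percore = 100 * core / (core +
#' edge)`. Core and edge areas partition the mask exactly.
#'
#' @param mask A [spheroid_mask()] or binary matrix.
#' @param ct Core Threshold radius (from [core_threshold()]); >= 0.
#' @param centroid 0-based `(row, col)`; defaults to the mask centroid.
#' @return A list of class `density_map`: `labels` (0 = background,
#'   1 = edge, 2 = core), `percore`, `core_area`, `edge_area`,
#'   `core_threshold_radius`, `centroid`.
#' @export
density_map <- function(mask, ct, centroid = NULL) {
  stopifnot(ct >= 0)
  m <- as_mask_matrix(mask)
  if (!any(m > 0)) stop("empty mask has no density map")
  if (is.null(centroid)) centroid <- mask_centroid(m)
  dist <- pixel_distances(nrow(m), ncol(m), centroid)
  labels <- matrix(0L, nrow(m), ncol(m))
  labels[m > 0] <- 1L
  labels[m > 0 & dist <= ct] <- 2L
  core <- sum(labels == 2L)
  edge <- sum(labels == 1L)
  structure(list(labels = labels, percore = 100 * core / (core + edge),
                 core_area = core, edge_area = edge,
                 core_threshold_radius = ct, centroid = centroid),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map CT=%g px, percore=%.1f%%>\n",
              x$core_threshold_radius, x$percore))
  invisible(x)
}

#' Full radial density analysis of one mask
#'
#' Profile, Core Threshold and density map in one call.
#'
#' @inheritParams density_profile
#' @param tau Density criterion for [core_threshold()].
#' @return A `density_map` with the `density_profile` attached as `$profile`.
#' @export
spheroid_density <- function(mask, centroid = NULL, ring_width = 2,
                             tau = 0.95, metric = "occupancy", image = NULL) {
  prof <- density_profile(mask, centroid = centroid, ring_width = ring_width,
                          metric = metric, image = image)
  ct <- core_threshold(prof, tau = tau)
  dm <- density_map(mask, ct, centroid = prof$centroid)
  dm$profile <- prof
  dm
}

# fixed palette: background black, invasive edge blue, core red
DENSITY_PALETTE <- c(background = "#000000", edge = "#1F78B4",
                     core = "#E31A1C")

#' Render a density map as a color PNG
#'
#' Fixed three-color palette (background black, edge blue, core red);
#' identical inputs render to identical bytes.
#'
#' @param map A `density_map` from [density_map()].
#' @param path Optional PNG output path.
#' @return Invisibly, an `[nrow, ncol, 3]` RGB array in `[0, 1]`.
#' @export
render_density_map <- function(map, path = NULL) {
  rgb <- grDevices::col2rgb(DENSITY_PALETTE) / 255
  lab <- map$labels
  arr <- array(0, c(nrow(lab), ncol(lab), 3))
  for (k in 1:3) arr[, , k] <- matrix(rgb[k, lab + 1L], nrow(lab), ncol(lab))
  if (!is.null(path)) png::writePNG(arr, path)
  invisible(arr)
}
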
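# --- contour and perimeter ---------------------------------------------------

# largest-object oriented outer contour, 0-based (row, col)
outer_contour <- function(m) {
  oc <- EBImage::ocontour(EBImage::Image(m))
  if (length(oc) == 0L) stop("mask has no contour")
  oc[[which.max(vapply(oc, nrow, integer(1)))]]
}

# chain-code perimeter with Proffitt-Rosen MSE-optimal step weights:
# 0.948 per axial step, 1.343 per diagonal step. Raw pixel-edge counting
# would bias circularity of rasterized disks low by ~12%.
chain_perimeter <- function(contour) {
  n <- nrow(contour)
  if (n == 1L) return(4 * 0.948)  # lone pixel: treat as unit square
  nxt <- rbind(contour[-1, , drop = FALSE], contour[1, , drop = FALSE])
  dr <- abs(nxt[, 1] - contour[, 1])
  dc <- abs(nxt[, 2] - contour[, 2])
  diag <- dr == 1 & dc == 1
  axial <- xor(dr > 0, dc > 0)
  0.948 * sum(axial) + 1.343 * sum(diag)
}

#' Shape descriptors of a segmented spheroid
#'
#' Area (pixel count), chain-code perimeter, circularity
#' \eqn{4\pi A / P^2} (clamped to 1), specific surface (perimeter / area, a
#' boundary-to-mass ratio), centroid and equivalent-disk radius. When
#' `pixel_size` is set, physical area (`area_phys`) is reported as
#' `area_px2 * pixel_size^2`.
#'
#' @param mask A [spheroid_mask()] or binary matrix with a single foreground
#'   component.
#' @param pixel_size Physical length of a pixel edge (default 1).
#' @return A list of class `shape_features`: `area_px2`, `area_phys`,
#'   `perimeter`, `circularity`, `specific_surface`, `centroid` (0-based
#'   `(row, col)`), `equivalent_radius`.
#' @export
shape_features <- function(mask, pixel_size = 1) {
  m <- as_mask_matrix(mask)
  if (!any(m > 0)) stop("cannot compute shape features of an empty mask")
  area <- sum(m)
  per <- chain_perimeter(outer_contour(m))
  structure(list(
    area_px2 = area, area_phys = area * pixel_size^2, perimeter = per,
    circularity = min(1, 4 * pi * area / per^2),
    specific_surface = per / area,
    centroid = mask_centroid(m),
    equivalent_radius = sqrt(area / pi)),
    class = "shape_features")
}

#' @export
print.shape_features <- function(x, ...) {
  cat(sprintf("<shape_features area=%g px^2, perimeter=%.1f px, circ=%.3f>\n",
              x$area_px2, x$perimeter, x$circularity))
  invisible(x)
}

# fill NA gaps in a circular series by linear interpolation
fill_circular_na <- function(x) {
  if (!anyNA(x)) return(x)
  n <- length(x)
  ok <- which(!is.na(x))
  if (length(ok) == 0L) stop("no boundary samples to interpolate")
  xx <- stats::approx(x = c(ok - n, ok, ok + n), y = rep(x[ok], 3),
                      xout = seq_len(n))$y
  xx
}

#' Boundary radius profile and protrusion count
#'
#' Traces the outer boundary, measures the radius from the mask centroid,
#' resamples it onto uniform angular bins (decoupling protrusion counting
#' from contour sampling density), smooths circularly, and counts local
#' maxima whose topographic prominence reaches `min_prominence` times the
#' mean radius. Each counted maximum is one boundary protrusion. Circular
#' topology is respected throughout: there is no seam artifact at the
#' angular origin, and a constant profile (a disk) yields zero maxima.
#'
#' @param mask A [spheroid_mask()] or binary matrix, single component, not
#'   covering the whole image.
#' @param smoothing_window Moving-average window in angular samples; default
#'   5\% of `n_bins` (forced odd).
#' @param min_prominence Prominence threshold as a fraction of the mean
#'   radius (default 0.05).
#' @param n_bins Number of uniform angular bins (default 360).
#' @return A list of class `boundary_profile`: `samples` (traced boundary:
#'   `arc_index`, `angle`, `radius`), `profile` (binned: `angle`, `radius`,
#'   `radius_smooth`), `n_maxima`, `maxima_angles`, `centroid`.
#' @export
boundary_profile <- function(mask, smoothing_window = NULL,
                             min_prominence = 0.05, n_bins = 360) {
  m <- as_mask_matrix(mask)
  if (!any(m > 0)) stop("empty mask has no boundary")
  if (all(m > 0)) stop("mask covers the whole image: no closed boundary")
  touches <- c(any(m[1, ] > 0), any(m[nrow(m), ] > 0),
               any(m[, 1] > 0), any(m[, ncol(m)] > 0))
  if (all(touches)) stop("mask touches all four image borders: no closed boundary")
  ctr <- mask_centroid(m)
  contour <- outer_contour(m)
  dy <- contour[, 1] - ctr[["row"]]
  dx <- contour[, 2] - ctr[["col"]]
  radius <- sqrt(dy^2 + dx^2)
  angle <- atan2(dx, dy)  # consistent convention; absolute origin irrelevant
  if (any(radius == 0)) radius[radius == 0] <- .Machine$double.eps

  bin <- pmin(n_bins, floor((angle + pi) / (2 * pi) * n_bins) + 1L)
  binned <- rep(NA_real_, n_bins)
  agg <- tapply(radius, bin, max)  # outer boundary: furthest point per bin
  binned[as.integer(names(agg))] <- agg
  binned <- fill_circular_na(binned)

  window <- smoothing_window %||% max(3L, round(0.05 * n_bins))
  smoothed <- circular_smooth(binned, window)
  peaks <- circular_peaks(smoothed, min_prominence * mean(radius))
  centers <- -pi + (seq_len(n_bins) - 0.5) * 2 * pi / n_bins
  structure(list(
    samples = data.frame(arc_index = seq_len(nrow(contour)),
                         angle = angle, radius = radius),
    profile = data.frame(angle = centers, radius = binned,
                         radius_smooth = smoothed),
    n_maxima = nrow(peaks),
    maxima_angles = centers[peaks$index],
    centroid = ctr),
    class = "boundary_profile")
}

#' @export
print.boundary_profile <- function(x, ...) {
  cat(sprintf("<boundary_profile %d samples, %d protrusions>\n",
              nrow(x$samples), x$n_maxima))
  invisible(x)
}

# --- skeleton ----------------------------------------------------------------

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Zhang-Suen thinning; m is 0/1, returns 0/1 skeleton
zhang_suen <- function(m) {
  m <- matrix(as.integer(m > 0), nrow(m), ncol(m))
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # neighbors P2..P9 clockwise from north; north = row - 1
      p2 <- shift_mat(m, 1, 0);  p3 <- shift_mat(m, 1, -1)
      p4 <- shift_mat(m, 0, -1); p5 <- shift_mat(m, -1, -1)
      p6 <- shift_mat(m, -1, 0); p7 <- shift_mat(m, -1, 1)
      p8 <- shift_mat(m, 0, 1);  p9 <- shift_mat(m, 1, 1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- 0L
      for (i in 1:8) a <- a + (seqs[[i]] == 0L) * (seqs[[i + 1L]] == 1L)
      cond <- m == 1L & b >= 2L & b <= 6L & a == 1L
      if (sub == 1L) {
        cond <- cond & (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      } else {
        cond <- cond & (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' Skeleton endpoints of a segmented spheroid
#'
#' Computes the topological skeleton by Zhang-Suen thinning and counts its
#' endpoints (skeleton pixels with exactly one 8-connected skeleton
#' neighbor). Invading protrusions show up as skeleton branches, so the
#' endpoint count tracks boundary complexity; a compact disk thins to a
#' near-point with at most one endpoint.
#'
#' @param mask A [spheroid_mask()] or binary matrix, single component.
#' @return A list of class `skeleton_features`: `n_endpoints`,
#'   `skeleton_length` (skeleton pixel count), `skeleton` (0/1 matrix).
#' @export
skeleton_features <- function(mask) {
  m <- as_mask_matrix(mask)
  if (!any(m > 0)) stop("cannot skeletonize an empty mask")
  sk <- zhang_suen(m)
  if (!any(sk > 0)) {
    # parallel thinning can erase small compact blobs (the classic 2x2
    # failure); a non-empty mask degenerates to a point, not to nothing
    ctr <- round(mask_centroid(m)) + 1
    sk[ctr[1], ctr[2]] <- 1L
  }
  nb <- matrix(0L, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- nb + shift_mat(sk, dr, dc)
  }
  structure(list(
    n_endpoints = sum(sk == 1L & nb == 1L),
    skeleton_length = sum(sk),
    skeleton = sk),
    class = "skeleton_features")
}

#' @export
print.skeleton_features <- function(x, ...) {
  cat(sprintf("<skeleton_features %d endpoints, length %d px>\n",
              x$n_endpoints, x$skeleton_length))
  invisible(x)
}
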
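#' Segmentation settings
#'
#' Controls how the spheroid is separated from the background. Thresholding
#' happens on range-normalized intensities, which makes the resulting mask
#' invariant to global affine intensity shifts for the automatic methods.
#'
#' @param threshold_method `"otsu"` (default), `"triangle"` or `"fixed"`.
#' @param fixed_threshold Raw intensity cutoff, used only by `"fixed"`.
#' @param invert `"auto"` (default: polarity detected from the image border),
#'   `TRUE` (spheroid darker than background, bright-field) or `FALSE`
#'   (spheroid brighter, fluorescence-like).
#' @param min_object_fraction Candidate objects smaller than this fraction of
#'   the image area are discarded.
#' @param closing_radius Radius in pixels of the morphological closing
#'   applied before hole filling; 0 disables.
#' @param fill_holes Fill enclosed background holes in the mask.
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(threshold_method = c("otsu", "triangle", "fixed"),
                                fixed_threshold = NULL, invert = "auto",
                                min_object_fraction = 0.001,
                                closing_radius = 2, fill_holes = TRUE) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed" && is.null(fixed_threshold))
    stop("fixed_threshold is required when threshold_method = 'fixed'")
  stopifnot(min_object_fraction > 0, min_object_fraction < 1,
            closing_radius >= 0)
  if (!identical(invert, "auto")) invert <- isTRUE(invert)
  structure(list(threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold, invert = invert,
                 min_object_fraction = min_object_fraction,
                 closing_radius = as.integer(closing_radius),
                 fill_holes = isTRUE(fill_holes)),
            class = "segmentation_config")
}

no_spheroid_found <- function(msg, ref = NULL) {
  stop(errorCondition(msg, ref = ref,
                      class = c("noSpheroidFound", "error", "condition")))
}

otsu_vec <- function(v) {
  if (diff(range(v)) == 0) return(v[1])
  as.numeric(EBImage::otsu(EBImage::Image(matrix(v, ncol = 1)),
                           range = c(0, 1), levels = 256))
}

# triangle threshold on a 256-bin histogram of values in [0, 1]
triangle_threshold <- function(y) {
  h <- graphics::hist(y, breaks = seq(0, 1, length.out = 257), plot = FALSE)
  counts <- h$counts
  peak <- which.max(counts)
  nz <- which(counts > 0)
  tail_bin <- if ((max(nz) - peak) >= (peak - min(nz))) max(nz) else min(nz)
  if (tail_bin == peak) return(h$mids[peak])
  idx <- seq(peak, tail_bin)
  # distance of each histogram point from the peak-to-tail chord
  x1 <- peak; y1 <- counts[peak]; x2 <- tail_bin; y2 <- counts[tail_bin]
  d <- abs((y2 - y1) * idx - (x2 - x1) * counts[idx] + x2 * y1 - y2 * x1)
  h$mids[idx[which.max(d)]]
}

#' Segment the spheroid from the background
#'
#' Thresholds the image, applies morphological closing and hole filling, and
#' keeps the largest sufficiently large 4-connected component. The result is
#' a mask with exactly one foreground component — the contract every
#' downstream measurement relies on. Polarity (dark spheroid on bright
#' background or vice versa) is detected automatically by default: the side
#' of the threshold containing the median border intensity is taken as
#' background. A mask touching the image border is accepted with a warning
#' (heavily disaggregated spheroids can overflow the field of view).
#'
#' @param image A [spheroid_image()].
#' @param config A [segmentation_config()].
#' @return A [spheroid_mask()] carrying the image's `ref`.
#' @section Errors: signals a condition of class `noSpheroidFound` when the
#'   image is constant or no candidate object reaches `min_object_fraction`.
#' @export
segment_spheroid <- function(image, config = segmentation_config()) {
  x <- as_image_matrix(image)
  ref <- if (inherits(image, "spheroid_image")) image$ref else NULL
  rng <- range(x)
  if (diff(rng) == 0)
    no_spheroid_found("constant-intensity image: no separable object", ref)
  y <- (x - rng[1]) / diff(rng)

  if (config$threshold_method == "fixed") {
    thr <- (config$fixed_threshold - rng[1]) / diff(rng)
  } else if (config$threshold_method == "otsu") {
    thr <- otsu_vec(as.numeric(y))
  } else {
    thr <- triangle_threshold(y)
  }

  border <- c(y[1, ], y[nrow(y), ], y[, 1], y[, ncol(y)])
  border_med <- stats::median(border)
  invert <- config$invert
  if (identical(invert, "auto")) {
    invert <- border_med > thr  # bright border => dark spheroid
  }

  if (config$threshold_method == "otsu") {
    # Iterative background refinement: a single Otsu split on a trimodal
    # bright-field image (dark core, mid-gray halo, bright background) can
    # land between core and halo. Re-split the background side; while the
    # newly separated band is still clearly darker (resp. brighter) than the
    # border population - pure background by construction - it is tissue,
    # so absorb it into the foreground by moving the threshold.
    margin <- 2 * max(stats::mad(border), 4 / 256)
    for (it in 1:5) {
      u <- if (invert) y[y > thr] else y[y < thr]
      if (length(u) < 100 || diff(range(u)) == 0) break
      t2 <- otsu_vec(u)
      if (invert && border_med > t2 + margin && t2 > thr) thr <- t2
      else if (!invert && border_med < t2 - margin && t2 < thr) thr <- t2
      else break
    }
  }
  fg <- if (invert) y <= thr else y > thr

  m <- matrix(as.integer(fg), nrow(y), ncol(y))
  if (config$closing_radius > 0)
    m <- EBImage::closing(m, disc_brush(config$closing_radius))
  if (config$fill_holes) m <- EBImage::fillHull(m)
  lab <- EBImage::bwlabel(m > 0)
  if (max(lab) == 0L)
    no_spheroid_found("no foreground object after thresholding", ref)
  counts <- tabulate(lab[lab > 0])
  min_px <- config$min_object_fraction * length(m)
  ok <- which(counts >= min_px)
  if (length(ok) == 0L)
    no_spheroid_found(sprintf(
      "no candidate object reaches min_object_fraction (largest: %d px)",
      max(counts)), ref)
  keep <- ok[which.max(counts[ok])]
  mask <- matrix(as.integer(lab == keep), nrow(m), ncol(m))
  # texture support: thresholded tissue pixels within the final component.
  # Closing fillets and filled holes are background-intensity field pixels;
  # including them would let single outliers stretch the min-max
  # normalization range of the texture module.
  support <- matrix(as.integer(fg & mask > 0), nrow(m), ncol(m))
  if (any(mask[1, ] > 0) || any(mask[nrow(mask), ] > 0) ||
      any(mask[, 1] > 0) || any(mask[, ncol(mask)] > 0))
    warning("segmented spheroid touches the image border", call. = FALSE)
  out_ref <- if (!is.null(ref)) {
    image_ref(ref$path, ref$condition, ref$well, ref$timepoint, "mask")
  } else NULL
  out <- spheroid_mask(mask, ref = out_ref)
  out$support <- support
  out
}

#' Validate an externally supplied mask
#'
#' Pre-segmented masks are accepted as-is except for the single-component
#' contract: the largest 4-connected component is retained and, optionally,
#' holes are filled. A warning reports any removed pixels; an already-clean
#' mask is returned unchanged.
#'
#' @param mask A [spheroid_mask()] or binary matrix.
#' @param fill_holes Fill enclosed holes (default `TRUE`).
#' @return A [spheroid_mask()].
#' @export
validate_external_mask <- function(mask, fill_holes = TRUE) {
  ref <- if (inherits(mask, "spheroid_mask")) mask$ref else NULL
  m <- as_mask_matrix(mask)
  if (!any(m > 0)) stop("external mask is empty")
  cleaned <- largest_component(m)
  if (fill_holes) cleaned <- EBImage::fillHull(cleaned)
  removed <- sum(m) - sum(m & cleaned)
  if (removed > 0)
    warning(sprintf("external mask: %d pixels outside the main component removed",
                    removed), call. = FALSE)
  spheroid_mask(cleaned, ref = ref)
}
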
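#' Gray-level co-occurrence settings
#'
#' @param levels Gray-level count after quantization (default 64).
#' @param distance Pixel offset between co-occurring pixels (default 1).
#' @param angles Offset directions in degrees, averaged (default
#'   `c(0, 45, 90, 135)`).
#' @param symmetric Accumulate each pair in both directions (default `TRUE`).
#' @param log_base 2 (entropy in bits, default) or `exp(1)` (nats).
#' @return A list of class `glcm_config`.
#' @export
glcm_config <- function(levels = 64, distance = 1,
                        angles = c(0, 45, 90, 135), symmetric = TRUE,
                        log_base = 2) {
  stopifnot(levels >= 2, distance >= 1,
            all(angles %in% c(0, 45, 90, 135, 180, 225, 270, 315)))
  structure(list(levels = as.integer(levels), distance = as.integer(distance),
                 angles = angles, symmetric = isTRUE(symmetric),
                 log_base = log_base),
            class = "glcm_config")
}

# angle (degrees) -> (drow, dcol) offset at a given distance; north = row - 1
angle_offset <- function(angle, d) {
  switch(as.character(angle),
         "0"   = c(0L, d), "45"  = c(-d, d), "90"  = c(-d, 0L),
         "135" = c(-d, -d), "180" = c(0L, -d), "225" = c(d, -d),
         "270" = c(d, 0L), "315" = c(d, d),
         stop("unsupported GLCM angle: ", angle))
}

#' Min-max normalize spheroid intensities to quantized gray levels
#'
#' Normalization uses only in-mask pixels: the in-mask minimum maps to level
#' 0 and the in-mask maximum to `levels - 1`, making all downstream texture
#' statistics invariant to global intensity shifts. Background pixels are
#' set to `NA` and excluded from every texture statistic. A constant
#' in-mask intensity maps everything to level 0 (entropy will be 0).
#'
#' @param image A [spheroid_image()] or intensity matrix.
#' @param mask The paired [spheroid_mask()] (same dimensions).
#' @param levels Number of quantized levels (default 64).
#' @return An integer matrix of levels in `0..levels-1`, `NA` outside the
#'   mask, with attribute `levels`.
#' @export
normalize_grayscale <- function(image, mask, levels = 64) {
  x <- as_image_matrix(image)
  m <- as_mask_matrix(mask)
  if (!all(dim(x) == dim(m))) stop("image and mask dimensions differ")
  if (!any(m > 0)) stop("empty mask: nothing to normalize")
  inside <- m > 0
  lo <- min(x[inside]); hi <- max(x[inside])
  out <- matrix(NA_integer_, nrow(x), ncol(x))
  if (hi > lo) {
    out[inside] <- as.integer(round((x[inside] - lo) / (hi - lo) * (levels - 1)))
  } else {
    out[inside] <- 0L
  }
  attr(out, "levels") <- as.integer(levels)
  out
}

# co-occurrence probability matrix for one offset; NULL if no pairs
glcm_matrix <- function(q, offset, levels, symmetric) {
  nr <- nrow(q); nc <- ncol(q)
  dr <- offset[1]; dc <- offset[2]
  r1 <- max(1, 1 - dr):min(nr, nr - dr)
  c1 <- max(1, 1 - dc):min(nc, nc - dc)
  if (length(r1) == 0L || length(c1) == 0L) return(NULL)
  i <- q[r1, c1, drop = FALSE]
  j <- q[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(i) & !is.na(j)
  if (!any(ok)) return(NULL)
  counts <- matrix(tabulate(i[ok] * levels + j[ok] + 1L, nbins = levels^2),
                   levels, levels, byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  counts / sum(counts)
}

#' GLCM texture entropy of the spheroid interior
#'
#' Accumulates gray-level co-occurrences over pixel pairs with *both* pixels
#' inside the mask (background co-occurrences would otherwise dominate the
#' statistic), one matrix per configured angle at the configured distance,
#' normalized to probabilities. Entropy per angle is
#' \eqn{-\sum_{i,j} p(i,j)\log p(i,j)} with \eqn{0\log 0 = 0}; the reported
#' entropy is the mean over angles. Higher entropy means a more disordered
#' gray-level texture.
#'
#' @param normalized Quantized raster from [normalize_grayscale()].
#' @param config A [glcm_config()]; its `levels` must match the raster's.
#' @return A list of class `glcm_entropy`: `entropy` (mean over angles),
#'   `per_angle` (named vector), `glcm` (list of probability matrices).
#' @export
glcm_entropy <- function(normalized, config = glcm_config()) {
  levels <- attr(normalized, "levels") %||% config$levels
  if (levels != config$levels)
    stop("raster was quantized to ", levels, " levels but config says ",
         config$levels)
  mats <- lapply(config$angles, function(a) {
    glcm_matrix(normalized, angle_offset(a, config$distance), levels,
                config$symmetric)
  })
  names(mats) <- paste0("deg", config$angles)
  if (any(vapply(mats, is.null, logical(1))))
    stop("too few in-mask pixel pairs at the configured GLCM offset")
  ent <- vapply(mats, function(p) {
    nz <- p[p > 0]
    -sum(nz * log(nz, base = config$log_base))
  }, numeric(1))
  structure(list(entropy = mean(ent), per_angle = ent, glcm = mats),
            class = "glcm_entropy")
}

#' @export
print.glcm_entropy <- function(x, ...) {
  cat(sprintf("<glcm_entropy %.4f (mean of %d angles)>\n",
              x$entropy, length(x$per_angle)))
  invisible(x)
}

#' Mean and standard deviation of normalized gray values
#'
#' Population statistics over in-mask pixels of the quantized raster.
#'
#' @param normalized Raster from [normalize_grayscale()] (`NA` outside mask).
#' @return Named numeric vector `c(mean_gray, gray_std)`.
#' @export
gray_statistics <- function(normalized) {
  v <- normalized[!is.na(normalized)]
  if (length(v) == 0L) stop("empty mask: no gray statistics")
  mu <- mean(v)
  c(mean_gray = mu, gray_std = sqrt(mean((v - mu)^2)))
}

#' All texture features for one image/mask pair
#'
#' Convenience wrapper: normalization, GLCM entropy, gray statistics, and —
#' when a density map is supplied — entropy recomputed separately inside the
#' core and edge regions (a shrinking, uniform core lowers core entropy; a
#' disaggregating edge raises edge entropy). Regional entropies are `NA`
#' when a region is too small to form pixel pairs.
#'
#' @param image A [spheroid_image()].
#' @param mask The paired [spheroid_mask()].
#' @param config A [glcm_config()].
#' @param density Optional `density_map` (see [density_map()]) for regional
#'   entropies.
#' @return A list of class `texture_features`: `entropy`, `mean_gray`,
#'   `gray_std`, `entropy_core`, `entropy_edge`, `normalized`.
#' @export
texture_features <- function(image, mask, config = glcm_config(),
                             density = NULL) {
  q <- normalize_grayscale(image, mask, levels = config$levels)
  ent <- glcm_entropy(q, config)
  gs <- gray_statistics(q)
  regional <- function(region_value) {
    if (is.null(density)) return(NA_real_)
    qq <- q
    qq[density$labels != region_value] <- NA_integer_
    attr(qq, "levels") <- attr(q, "levels")
    tryCatch(glcm_entropy(qq, config)$entropy, error = function(e) NA_real_)
  }
  structure(list(entropy = ent$entropy,
                 mean_gray = unname(gs["mean_gray"]),
                 gray_std = unname(gs["gray_std"]),
                 entropy_core = regional(2L), entropy_edge = regional(1L),
                 normalized = q),
            class = "texture_features")
}

# fixed 16-color table (spectral-like), deterministic across runs
TEXTURE_LUT <- c(
  "#00008F", "#0000F5", "#005AFF", "#00BDFF", "#23FFDB", "#86FF78",
  "#E8FF16", "#FFD000", "#FF6D00", "#FF0A00", "#A60000", "#800000",
  "#8F0060", "#C400A8", "#F500E8", "#FF80FF")

#' Render the normalized spheroid texture with a 16-color table
#'
#' Bins the quantized gray levels uniformly into 16 colors (64 levels map 4
#' levels per color) to make texture differences visible at a glance;
#' background is black. The palette is fixed, so identical inputs render to
#' identical bytes.
#'
#' @param normalized Raster from [normalize_grayscale()].
#' @param path Optional PNG output path.
#' @return Invisibly, an `[nrow, ncol, 3]` RGB array in `[0, 1]`.
#' @export
render_texture_lut <- function(normalized, path = NULL) {
  levels <- attr(normalized, "levels") %||% (max(normalized, na.rm = TRUE) + 1L)
  bin <- pmin(15L, as.integer(floor(normalized / (levels / 16))))
  rgb <- grDevices::col2rgb(TEXTURE_LUT) / 255
  arr <- array(0, c(nrow(normalized), ncol(normalized), 3))
  inside <- !is.na(bin)
  for (k in 1:3) {
    plane <- matrix(0, nrow(normalized), ncol(normalized))
    plane[inside] <- rgb[k, bin[inside] + 1L]
    arr[, , k] <- plane
  }
  if (!is.null(path)) png::writePNG(arr, path)
  invisible(arr)
}
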
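#' Reference to one image file in a dataset
#'
#' An `image_ref` records where an image lives and which experimental unit it
#' belongs to: condition (folder name), well and timepoint (parsed from the
#' filename). `kind` distinguishes grayscale micrographs from binary masks and
#' is always derived from the folder layout, never from pixel content.
#'
#' @param path File path.
#' @param condition Condition label (typically the folder name).
#' @param well Well label.
#' @param timepoint Non-negative numeric timepoint (days or frame index).
#' @param kind `"grayscale"` or `"mask"`.
#' @param mask_path Optional path of the paired mask file (grayscale refs only).
#' @return An object of class `image_ref`.
#' @export
image_ref <- function(path, condition = "default", well = "w1",
                      timepoint = 0, kind = c("grayscale", "mask"),
                      mask_path = NA_character_) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(timepoint), length(timepoint) == 1L, timepoint >= 0)
  structure(
    list(path = as.character(path), condition = as.character(condition),
         well = as.character(well), timepoint = as.numeric(timepoint),
         kind = kind, mask_path = as.character(mask_path)),
    class = "image_ref")
}

#' @export
print.image_ref <- function(x, ...) {
  cat(sprintf("<image_ref %s | %s/%s t=%g | %s>\n",
              x$kind, x$condition, x$well, x$timepoint, x$path))
  invisible(x)
}

#' Single-channel spheroid micrograph
#'
#' Wraps a 2-D integer intensity matrix (rows x cols) with its bit depth,
#' physical pixel size and provenance. Intensities are kept exactly as read
#' from disk; any normalization is an explicit later step.
#'
#' @param pixels Numeric matrix of intensities, `[row, col]`.
#' @param bit_depth 8 or 16.
#' @param pixel_size Physical length of one pixel edge (default 1, i.e.
#'   results stay in pixel units).
#' @param ref Optional [image_ref()].
#' @return An object of class `spheroid_image`.
#' @export
spheroid_image <- function(pixels, bit_depth = 8, pixel_size = 1, ref = NULL) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 64 || ncol(pixels) < 64)
    stop("spheroid images must be at least 64x64 pixels")
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (is.null(ref)) ref <- image_ref(path = NA_character_)
  structure(list(pixels = pixels, bit_depth = as.integer(bit_depth),
                 pixel_size = as.numeric(pixel_size), ref = ref),
            class = "spheroid_image")
}

#' @export
print.spheroid_image <- function(x, ...) {
  cat(sprintf("<spheroid_image %dx%d, %d-bit, range [%g, %g]>\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Binary spheroid mask
#'
#' A 0/1 matrix marking spheroid foreground, paired with a grayscale
#' [spheroid_image()] of identical dimensions. Masks produced by
#' [segment_spheroid()] contain exactly one 4-connected foreground component;
#' externally supplied masks are brought to that state by
#' [validate_external_mask()].
#'
#' @param pixels Matrix coercible to 0/1 (any value > 0 is foreground).
#' @param ref Optional [image_ref()].
#' @return An object of class `spheroid_mask`.
#' @export
spheroid_mask <- function(pixels, ref = NULL) {
  pixels <- as.matrix(pixels)
  m <- matrix(as.integer(pixels > 0), nrow(pixels), ncol(pixels))
  if (is.null(ref)) ref <- image_ref(path = NA_character_, kind = "mask")
  structure(list(pixels = m, ref = ref), class = "spheroid_mask")
}

#' @export
print.spheroid_mask <- function(x, ...) {
  cat(sprintf("<spheroid_mask %dx%d, area %d px>\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels)))
  invisible(x)
}

# coerce helpers used throughout: accept the class or a bare matrix
as_mask_matrix <- function(mask) {
  if (inherits(mask, "spheroid_mask")) mask$pixels
  else matrix(as.integer(as.matrix(mask) > 0),
              nrow(as.matrix(mask)), ncol(as.matrix(mask)))
}

as_image_matrix <- function(image) {
  if (inherits(image, "spheroid_image")) image$pixels else as.matrix(image)
}
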
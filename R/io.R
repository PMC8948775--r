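IMAGE_EXTENSIONS <- c("tif", "tiff", "png")

#' Filename parsing rules for a dataset folder
#'
#' Datasets are laid out as one subfolder per experimental condition. Well
#' and timepoint are parsed from the file stem with a Perl regular expression
#' containing named groups `well` and `timepoint`; the default matches stems
#' like `w3_d14` (well `w3`, day 14). Masks may sit either in a `masks`
#' subfolder next to the grayscale files or in a `masks` subfolder sibling to
#' a `grayscale` subfolder, paired by identical stem.
#'
#' @param pattern Perl regex with named groups `well` and `timepoint`,
#'   matched against the file stem (name without extension).
#' @param grayscale_subdir,mask_subdir Subfolder names used when grayscale
#'   images and masks are separated.
#' @return A list of class `naming_config`.
#' @export
naming_config <- function(pattern = "^(?<well>[A-Za-z0-9]+)_d(?<timepoint>[0-9]+(\\.[0-9]+)?)$",
                          grayscale_subdir = "grayscale",
                          mask_subdir = "masks") {
  structure(list(pattern = pattern, grayscale_subdir = grayscale_subdir,
                 mask_subdir = mask_subdir), class = "naming_config")
}

# extract named groups well/timepoint from a stem; NULL when unparseable
parse_stem <- function(stem, pattern) {
  m <- regexpr(pattern, stem, perl = TRUE)
  if (m == -1L) return(NULL)
  st <- attr(m, "capture.start")[1, ]
  ln <- attr(m, "capture.length")[1, ]
  grab <- function(name) substr(stem, st[[name]], st[[name]] + ln[[name]] - 1L)
  tp <- suppressWarnings(as.numeric(grab("timepoint")))
  if (is.na(tp) || tp < 0) return(NULL)
  list(well = grab("well"), timepoint = tp)
}

file_stem <- function(path) tools::file_path_sans_ext(basename(path))

# list image files in a folder (non-recursive), warning on other files
list_image_files <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  ext <- tolower(tools::file_ext(files))
  skip <- files[!ext %in% IMAGE_EXTENSIONS]
  for (f in skip) warning("skipping non-image file: ", f, call. = FALSE)
  sort(files[ext %in% IMAGE_EXTENSIONS])
}

#' Scan a condition/well/timepoint dataset folder
#'
#' Walks `root_folder` (one subfolder per condition, or a flat folder treated
#' as a single condition), parses well and timepoint from each image filename
#' per `naming`, and pairs pre-made masks to their grayscale originals by
#' stem. Files that are not images or whose names do not parse are skipped
#' with a warning. Output order is deterministic: condition, well, timepoint,
#' then path, all ascending.
#'
#' @param root_folder Dataset root.
#' @param naming A [naming_config()].
#' @return A data frame of class `spheroid_dataset` with columns `path`,
#'   `condition`, `well`, `timepoint`, `kind` and `mask_path` (`NA` when no
#'   mask is paired).
#' @export
scan_dataset <- function(root_folder, naming = naming_config()) {
  if (!dir.exists(root_folder)) stop("root folder does not exist: ", root_folder)
  cond_dirs <- list.dirs(root_folder, recursive = FALSE)
  cond_dirs <- cond_dirs[!basename(cond_dirs) %in%
                           c(naming$grayscale_subdir, naming$mask_subdir,
                             "results")]
  if (length(cond_dirs) == 0L) cond_dirs <- root_folder
  rows <- list()
  for (cd in cond_dirs) {
    condition <- basename(cd)
    gdir <- file.path(cd, naming$grayscale_subdir)
    gray_dir <- if (dir.exists(gdir)) gdir else cd
    mdir <- file.path(cd, naming$mask_subdir)
    mask_files <- if (dir.exists(mdir)) list_image_files(mdir) else character()
    mask_by_stem <- stats::setNames(mask_files, file_stem(mask_files))
    for (f in list_image_files(gray_dir)) {
      p <- parse_stem(file_stem(f), naming$pattern)
      if (is.null(p)) {
        warning("unparseable filename, skipped: ", f, call. = FALSE)
        next
      }
      mp <- unname(mask_by_stem[file_stem(f)])
      rows[[length(rows) + 1L]] <- data.frame(
        path = f, condition = condition, well = p$well,
        timepoint = p$timepoint, kind = "grayscale",
        mask_path = if (length(mp) && !is.na(mp)) mp else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) stop("no parseable images found under ", root_folder)
  out <- do.call(rbind, rows)
  out <- out[order(out$condition, out$well, out$timepoint, out$path), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("spheroid_dataset", "data.frame")
  out
}

# one row of a spheroid_dataset -> image_ref
as_image_ref <- function(row) {
  image_ref(path = row$path, condition = row$condition, well = row$well,
            timepoint = row$timepoint, kind = row$kind,
            mask_path = row$mask_path)
}

read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    bits <- attr(x, "bits.per.sample") %||% if (max(x) > 255) 16L else 8L
    list(pixels = x, bit_depth = as.integer(bits))
  } else if (ext == "png") {
    x <- png::readPNG(path, info = TRUE)
    bits <- attr(x, "info")$bit.depth %||% 8L
    list(pixels = x * (2^bits - 1), bit_depth = as.integer(bits))
  } else {
    stop("unsupported image format: ", path)
  }
}

#' Read one grayscale image or mask
#'
#' Intensities are preserved bit-exact; no rescaling happens at read time
#' (intensity normalization is an explicit texture-analysis step). RGB files
#' are accepted only when all channels are identical. Mask files are
#' binarized by a `> 0` test.
#'
#' @param ref An [image_ref()], a row of a [scan_dataset()] table, or a bare
#'   path.
#' @param kind Overrides `ref$kind` when `ref` is a bare path.
#' @param pixel_size Physical pixel edge length attached to the result.
#' @return A [spheroid_image()] or [spheroid_mask()].
#' @export
read_image <- function(ref, kind = NULL, pixel_size = 1) {
  if (is.character(ref)) ref <- image_ref(ref, kind = kind %||% "grayscale")
  if (is.data.frame(ref)) ref <- as_image_ref(ref[1, ])
  kind <- kind %||% ref$kind
  raw <- read_raster(ref$path)
  x <- raw$pixels
  if (length(dim(x)) == 3L) {
    ch <- dim(x)[3]
    flat <- matrix(x, ncol = ch)
    if (ch >= 3L && !all(flat[, 1] == flat[, 2] & flat[, 1] == flat[, 3]))
      stop("multi-channel non-grayscale image: ", ref$path)
    x <- x[, , 1]
  }
  x <- round(as.matrix(x))
  if (kind == "mask") {
    spheroid_mask(x > 0, ref = ref)
  } else {
    spheroid_image(x, bit_depth = raw$bit_depth, pixel_size = pixel_size,
                   ref = ref)
  }
}

#' Write a binary mask to disk
#'
#' Foreground is written as white (1), background black; round-trips
#' bit-exact through [read_image()].
#'
#' @param mask A [spheroid_mask()] or 0/1 matrix.
#' @param path Output path; format chosen by extension (`.png` or `.tif`).
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  m <- as_mask_matrix(mask)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m * 1.0, path, bits.per.sample = 8L)
  } else {
    png::writePNG(m * 1.0, path)
  }
  invisible(path)
}

# flatten one spheroid_record into a single CSV row (NA -> empty cell later)
record_to_row <- function(rec) {
  num <- function(x) if (is.null(x) || length(x) == 0L) NA_real_ else as.numeric(x)
  data.frame(
    condition = rec$ref$condition, well = rec$ref$well,
    timepoint = rec$ref$timepoint, file = basename(rec$ref$path),
    area_px2 = num(rec$shape$area_px2), area_um2 = num(rec$shape$area_phys),
    perimeter_px = num(rec$shape$perimeter),
    circularity = num(rec$shape$circularity),
    specific_surface = num(rec$shape$specific_surface),
    equivalent_radius_px = num(rec$shape$equivalent_radius),
    centroid_row = num(rec$shape$centroid[["row"]]),
    centroid_col = num(rec$shape$centroid[["col"]]),
    n_protrusions = num(rec$boundary$n_maxima),
    n_skeleton_endpoints = num(rec$skeleton$n_endpoints),
    skeleton_length_px = num(rec$skeleton$skeleton_length),
    mean_gray = num(rec$texture$mean_gray),
    gray_std = num(rec$texture$gray_std),
    entropy = num(rec$texture$entropy),
    entropy_core = num(rec$texture$entropy_core),
    entropy_edge = num(rec$texture$entropy_edge),
    core_threshold_px = num(rec$density$core_threshold_radius),
    core_area_px2 = num(rec$density$core_area),
    edge_area_px2 = num(rec$density$edge_area),
    percore = num(rec$density$percore),
    stringsAsFactors = FALSE)
}

#' Write per-image results: table, masks and density maps
#'
#' Writes `results.csv` (one row per analyzed image; undefined values are
#' empty cells, never zero), a binarized mask PNG and a density-map PNG per
#' record. Re-running on the same inputs overwrites and is byte-identical.
#'
#' @param records List of `spheroid_record` objects from [analyze_image()].
#' @param out_folder Destination folder (created if needed).
#' @return Invisibly, the path of the written CSV.
#' @export
write_results <- function(records, out_folder) {
  dir.create(out_folder, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_folder) || file.access(out_folder, 2) != 0)
    stop("output folder not writable: ", out_folder)
  tab <- do.call(rbind, lapply(records, record_to_row))
  csv <- file.path(out_folder, "results.csv")
  utils::write.csv(tab, csv, row.names = FALSE, na = "")
  for (rec in records) {
    stem <- file_stem(rec$ref$path)
    if (!is.null(rec$mask))
      write_mask(rec$mask, file.path(out_folder, paste0(stem, "_mask.png")))
    if (!is.null(rec$density$labels))
      render_density_map(rec$density,
                         file.path(out_folder, paste0(stem, "_densitymap.png")))
  }
  invisible(csv)
}
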
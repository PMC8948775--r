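run_config_defaults <- function() {
  list(
    input_root = NULL, output_root = NULL,
    segmentation = list(threshold_method = "otsu", fixed_threshold = NULL,
                        invert = "auto", min_object_fraction = 0.001,
                        closing_radius = 2, fill_holes = TRUE),
    texture = list(levels = 64, distance = 1, angles = c(0, 45, 90, 135),
                   symmetric = TRUE, log_base = 2),
    density = list(tau = 0.95, ring_width = 2, metric = "occupancy"),
    boundary = list(smoothing_window = NULL, min_prominence = 0.05),
    disruption = list(form = "area_over_percore", epsilon = 1e-9,
                      use_normalized_area = FALSE),
    naming = list(pattern = naming_config()$pattern),
    skip_segmentation = FALSE, viability_csv = NULL,
    pixel_size = 1, log_level = "INFO")
}

check_known_keys <- function(given, known, where) {
  unknown <- setdiff(names(given), names(known))
  if (length(unknown) > 0)
    stop("unknown config key", if (length(unknown) > 1) "s", " in ", where,
         ": ", paste(unknown, collapse = ", "))
}

#' Assemble a pipeline run configuration
#'
#' All analysis parameters in one validated object, loadable from and
#' dumpable to a single YAML file. Unknown keys are rejected rather than
#' ignored, so typos fail fast.
#'
#' @param ... Overrides of the defaults; nested sections (`segmentation`,
#'   `texture`, `density`, `boundary`, `disruption`, `naming`) are lists and
#'   are merged key-wise.
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  given <- list(...)
  defaults <- run_config_defaults()
  check_known_keys(given, defaults, "config")
  cfg <- defaults
  for (k in names(given)) {
    if (is.list(defaults[[k]]) && !is.null(given[[k]])) {
      check_known_keys(given[[k]], defaults[[k]], k)
      cfg[[k]] <- utils::modifyList(defaults[[k]], given[[k]],
                                    keep.null = TRUE)
    } else {
      cfg[[k]] <- given[[k]]
    }
  }
  # construct the typed sub-configs now so invalid values fail here
  cfg$segmentation_config <- do.call(segmentation_config, cfg$segmentation)
  cfg$texture_config <- do.call(glcm_config, cfg$texture)
  stopifnot(cfg$density$tau > 0, cfg$density$tau < 1,
            cfg$density$ring_width > 0)
  structure(cfg, class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file with any subset of the [run_config()] keys.
#' @return A validated `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(run_config, yaml::read_yaml(path))
}

#' Write a run configuration to YAML
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(config_as_list(config), path)
  invisible(path)
}

config_as_list <- function(config) {
  keep <- names(run_config_defaults())
  out <- unclass(config)[keep]
  out[!vapply(out, is.null, logical(1))]
}

# md5 of the canonical YAML dump: changes iff any config value changes
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config_as_list(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Analyze one spheroid image into a full parameter record
#'
#' Runs the whole single-image chain: segmentation (or validation of a
#' supplied mask), shape descriptors, boundary protrusion profile, skeleton
#' endpoints, radial density analysis (profile, Core Threshold, core/edge
#' map) and GLCM texture, including per-region entropies.
#'
#' @param image A [spheroid_image()].
#' @param mask Optional pre-made [spheroid_mask()]; segmented from `image`
#'   when `NULL`.
#' @param config A [run_config()].
#' @return A list of class `spheroid_record` with elements `ref`, `shape`,
#'   `boundary`, `skeleton`, `texture`, `density`, `mask`.
#' @export
analyze_image <- function(image, mask = NULL, config = run_config()) {
  if (is.null(mask)) {
    mask <- segment_spheroid(image, config$segmentation_config)
  } else {
    mask <- validate_external_mask(mask,
                                   fill_holes = config$segmentation$fill_holes)
  }
  shape <- shape_features(mask, pixel_size = config$pixel_size)
  boundary <- tryCatch(
    boundary_profile(mask,
                     smoothing_window = config$boundary$smoothing_window,
                     min_prominence = config$boundary$min_prominence),
    error = function(e) {
      warning("boundary profile unavailable: ", conditionMessage(e),
              call. = FALSE)
      list(n_maxima = NA_integer_, samples = NULL)
    })
  skeleton <- skeleton_features(mask)
  density <- spheroid_density(mask, centroid = shape$centroid,
                              ring_width = config$density$ring_width,
                              tau = config$density$tau,
                              metric = config$density$metric, image = image)
  # texture is measured on tissue pixels: the thresholded support when the
  # mask came from segmentation (excludes background-intensity pixels added
  # by closing / hole filling), the mask itself otherwise
  tex_mask <- if (!is.null(mask$support)) spheroid_mask(mask$support) else mask
  texture <- texture_features(image, tex_mask, config = config$texture_config,
                              density = density)
  texture$normalized <- NULL  # rasters stay out of the record
  structure(list(ref = image$ref, shape = shape, boundary = boundary,
                 skeleton = skeleton, texture = texture, density = density,
                 mask = mask),
            class = "spheroid_record")
}

#' @export
print.spheroid_record <- function(x, ...) {
  cat(sprintf(
    "<spheroid_record %s/%s t=%g: area=%g px^2, circ=%.3f, %s protrusions, entropy=%.3f, percore=%.1f%%>\n",
    x$ref$condition, x$ref$well, x$ref$timepoint, x$shape$area_px2,
    x$shape$circularity, format(x$boundary$n_maxima), x$texture$entropy,
    x$density$percore))
  invisible(x)
}

pipe_log <- function(config, level, ...) {
  levels <- c(DEBUG = 1, INFO = 2, WARN = 3, ERROR = 4, QUIET = 5)
  if (levels[[level]] >= levels[[config$log_level %||% "INFO"]])
    message(sprintf("[%s] %s", level, paste0(...)))
}

#' Run the full batch pipeline over a dataset folder
#'
#' Scans `input_root`, analyzes every grayscale image (segmenting, or using
#' the paired mask when `skip_segmentation` is set), writes per-condition
#' results folders (results.csv, binarized masks, density maps), a combined
#' `results.csv` and `disruption.csv` under `output_root`, an optional
#' viability-correlation report, and a run manifest with the config hash and
#' per-file status. Failures are per-file: the file is logged and skipped,
#' the batch continues, and the returned `status` is 1 if anything failed.
#'
#' @param config A [run_config()] with `input_root` and `output_root` set.
#' @return Invisibly, a list: `records`, `results` (data frame),
#'   `disruption` (data frame), `viability` (or `NULL`), `manifest`,
#'   `status` (0 = all files analyzed).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$input_root) || is.null(config$output_root))
    stop("config must set input_root and output_root")
  naming <- naming_config(pattern = config$naming$pattern)
  ds <- scan_dataset(config$input_root, naming)
  gray <- ds[ds$kind == "grayscale", , drop = FALSE]
  if (isTRUE(config$skip_segmentation)) {
    missing <- gray$path[is.na(gray$mask_path)]
    if (length(missing) > 0)
      stop("skip_segmentation is set but masks are missing for:\n  ",
           paste(missing, collapse = "\n  "))
  }
  dir.create(config$output_root, recursive = TRUE, showWarnings = FALSE)

  records <- list()
  status <- character(nrow(gray))
  for (i in seq_len(nrow(gray))) {
    row <- gray[i, ]
    res <- tryCatch({
      img <- read_image(row, pixel_size = config$pixel_size)
      mask <- NULL
      if (isTRUE(config$skip_segmentation) || !is.na(row$mask_path)) {
        mask <- read_image(row$mask_path, kind = "mask")
        mask$ref <- img$ref
      }
      analyze_image(img, mask = mask, config = config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status[i] <- paste0("error: ", conditionMessage(res))
      pipe_log(config, "ERROR", row$path, " failed: ", conditionMessage(res))
    } else {
      status[i] <- "ok"
      records[[length(records) + 1L]] <- res
      pipe_log(config, "INFO", "analyzed ", row$path)
    }
  }
  if (length(records) == 0L) stop("no image could be analyzed")

  # per-condition results folders, then combined tables at the root
  conds <- vapply(records, function(r) r$ref$condition, character(1))
  for (cond in unique(conds)) {
    write_results(records[conds == cond],
                  file.path(config$output_root, cond, "results"))
  }
  results <- do.call(rbind, lapply(records, record_to_row))
  utils::write.csv(results, file.path(config$output_root, "results.csv"),
                   row.names = FALSE, na = "")
  disruption <- disruption_table(
    records, epsilon = config$disruption$epsilon,
    form = config$disruption$form,
    use_normalized_area = isTRUE(config$disruption$use_normalized_area))
  utils::write.csv(disruption, file.path(config$output_root, "disruption.csv"),
                   row.names = FALSE, na = "")

  viability <- NULL
  if (!is.null(config$viability_csv)) {
    vtab <- utils::read.csv(config$viability_csv, stringsAsFactors = FALSE)
    area_tab <- results[, c("condition", "well", "timepoint", "area_px2")]
    area_tab$normalized_area <- stats::ave(
      area_tab$area_px2, area_tab$condition, area_tab$well,
      FUN = function(a) 100 * a / a[1])
    viability <- correlate_viability(area_tab, vtab)
    vi <- list(pearson_r = viability$pearson_r, n = viability$n,
               fit = viability$fit)
    yaml::write_yaml(vi, file.path(config$output_root,
                                   "viability_correlation.yaml"))
  }

  manifest <- list(config_hash = config_hash(config),
                   n_images = nrow(gray),
                   n_analyzed = length(records),
                   files = stats::setNames(as.list(status), gray$path))
  yaml::write_yaml(manifest, file.path(config$output_root, "manifest.yaml"))
  invisible(list(records = records, results = results,
                 disruption = disruption, viability = viability,
                 manifest = manifest,
                 status = if (all(status == "ok")) 0L else 1L))
}
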
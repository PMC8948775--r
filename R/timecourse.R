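#' Normalize a per-well area trajectory to Day 0
#'
#' Expresses each area as a percentage of the area at the earliest
#' timepoint, the conventional way spheroid growth curves are reported: the
#' first value is exactly 100.
#'
#' @param areas Numeric vector of areas.
#' @param timepoints Numeric vector of timepoints, same length; the earliest
#'   defines the baseline.
#' @return Numeric vector of normalized areas (percent), in input order.
#' @export
normalize_to_day0 <- function(areas, timepoints = seq_along(areas) - 1) {
  stopifnot(length(areas) == length(timepoints), length(areas) >= 1)
  if (anyNA(areas) || anyNA(timepoints)) stop("NA in trajectory")
  base <- areas[which.min(timepoints)]
  if (base <= 0) stop("baseline area must be positive")
  100 * areas / base
}

delta_or_na <- function(x, y) if (is.null(x) || is.null(y)) NA_real_ else y - x

#' Spheroid disruption statistic between two timepoints
#'
#' Quantifies loss of spheroid integrity between a baseline and a later
#' timepoint by combining the three trend parameters into
#' \deqn{D = \frac{Area_t - Area_0}{Percore_t - Percore_0} \times \alpha,
#' \qquad \alpha = Entropy_t - Entropy_0.}
#' When texture entropy is rising (\eqn{\alpha > 0}), a negative value flags
#' a death process: total area and core percentage are trending in opposite
#' directions (the mass spreads while the dense core dissolves). When
#' entropy is *falling* the raw sign can invert; [classify_death_mode()] is
#' the recommended phenotype call in that regime. The statistic is undefined
#' when the core percentage did not change (`|delta_percore| < epsilon`).
#'
#' @param rec0,rect Baseline and later records: either `spheroid_record`
#'   objects from [analyze_image()] or plain lists with `area`, `percore`,
#'   `entropy` elements.
#' @param epsilon Guard for the `delta_percore` denominator (percentage
#'   points, default 1e-9).
#' @param form `"area_over_percore"` (the default reading of the statistic)
#'   or `"percore_over_area"` (the inverted ratio; same sign when
#'   \eqn{\alpha > 0}).
#' @return A list of class `disruption_result`: `well`, `t0`, `t`,
#'   `delta_area`, `delta_percore`, `alpha`, `disruption` (`NA` when not
#'   defined), `defined`.
#' @examples
#' r0 <- list(area = 100, percore = 60, entropy = 4)
#' r1 <- list(area = 150, percore = 40, entropy = 5)
#' spheroid_disruption(r0, r1)$disruption  # -2.5
#' @export
spheroid_disruption <- function(rec0, rect, epsilon = 1e-9,
                                form = c("area_over_percore",
                                         "percore_over_area")) {
  form <- match.arg(form)
  pull <- function(r, what) {
    if (inherits(r, "spheroid_record")) {
      switch(what, area = r$shape$area_px2, percore = r$density$percore,
             entropy = r$texture$entropy)
    } else r[[what]]
  }
  meta <- function(r, what, default) {
    if (inherits(r, "spheroid_record")) r$ref[[what]] else r[[what]] %||% default
  }
  d_area <- delta_or_na(pull(rec0, "area"), pull(rect, "area"))
  d_percore <- delta_or_na(pull(rec0, "percore"), pull(rect, "percore"))
  alpha <- delta_or_na(pull(rec0, "entropy"), pull(rect, "entropy"))
  defined <- is.finite(d_percore) && abs(d_percore) >= epsilon &&
    is.finite(d_area) && is.finite(alpha)
  disruption <- if (!defined) NA_real_
  else if (form == "area_over_percore") (d_area / d_percore) * alpha
  else (d_percore / d_area) * alpha
  structure(list(
    well = meta(rec0, "well", NA_character_),
    t0 = meta(rec0, "timepoint", NA_real_),
    t = meta(rect, "timepoint", NA_real_),
    delta_area = d_area, delta_percore = d_percore, alpha = alpha,
    disruption = disruption, defined = defined),
    class = "disruption_result")
}

#' @export
print.disruption_result <- function(x, ...) {
  cat(sprintf(
    "<disruption %s t%g->t%g: dArea=%.3g dPercore=%.3g alpha=%.3g D=%s>\n",
    x$well %||% "?", x$t0, x$t, x$delta_area, x$delta_percore, x$alpha,
    if (x$defined) sprintf("%.4g", x$disruption) else "undefined"))
  invisible(x)
}

#' Classify the fate of a spheroid trajectory
#'
#' Calls one of the three canonical phenotypes from the area and entropy
#' trends between two timepoints. A stable entropy (within the stability
#' band) indicates a self-consistent spheroid structure, so rising area with
#' stable entropy is growth. Shrinking area with falling entropy is
#' *collapse* (compaction into a uniform dense core); rising area with
#' rising entropy is *disruption* (progressive loss of integrity).
#' Everything else is indeterminate.
#'
#' @param area0,areat Areas at baseline and later timepoint.
#' @param entropy0,entropyt GLCM entropies at the two timepoints.
#' @param stability_band Entropy stability band as a fraction of `entropy0`
#'   (default 0.05).
#' @return One of `"growth"`, `"collapse"`, `"disruption"`,
#'   `"indeterminate"`.
#' @export
classify_death_mode <- function(area0, areat, entropy0, entropyt,
                                stability_band = 0.05) {
  stopifnot(is.finite(area0), is.finite(areat),
            is.finite(entropy0), is.finite(entropyt), entropy0 >= 0)
  d_area <- areat - area0
  d_ent <- entropyt - entropy0
  s <- stability_band * entropy0
  if (d_area > 0 && abs(d_ent) <= s) "growth"
  else if (d_area < 0 && d_ent < -s) "collapse"
  else if (d_area > 0 && d_ent > s) "disruption"
  else "indeterminate"
}

#' Disruption table for a set of analyzed records
#'
#' Groups records by (condition, well), takes the earliest timepoint of each
#' well as baseline, and computes one [spheroid_disruption()] row per later
#' timepoint, plus the [classify_death_mode()] call.
#'
#' @param records List of `spheroid_record` objects.
#' @param epsilon,form Passed to [spheroid_disruption()].
#' @param stability_band Passed to [classify_death_mode()].
#' @param use_normalized_area Use day-0-normalized areas in the statistic
#'   (rescales but does not change its sign).
#' @return A data frame with one row per (well, t0 -> t) pair.
#' @export
disruption_table <- function(records, epsilon = 1e-9,
                             form = "area_over_percore",
                             stability_band = 0.05,
                             use_normalized_area = FALSE) {
  key <- vapply(records, function(r) paste(r$ref$condition, r$ref$well,
                                           sep = "\r"), character(1))
  rows <- list()
  for (k in unique(key)) {
    recs <- records[key == k]
    tps <- vapply(recs, function(r) r$ref$timepoint, numeric(1))
    recs <- recs[order(tps)]
    tps <- sort(tps)
    base <- recs[[1]]
    base_area <- base$shape$area_px2
    for (i in seq_along(recs)[-1]) {
      r0 <- list(area = if (use_normalized_area) 100 else base_area,
                 percore = base$density$percore,
                 entropy = base$texture$entropy,
                 well = base$ref$well, timepoint = base$ref$timepoint)
      rt <- list(area = if (use_normalized_area)
                   100 * recs[[i]]$shape$area_px2 / base_area
                 else recs[[i]]$shape$area_px2,
                 percore = recs[[i]]$density$percore,
                 entropy = recs[[i]]$texture$entropy,
                 well = recs[[i]]$ref$well,
                 timepoint = recs[[i]]$ref$timepoint)
      d <- spheroid_disruption(r0, rt, epsilon = epsilon, form = form)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = base$ref$condition, well = base$ref$well,
        t0 = d$t0, t = d$t, delta_area = d$delta_area,
        delta_percore = d$delta_percore, alpha = d$alpha,
        disruption = if (d$defined) d$disruption else NA_real_,
        defined = d$defined,
        death_mode = classify_death_mode(r0$area, rt$area, r0$entropy,
                                         rt$entropy, stability_band),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(condition = character(), well = character(),
                      t0 = numeric(), t = numeric(), delta_area = numeric(),
                      delta_percore = numeric(), alpha = numeric(),
                      disruption = numeric(), defined = logical(),
                      death_mode = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$condition, out$well, out$t), , drop = FALSE]
}

#' Correlate spheroid area with viability readings
#'
#' Matches per-well morphology to a viability table by (condition, well,
#' timepoint), reports the Pearson correlation, and fits the power-law
#' calibration \eqn{viability = a\,x^{3/2} + b} over normalized area `x` by
#' least squares (the model is linear in \eqn{x^{3/2}}, so the fit is
#' closed-form). Unmatched rows are listed in a warning and excluded. At
#' least 3 matched pairs are required for the fit; with 2 pairs the fit is
#' refused (warning, `fit = NULL`) but the correlation is still returned.
#'
#' @param area_table Data frame with columns `condition`, `well`,
#'   `timepoint` and the area column named by `area_col`.
#' @param viability_table Data frame with columns `condition`, `well`,
#'   `timepoint`, `viability`.
#' @param area_col Name of the area column (default `"normalized_area"`).
#' @return A list of class `viability_correlation`: `pearson_r`, `n`,
#'   `fit` (list `a`, `b`, `se_a`, `se_b` or `NULL`), `pairs` (the matched
#'   data frame).
#' @export
correlate_viability <- function(area_table, viability_table,
                                area_col = "normalized_area") {
  need <- c("condition", "well", "timepoint")
  stopifnot(all(c(need, area_col) %in% names(area_table)),
            all(c(need, "viability") %in% names(viability_table)))
  merged <- merge(area_table, viability_table, by = need)
  lost_v <- nrow(viability_table) - nrow(merged)
  if (lost_v > 0) {
    key <- function(d) paste(d$condition, d$well, d$timepoint)
    miss <- setdiff(key(viability_table), key(area_table))
    warning("unmatched viability rows excluded: ",
            paste(miss, collapse = "; "), call. = FALSE)
  }
  x <- merged[[area_col]]
  v <- merged$viability
  if (length(x) < 2) stop("need at least 2 matched pairs for correlation")
  r <- stats::cor(x, v)
  fit <- NULL
  if (length(x) >= 3) {
    xm <- x^1.5
    lmfit <- stats::lm(v ~ xm)
    cf <- summary(lmfit)$coefficients
    fit <- list(a = unname(cf["xm", "Estimate"]),
                b = unname(cf["(Intercept)", "Estimate"]),
                se_a = unname(cf["xm", "Std. Error"]),
                se_b = unname(cf["(Intercept)", "Std. Error"]))
  } else {
    warning("fewer than 3 matched pairs: a*x^(3/2) + b fit refused",
            call. = FALSE)
  }
  structure(list(pearson_r = r, n = length(x), fit = fit, pairs = merged),
            class = "viability_correlation")
}

#' @export
print.viability_correlation <- function(x, ...) {
  cat(sprintf("<viability_correlation r=%.3f over %d pairs%s>\n",
              x$pearson_r, x$n,
              if (is.null(x$fit)) ", no fit"
              else sprintf(", a=%.3g b=%.3g", x$fit$a, x$fit$b)))
  invisible(x)
}
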
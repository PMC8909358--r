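## calibration: standard curves from spheroid digestion counts, area- and
## content-mediated viable-cell estimation, size-class binning.

#' Build a table of calibration points
#'
#' Each point is one digestion pool: the pooled spheroids' mean predictor
#' value (projected area in µm², protein in µg, or DNA in ng) against the
#' mean viable-cell count per spheroid from trypan-blue counting.
#'
#' @param predictor per-spheroid predictor values (> 0 where cells > 0).
#' @param viable_cells per-spheroid viable-cell counts (>= 0).
#' @param n_pooled spheroids pooled per digestion tube (>= 1); typical
#'   pools hold 8–15 spheroids.
#' @param method predictor type: "area", "protein" or "dna".
#' @return data.frame of class `calibration_points`.
#' @export
calibration_points <- function(predictor, viable_cells, n_pooled = 1L,
                               method = c("area", "protein", "dna")) {
  method <- match.arg(method)
  stopifnot(length(predictor) == length(viable_cells))
  if (any(viable_cells < 0)) {
    abort_sf("viable_cells must be non-negative", "sf_input_error")
  }
  if (any(predictor <= 0 & viable_cells > 0)) {
    abort_sf("predictor must be positive where viable_cells > 0", "sf_input_error")
  }
  df <- data.frame(predictor = predictor, viable_cells = viable_cells,
                   n_pooled = as.integer(n_pooled), method = method)
  class(df) <- c("calibration_points", "data.frame")
  df
}

#' Fit a linear standard curve mapping a predictor to viable cells
#'
#' Ordinary least squares `viable_cells = slope * predictor + intercept`.
#' The intercept is estimated, not forced through the origin: spheroids
#' carry a dead-core contribution to area that holds no viable cells.
#' Weighting by pool size is available but off by default.
#'
#' @param points a [calibration_points()] table with >= 2 distinct
#'   predictor values.
#' @param weight_by_pool weight each point by its pool size.
#' @return A `calibration_curve`: list with `method`, `slope` (cells per
#'   predictor unit), `intercept` (cells), `r_squared`, `n_points`,
#'   `predictor_range`.
#' @export
fit_calibration <- function(points, weight_by_pool = FALSE) {
  stopifnot(inherits(points, "calibration_points") || is.data.frame(points))
  if (length(unique(points$predictor)) < 2) {
    abort_sf("calibration needs at least 2 distinct predictor values",
             "sf_fit_error")
  }
  w <- if (weight_by_pool) points$n_pooled else NULL
  fit <- stats::lm(viable_cells ~ predictor, data = points, weights = w)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((points$viable_cells - mean(points$viable_cells))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(
    list(method = points$method[1] %||% "area",
         slope = unname(stats::coef(fit)["predictor"]),
         intercept = unname(stats::coef(fit)["(Intercept)"]),
         r_squared = max(0, min(1, r2)),
         n_points = nrow(points),
         predictor_range = range(points$predictor)),
    class = "calibration_curve"
  )
}

#' Estimate viable cells per spheroid from its projected area
#'
#' Applies an area-method standard curve; raw estimates are floored at 0
#' and rounded to the nearest cell. Areas beyond twice the calibrated
#' range are still converted but flagged as extrapolated.
#'
#' @param curve a `calibration_curve` with `method == "area"`.
#' @param area_um2 spheroid area(s) in µm².
#' @return data.frame with `cells_est` and `extrapolated_flag`.
#' @export
estimate_cells_from_area <- function(curve, area_um2) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$method != "area") {
    abort_sf("curve method must be 'area'", "sf_input_error")
  }
  raw <- curve$slope * area_um2 + curve$intercept
  clamped <- raw < 0
  if (any(clamped)) {
    warn_sf(sprintf("%d negative cell estimate(s) clamped to 0", sum(clamped)),
            "sf_clamp_warning")
  }
  extr <- area_um2 > 2 * curve$predictor_range[2] |
    area_um2 < curve$predictor_range[1] / 2
  data.frame(cells_est = as.integer(round(pmax(raw, 0))),
             extrapolated_flag = extr)
}

#' Per-cell content reference for protein/DNA normalization
#'
#' @param value µg protein per cell or ng DNA per cell (> 0), from a
#'   digestion-count standard curve.
#' @param blank assay blank (coating contribution), same unit (>= 0).
#' @param method "protein" or "dna".
#' @return A `content_per_cell` object.
#' @export
content_per_cell <- function(value, blank = 0, method = c("protein", "dna")) {
  method <- match.arg(method)
  if (!is_scalar_number(value) || value <= 0) {
    abort_sf("per-cell content must be a positive number", "sf_input_error")
  }
  if (!is_scalar_number(blank) || blank < 0) {
    abort_sf("blank must be non-negative", "sf_input_error")
  }
  structure(list(method = method, value = value, blank = blank),
            class = "content_per_cell")
}

#' Estimate cells per spheroid from total protein or DNA content
#'
#' `cells = (total - blank) / per_cell`, rounded. Totals below the blank
#' yield 0 with a warning (blank over-subtraction).
#'
#' @param total total content per well (µg protein or ng DNA).
#' @param per_cell a [content_per_cell()].
#' @return integer cell count(s).
#' @export
estimate_cells_from_content <- function(total, per_cell) {
  stopifnot(inherits(per_cell, "content_per_cell"))
  under <- total < per_cell$blank
  if (any(under)) {
    warn_sf(sprintf("%d well(s) with content below blank set to 0 cells",
                    sum(under)), "sf_clamp_warning")
  }
  as.integer(round(pmax(total - per_cell$blank, 0) / per_cell$value))
}

SIZE_CLASS_LABELS <- c("(07-10)k", "(11-15)k", "(16-22)k")

#' Assign spheroids to size classes by estimated cell number
#'
#' Classes follow the 7–10k / 11–15k / 16–22k cells-per-spheroid
#' convention; the gaps between published class labels are closed at the
#' midpoints (10,500 and 15,500) so the classes partition 7,000–22,000.
#' Counts outside the range map to "unclassified".
#'
#' @param cells integer cell count(s).
#' @param edges class boundaries, length 4 ascending (lower edge of the
#'   first class, two internal cuts, inclusive upper edge of the last).
#' @return factor with levels `(07-10)k`, `(11-15)k`, `(16-22)k`,
#'   `unclassified`.
#' @export
assign_size_class <- function(cells, edges = c(7000, 10500, 15500, 22000)) {
  stopifnot(length(edges) == 4, !is.unsorted(edges, strictly = TRUE))
  lab <- rep("unclassified", length(cells))
  lab[cells >= edges[1] & cells < edges[2]] <- SIZE_CLASS_LABELS[1]
  lab[cells >= edges[2] & cells < edges[3]] <- SIZE_CLASS_LABELS[2]
  lab[cells >= edges[3] & cells <= edges[4]] <- SIZE_CLASS_LABELS[3]
  factor(lab, levels = c(SIZE_CLASS_LABELS, "unclassified"))
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s: cells = %.4g * predictor + %.4g (R^2 = %.3f, n = %d)\n",
              x$method, x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}
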
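## qc: movement-artifact and completeness screening of wells before
## respiration-parameter extraction. Artifacts are excluded, never
## repaired.

QC_FLAGS <- c("rate_jump", "displaced", "incomplete", "border_truncated",
              "negative_rate")

#' Detect sudden OCR variations not explained by a drug injection
#'
#' For consecutive measurements within the same phase the relative jump
#' `J = |OCR_i - OCR_(i-1)| / max(|OCR_(i-1)|, epsilon)` is computed;
#' a well is flagged when any J exceeds `theta`. Pairs spanning an
#' injection boundary are never tested — a drug response is not an
#' artifact. The criterion is OCR-only; the corresponding ECAR jump
#' statistic is returned for information.
#'
#' @param pk a phase-labelled `plate_kinetics`.
#' @param theta relative jump threshold (default 0.4, i.e. 40%).
#' @param epsilon rate floor in pmol/min guarding the denominator.
#' @return data.frame: `well, rate_jump, jump_index, max_jump,
#'   max_ecar_jump`.
#' @export
detect_rate_jumps <- function(pk, theta = 0.4, epsilon = 1) {
  stopifnot(inherits(pk, "plate_kinetics"))
  if (all(is.na(pk$rates$phase))) {
    abort_sf("phases must be assigned before jump detection (see assign_phases)",
             "sf_state_error")
  }
  wells <- unique(pk$rates$well)
  out <- lapply(wells, function(w) {
    r <- pk$rates[pk$rates$well == w, , drop = FALSE]
    r <- r[order(r$measurement), , drop = FALSE]
    n <- nrow(r)
    if (n < 2) {
      return(data.frame(well = w, rate_jump = FALSE, jump_index = NA_integer_,
                        max_jump = NA_real_, max_ecar_jump = NA_real_))
    }
    same_phase <- r$phase[-1] == r$phase[-n]
    j_ocr <- abs(diff(r$ocr)) / pmax(abs(r$ocr[-n]), epsilon)
    j_ecar <- abs(diff(r$ecar)) / pmax(abs(r$ecar[-n]), epsilon)
    j_ocr[!same_phase] <- NA
    j_ecar[!same_phase] <- NA
    hit <- which(!is.na(j_ocr) & j_ocr > theta)
    data.frame(
      well = w,
      rate_jump = length(hit) > 0,
      jump_index = if (length(hit) > 0) r$measurement[hit[1] + 1L] else NA_integer_,
      max_jump = if (any(!is.na(j_ocr))) max(j_ocr, na.rm = TRUE) else NA_real_,
      max_ecar_jump = if (any(!is.na(j_ecar))) max(j_ecar, na.rm = TRUE) else NA_real_
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Flag spheroids displaced during the assay
#'
#' Compares pre- and post-assay centroids; a displacement above
#' `delta_um` marks the well as displaced (the spheroid left the sensor
#' spot). A missing post-assay result yields an `incomplete` flag
#' instead.
#'
#' @param pre,post `morphometry_result`s for the same well (`post` may be
#'   `NULL`).
#' @param delta_um displacement threshold in µm; the 200 µm default is of
#'   the order of a spheroid radius.
#' @return list with `displaced`, `incomplete`, `displacement_um`.
#' @export
detect_displacement <- function(pre, post, delta_um = 200) {
  if (is.null(post)) {
    return(list(displaced = FALSE, incomplete = TRUE, displacement_um = NA_real_))
  }
  d <- centroid_displacement(pre, post)
  list(displaced = d > delta_um, incomplete = FALSE, displacement_um = d)
}

#' Assemble per-well QC reports
#'
#' Merges jump detection, displacement, completeness and morphometry
#' border flags into one row per well, and applies the exclusion policy
#' (by default a well is excluded iff it carries any of `rate_jump`,
#' `displaced`, `incomplete`). Background wells are never excluded by
#' `rate_jump`: they carry no spheroid, so near-zero noise ratios are
#' meaningless there.
#'
#' @param pk a phase-labelled `plate_kinetics`.
#' @param jumps output of [detect_rate_jumps()] (computed if missing).
#' @param displacement optional data.frame `well, displacement_um` of
#'   pre/post centroid distances.
#' @param border_wells wells whose spheroid touched the image border.
#' @param theta,delta_um thresholds, see [detect_rate_jumps()] and
#'   [detect_displacement()].
#' @param exclude_on flags that trigger exclusion.
#' @return data.frame of class `qc_report`: `well, rate_jump, displaced,
#'   incomplete, border_truncated, negative_rate, jump_index,
#'   displacement_um, excluded`.
#' @export
qc_report <- function(pk, jumps = NULL, displacement = NULL,
                      border_wells = character(), theta = 0.4, delta_um = 200,
                      exclude_on = c("rate_jump", "displaced", "incomplete")) {
  stopifnot(all(exclude_on %in% QC_FLAGS))
  if (is.null(jumps)) jumps <- detect_rate_jumps(pk, theta = theta)
  wells <- unique(pk$rates$well)
  inc <- incomplete_wells(pk)
  bg <- pk$layout$well[pk$layout$is_background]
  neg <- vapply(wells, function(w) {
    any(pk$rates$ocr[pk$rates$well == w] < 0)
  }, logical(1))
  rep <- data.frame(well = wells, stringsAsFactors = FALSE)
  rep$rate_jump <- jumps$rate_jump[match(wells, jumps$well)] & !(wells %in% bg)
  rep$displaced <- FALSE
  rep$incomplete <- wells %in% inc
  rep$border_truncated <- wells %in% border_wells
  rep$negative_rate <- unname(neg) & !(wells %in% bg)
  rep$jump_index <- ifelse(rep$rate_jump, jumps$jump_index[match(wells, jumps$well)],
                           NA_integer_)
  rep$displacement_um <- NA_real_
  if (!is.null(displacement)) {
    i <- match(wells, displacement$well)
    rep$displacement_um <- displacement$displacement_um[i]
    rep$displaced <- !is.na(rep$displacement_um) & rep$displacement_um > delta_um
    rep$incomplete <- rep$incomplete |
      (!(wells %in% bg) & !is.na(i) & is.na(rep$displacement_um))
  }
  rep$excluded <- Reduce(`|`, lapply(exclude_on, function(f) rep[[f]]))
  class(rep) <- c("qc_report", "data.frame")
  rep
}

#' Remove excluded wells from a plate
#'
#' Wells flagged by the QC policy are dropped from the kinetics; the
#' exclusion table records every removed well with its reasons, so wells
#' in = wells out + exclusions. Under `policy = "report-only"` nothing is
#' removed. Excluding every sample well aborts with a diagnostic.
#'
#' @param pk a `plate_kinetics`.
#' @param report a [qc_report()] covering every well of `pk`.
#' @param policy "exclude" (default) or "report-only".
#' @return list with `kinetics` (filtered `plate_kinetics`) and
#'   `exclusions` (data.frame `well, flags`).
#' @export
apply_exclusions <- function(pk, report, policy = c("exclude", "report-only")) {
  policy <- match.arg(policy)
  wells <- unique(pk$rates$well)
  miss <- setdiff(wells, report$well)
  if (length(miss) > 0) {
    abort_sf(sprintf("QC report missing well(s): %s", paste(miss, collapse = ", ")),
             "sf_input_error")
  }
  flag_cols <- intersect(QC_FLAGS, names(report))
  drop <- report$well[report$excluded]
  excl <- report[report$excluded, , drop = FALSE]
  flags <- vapply(seq_len(nrow(excl)), function(i) {
    on <- vapply(flag_cols, function(f) isTRUE(excl[[f]][i]), logical(1))
    paste(flag_cols[on], collapse = ";")
  }, character(1))
  table <- data.frame(well = excl$well, flags = flags)
  rownames(table) <- NULL
  if (policy == "report-only" || length(drop) == 0) {
    return(list(kinetics = pk, exclusions = table[0, , drop = FALSE],
                flagged = table))
  }
  bg <- pk$layout$well[pk$layout$is_background]
  sample_wells <- setdiff(wells, bg)
  if (all(sample_wells %in% drop)) {
    abort_sf(sprintf("QC excluded all %d sample wells — check thresholds (theta/delta)",
                     length(sample_wells)), "sf_pipeline_error")
  }
  pk$rates <- pk$rates[!(pk$rates$well %in% drop), , drop = FALSE]
  rownames(pk$rates) <- NULL
  list(kinetics = pk, exclusions = table, flagged = table)
}
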
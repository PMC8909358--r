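## mito_stress: decompose a phase-labelled OCR series into the six
## respiration parameters, per well and under per-area / per-cell bases.

RATE_FIELDS <- c("non_mito", "basal_resp", "atp_linked", "proton_leak",
                 "maximal_resp", "spare_capacity",
                 "last_basal_ocr", "last_basal_ecar",
                 "stressed_ocr", "stressed_ecar")

#' Extract Mito Stress respiration parameters from one well
#'
#' Definitions (all rates in the well's recorded units):
#' * basal OCR — the *last* pre-injection measurement (the settled value,
#'   conventionally the 3rd cycle), not the basal-phase mean;
#' * `non_mito` — minimum OCR over the rotenone/antimycin A phase
#'   (post-injection rates keep falling, so the minimum, not the last
#'   point, is the residual);
#' * `basal_resp` = last basal − non_mito;
#' * `atp_linked` = last basal − minimum OCR over the oligomycin phase;
#' * `proton_leak` = oligomycin minimum − non_mito;
#' * `maximal_resp` = FCCP-phase maximum − non_mito;
#' * `spare_capacity` = maximal_resp − basal_resp;
#' * `spare_capacity_pct` = 100 * maximal_resp / basal_resp (undefined,
#'   with a quality flag, when basal_resp <= 0).
#'
#' Stressed OCR/ECAR are read at the FCCP-phase measurement where OCR is
#' maximal; basal ECAR at the last basal measurement.
#'
#' @param wk one well's kinetics: a data.frame with `measurement`, `ocr`,
#'   `ecar`, `phase` (e.g. from [well_kinetics()] after
#'   [assign_phases()]).
#' @param maximal_subtracts_non_mito the vendor convention (default)
#'   reports maximal respiration above the non-mitochondrial floor; set
#'   FALSE to report the raw FCCP plateau instead (spare capacity then
#'   follows from the same definition `maximal - basal`).
#' @return A `mito_stress_params` list, basis `per_well`.
#' @export
extract_params <- function(wk, maximal_subtracts_non_mito = TRUE) {
  stopifnot(is.data.frame(wk), all(c("measurement", "ocr", "ecar", "phase") %in% names(wk)))
  if (anyNA(wk$phase)) {
    abort_sf("phases must be assigned before parameter extraction", "sf_state_error")
  }
  missing_ph <- setdiff(PHASE_NAMES, unique(wk$phase))
  if (length(missing_ph) > 0) {
    abort_sf(sprintf("well %s has no measurements in phase(s): %s",
                     wk$well[1] %||% "?", paste(missing_ph, collapse = ", ")),
             "sf_incomplete_error")
  }
  wk <- wk[order(wk$measurement), , drop = FALSE]
  ph <- function(p) wk[wk$phase == p, , drop = FALSE]
  basal <- ph("basal"); oligo <- ph("oligomycin")
  fccp <- ph("fccp"); rot <- ph("rot_aa")

  last_basal <- basal$ocr[nrow(basal)]
  last_basal_ecar <- basal$ecar[nrow(basal)]
  oligo_min <- min(oligo$ocr)
  i_max <- which.max(fccp$ocr)
  fccp_max <- fccp$ocr[i_max]
  stressed_ecar <- fccp$ecar[i_max]
  non_mito <- min(rot$ocr)

  basal_resp <- last_basal - non_mito
  atp_linked <- last_basal - oligo_min
  proton_leak <- oligo_min - non_mito
  maximal_resp <- if (maximal_subtracts_non_mito) fccp_max - non_mito else fccp_max
  spare_capacity <- maximal_resp - basal_resp

  structure(
    list(non_mito = non_mito, basal_resp = basal_resp,
         atp_linked = atp_linked, proton_leak = proton_leak,
         maximal_resp = maximal_resp, spare_capacity = spare_capacity,
         spare_capacity_pct = if (basal_resp > 0) 100 * maximal_resp / basal_resp else NA_real_,
         last_basal_ocr = last_basal, last_basal_ecar = last_basal_ecar,
         stressed_ocr = fccp_max, stressed_ecar = stressed_ecar,
         basis = "per_well",
         quality_flag = if (basal_resp <= 0) "nonpositive_basal" else ""),
    class = "mito_stress_params"
  )
}

#' Re-express Mito Stress parameters per 1000 cells or per 1000 µm²
#'
#' Every rate field is divided by `cells / 1000` (basis
#' `per_1000_cells`) or `area / 1000` (basis `per_1000_um2`); the
#' denominator keeps the numbers O(1). `spare_capacity_pct` is a ratio
#' and is left unchanged.
#'
#' @param p a `mito_stress_params` with basis `per_well`.
#' @param cells viable-cell count (> 0), or
#' @param area spheroid area in µm² (> 0). Exactly one must be given.
#' @return A `mito_stress_params` on the new basis.
#' @export
normalize_params <- function(p, cells = NULL, area = NULL) {
  stopifnot(inherits(p, "mito_stress_params"))
  if (p$basis != "per_well") {
    abort_sf("parameters are already normalized", "sf_state_error")
  }
  if (is.null(cells) == is.null(area)) {
    abort_sf("give exactly one of cells or area", "sf_input_error")
  }
  denom <- if (!is.null(cells)) cells else area
  if (!is_scalar_number(denom) || denom <= 0) {
    abort_sf("normalization denominator must be a positive number",
             "sf_normalization_error")
  }
  for (f in RATE_FIELDS) p[[f]] <- p[[f]] / (denom / 1000)
  p$basis <- if (!is.null(cells)) "per_1000_cells" else "per_1000_um2"
  p
}

#' Extract parameters for every (non-background) well on a plate
#'
#' Incomplete wells are skipped with their ids recorded in the
#' `"skipped"` attribute.
#'
#' @param pk a phase-labelled `plate_kinetics`.
#' @return data.frame, one row per well, columns
#'   `well, basis, non_mito, basal_resp, atp_linked, proton_leak,
#'   maximal_resp, spare_capacity, spare_capacity_pct, last_basal_ocr,
#'   last_basal_ecar, stressed_ocr, stressed_ecar, quality_flag`.
#' @export
extract_params_plate <- function(pk) {
  stopifnot(inherits(pk, "plate_kinetics"))
  bg <- pk$layout$well[pk$layout$is_background]
  wells <- setdiff(unique(pk$rates$well), bg)
  inc <- incomplete_wells(pk)
  wells_ok <- setdiff(wells, inc)
  rows <- lapply(wells_ok, function(w) {
    p <- extract_params(well_kinetics(pk, w))
    data.frame(well = w, basis = p$basis,
               non_mito = p$non_mito, basal_resp = p$basal_resp,
               atp_linked = p$atp_linked, proton_leak = p$proton_leak,
               maximal_resp = p$maximal_resp, spare_capacity = p$spare_capacity,
               spare_capacity_pct = p$spare_capacity_pct,
               last_basal_ocr = p$last_basal_ocr,
               last_basal_ecar = p$last_basal_ecar,
               stressed_ocr = p$stressed_ocr, stressed_ecar = p$stressed_ecar,
               quality_flag = p$quality_flag)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- intersect(wells, inc)
  out
}

#' @export
print.mito_stress_params <- function(x, ...) {
  cat(sprintf("<mito_stress_params> basis %s\n", x$basis))
  for (f in c("basal_resp", "atp_linked", "proton_leak", "maximal_resp",
              "spare_capacity", "non_mito")) {
    cat(sprintf("  %-15s %8.3f\n", f, x[[f]]))
  }
  if (!is.na(x$spare_capacity_pct)) {
    cat(sprintf("  %-15s %7.1f%%\n", "spare (% basal)", x$spare_capacity_pct))
  }
  invisible(x)
}
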
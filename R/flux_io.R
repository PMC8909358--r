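## flux_io: rate-table and plate-layout IO, background correction,
## injection-phase labelling.
##
## A plate_kinetics object is a list with
##   $rates   data.frame(well, measurement, time_min, ocr, ecar, phase)
##   $layout  data.frame(well, group, is_background)
##   $schedule injection_schedule or NULL
##   $background_corrected logical
##   $units   c(ocr = "pmol O2/min/well", ecar = "mpH/min/well")
## Rates are always stored sorted by (well, measurement) so parsing is
## independent of input row order.

PHASE_NAMES <- c("basal", "oligomycin", "fccp", "rot_aa")

#' Injection schedule for a Mito Stress assay
#'
#' Maps 1-based measurement indices onto the four assay phases. Phases
#' must appear in canonical order (basal, oligomycin, fccp, rot_aa; any
#' suffix of later phases may be absent), with contiguous, non-overlapping
#' index blocks starting at 1.
#'
#' @param phases data.frame with columns `name`, `first`, `last`.
#' @param drug_conc_um optional named numeric, final drug concentration per
#'   phase in µM (metadata only; the standard kit uses 2 µM oligomycin,
#'   2 µM FCCP, 0.5 µM rotenone/antimycin A).
#' @return An `injection_schedule` object.
#' @seealso [default_mito_schedule()]
#' @export
injection_schedule <- function(phases, drug_conc_um = NULL) {
  stopifnot(is.data.frame(phases), all(c("name", "first", "last") %in% names(phases)))
  phases$name <- as.character(phases$name)
  bad <- setdiff(phases$name, PHASE_NAMES)
  if (length(bad) > 0) {
    abort_sf(sprintf("unknown phase name(s): %s", paste(bad, collapse = ", ")),
             "sf_schedule_error")
  }
  ord <- match(phases$name, PHASE_NAMES)
  if (is.unsorted(ord, strictly = TRUE)) {
    abort_sf("phases must be in order basal, oligomycin, fccp, rot_aa",
             "sf_schedule_error")
  }
  if (phases$first[1] != 1L) {
    abort_sf("first phase must start at measurement 1", "sf_schedule_error")
  }
  if (any(phases$last < phases$first)) {
    abort_sf("phase block with last < first", "sf_schedule_error")
  }
  if (nrow(phases) > 1 &&
      any(phases$first[-1] != phases$last[-nrow(phases)] + 1L)) {
    abort_sf("phase blocks must be contiguous and non-overlapping",
             "sf_schedule_error")
  }
  structure(
    list(phases = data.frame(name = phases$name,
                             first = as.integer(phases$first),
                             last = as.integer(phases$last)),
         drug_conc_um = drug_conc_um),
    class = "injection_schedule"
  )
}

#' Default 16-measurement Mito Stress schedule
#'
#' Basal 1–3, oligomycin 4–8, FCCP 9–12, rotenone/antimycin A 13–16 — the
#' standard spheroid Mito Stress cycle layout.
#'
#' @return An [injection_schedule()].
#' @export
default_mito_schedule <- function() {
  injection_schedule(
    data.frame(name = PHASE_NAMES,
               first = c(1L, 4L, 9L, 13L),
               last = c(3L, 8L, 12L, 16L)),
    drug_conc_um = c(oligomycin = 2, fccp = 2, rot_aa = 0.5)
  )
}

#' Read an injection schedule from a YAML config
#'
#' Expects `phases: [{name: basal, first: 1, last: 3}, ...]`.
#'
#' @param path YAML file path.
#' @return An [injection_schedule()].
#' @export
read_schedule <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$phases)) {
    abort_sf("schedule YAML must contain a 'phases' list", "sf_format_error")
  }
  ph <- do.call(rbind, lapply(cfg$phases, function(p) {
    data.frame(name = p$name, first = p$first, last = p$last)
  }))
  injection_schedule(ph, drug_conc_um = unlist(cfg$drug_conc_um))
}

#' Write an injection schedule to YAML
#' @param schedule an [injection_schedule()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  ph <- schedule$phases
  lst <- list(phases = lapply(seq_len(nrow(ph)), function(i) {
    list(name = ph$name[i], first = ph$first[i], last = ph$last[i])
  }))
  if (!is.null(schedule$drug_conc_um)) {
    lst$drug_conc_um <- as.list(schedule$drug_conc_um)
  }
  yaml::write_yaml(lst, path)
  invisible(path)
}

n_measurements <- function(schedule) max(schedule$phases$last)

phase_of_index <- function(schedule, idx) {
  ph <- schedule$phases
  out <- rep(NA_character_, length(idx))
  for (i in seq_len(nrow(ph))) {
    out[idx >= ph$first[i] & idx <= ph$last[i]] <- ph$name[i]
  }
  out
}

#' Read a plate layout CSV
#'
#' Layout CSV columns: `well,group,is_background`.
#'
#' @param path CSV file.
#' @return data.frame with columns well, group, is_background.
#' @export
read_layout <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "group", "is_background")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort_sf(sprintf("layout is missing column(s): %s", paste(miss, collapse = ", ")),
             "sf_format_error")
  }
  if (anyDuplicated(df$well)) {
    abort_sf("duplicate well ids in layout", "sf_duplicate_error")
  }
  df$is_background <- as.logical(df$is_background)
  df[order(df$well), need, drop = FALSE]
}

new_plate_kinetics <- function(rates, layout, schedule = NULL,
                               background_corrected = FALSE) {
  rates <- rates[order(rates$well, rates$measurement), , drop = FALSE]
  rownames(rates) <- NULL
  structure(
    list(rates = rates, layout = layout, schedule = schedule,
         background_corrected = background_corrected,
         units = c(ocr = "pmol O2/min/well", ecar = "mpH/min/well")),
    class = "plate_kinetics"
  )
}

#' Read a per-well rate table with its plate layout
#'
#' The rate CSV must have columns `well,measurement,time_min,OCR,ECAR`
#' (one row per well and measurement cycle; OCR in pmol O2/min/well, ECAR
#' in mpH/min/well). Parsing is independent of row order. Phases are left
#' unset and no background correction is applied — see [assign_phases()]
#' and [apply_background_correction()].
#'
#' @param path rate-table CSV.
#' @param layout_path plate-layout CSV (`well,group,is_background`).
#' @return A `plate_kinetics` object.
#' @export
read_rate_table <- function(path, layout_path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "measurement", "time_min", "OCR", "ECAR")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort_sf(sprintf("rate table is missing column(s): %s",
                     paste(miss, collapse = ", ")), "sf_format_error")
  }
  layout <- read_layout(layout_path)
  unknown <- setdiff(unique(df$well), layout$well)
  if (length(unknown) > 0) {
    abort_sf(sprintf("well(s) in rate table absent from layout: %s",
                     paste(unknown, collapse = ", ")), "sf_layout_error")
  }
  if (anyDuplicated(df[c("well", "measurement")])) {
    abort_sf("duplicate (well, measurement) records in rate table",
             "sf_duplicate_error")
  }
  rates <- data.frame(well = as.character(df$well),
                      measurement = as.integer(df$measurement),
                      time_min = as.numeric(df$time_min),
                      ocr = as.numeric(df$OCR),
                      ecar = as.numeric(df$ECAR),
                      phase = NA_character_)
  new_plate_kinetics(rates, layout)
}

#' Write a plate_kinetics rate table back to CSV
#'
#' Inverse of [read_rate_table()]; numeric rates are written at 6
#' significant digits (the declared round-trip precision).
#'
#' @param pk a `plate_kinetics`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(pk, path) {
  df <- data.frame(well = pk$rates$well,
                   measurement = pk$rates$measurement,
                   time_min = signif(pk$rates$time_min, 6),
                   OCR = signif(pk$rates$ocr, 6),
                   ECAR = signif(pk$rates$ecar, 6))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Subtract the background-well signal from every well
#'
#' For each measurement index the mean OCR (and mean ECAR) over background
#' wells is subtracted from every well, background wells included, so that
#' the background traces average to zero at every index.
#'
#' @param pk a `plate_kinetics` with `background_corrected = FALSE`.
#' @return The corrected `plate_kinetics`.
#' @export
apply_background_correction <- function(pk) {
  stopifnot(inherits(pk, "plate_kinetics"))
  if (isTRUE(pk$background_corrected)) {
    abort_sf("plate is already background-corrected", "sf_state_error")
  }
  bg_wells <- pk$layout$well[pk$layout$is_background]
  if (length(bg_wells) == 0) {
    abort_sf("background correction requested but layout has no background wells",
             "sf_config_error")
  }
  r <- pk$rates
  is_bg <- r$well %in% bg_wells
  bg_ocr <- tapply(r$ocr[is_bg], r$measurement[is_bg], mean)
  bg_ecar <- tapply(r$ecar[is_bg], r$measurement[is_bg], mean)
  key <- as.character(r$measurement)
  r$ocr <- as.vector(r$ocr - bg_ocr[key])
  r$ecar <- as.vector(r$ecar - bg_ecar[key])
  pk$rates <- r
  pk$background_corrected <- TRUE
  pk
}

#' Label every measurement with its injection phase
#'
#' Pure relabeling: rates are untouched. Idempotent; re-assigning with a
#' different schedule simply overwrites the labels.
#'
#' @param pk a `plate_kinetics`.
#' @param schedule an [injection_schedule()] covering all measurement
#'   indices present on the plate.
#' @return The labelled `plate_kinetics`.
#' @export
assign_phases <- function(pk, schedule = default_mito_schedule()) {
  stopifnot(inherits(pk, "plate_kinetics"), inherits(schedule, "injection_schedule"))
  idx <- sort(unique(pk$rates$measurement))
  ph <- phase_of_index(schedule, idx)
  if (anyNA(ph)) {
    abort_sf(sprintf("measurement index(es) outside schedule: %s",
                     paste(idx[is.na(ph)], collapse = ", ")),
             "sf_schedule_error")
  }
  pk$rates$phase <- phase_of_index(schedule, pk$rates$measurement)
  pk$schedule <- schedule
  pk
}

#' Extract one well's kinetics
#' @param pk a `plate_kinetics`.
#' @param well well id, e.g. "A1".
#' @return data.frame of that well's measurements, sorted by index.
#' @export
well_kinetics <- function(pk, well) {
  out <- pk$rates[pk$rates$well == well, , drop = FALSE]
  if (nrow(out) == 0) {
    abort_sf(sprintf("well '%s' not present on plate", well), "sf_layout_error")
  }
  rownames(out) <- NULL
  out
}

#' Wells with missing measurement cycles
#'
#' A well is incomplete when its measurement-index set is a strict subset
#' of the plate-wide union. Incomplete wells are excluded from parameter
#' extraction (no imputation: the parameters rely on within-phase
#' extremes).
#'
#' @param pk a `plate_kinetics`.
#' @return character vector of incomplete well ids.
#' @export
incomplete_wells <- function(pk) {
  full <- sort(unique(pk$rates$measurement))
  counts <- table(pk$rates$well)
  names(counts)[counts < length(full)]
}

#' @export
print.plate_kinetics <- function(x, ...) {
  cat(sprintf("<plate_kinetics> %d wells x %d measurements; background_corrected=%s; phases %s\n",
              length(unique(x$rates$well)),
              length(unique(x$rates$measurement)),
              x$background_corrected,
              if (all(is.na(x$rates$phase))) "unset" else "assigned"))
  invisible(x)
}
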
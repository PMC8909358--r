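## synthetic_cohort: simulate spheroid cohorts end-to-end — viable-cell
## counts, areas, fluorescence stacks and four-phase Mito Stress
## OCR/ECAR kinetics with protocol-dependent dispersion, background
## wells and optional movement artifacts — so every pipeline stage can
## be exercised against known truth.

#' Synthetic cell-line metabolic profile
#'
#' Parameterizes per-cell rates and the drug-response shape of the Mito
#' Stress kinetics. The bundled profiles contrast an aerobic line with a
#' glycolytic, stress-responsive one; both are synthetic and are not the
#' fitted parameters of any real line.
#'
#' @param name profile label.
#' @param per_cell_basal_ocr basal OCR, pmol O2/min per 1000 cells.
#' @param per_cell_basal_ecar basal ECAR, mpH/min per 1000 cells.
#' @param oligo_fraction OCR fraction remaining at the oligomycin
#'   plateau, in (0, 1).
#' @param fccp_multiplier maximal/basal OCR ratio under FCCP (>= 0).
#' @param non_mito_fraction residual OCR fraction after rotenone/
#'   antimycin A, in (0, 1), below `oligo_fraction`.
#' @param stress_ecar_multiplier post-FCCP/basal ECAR ratio (>= 1).
#' @return A `cell_line_profile` object.
#' @export
cell_line_profile <- function(name, per_cell_basal_ocr, per_cell_basal_ecar,
                              oligo_fraction, fccp_multiplier,
                              non_mito_fraction, stress_ecar_multiplier = 1.2) {
  stopifnot(per_cell_basal_ocr > 0, per_cell_basal_ecar > 0,
            oligo_fraction > 0, oligo_fraction < 1,
            fccp_multiplier >= 0, stress_ecar_multiplier >= 1)
  if (!(non_mito_fraction > 0 && non_mito_fraction < oligo_fraction)) {
    abort_sf("need 0 < non_mito_fraction < oligo_fraction < 1", "sf_input_error")
  }
  structure(list(name = name,
                 per_cell_basal_ocr = per_cell_basal_ocr,
                 per_cell_basal_ecar = per_cell_basal_ecar,
                 oligo_fraction = oligo_fraction,
                 fccp_multiplier = fccp_multiplier,
                 non_mito_fraction = non_mito_fraction,
                 stress_ecar_multiplier = stress_ecar_multiplier),
            class = "cell_line_profile")
}

#' @rdname cell_line_profile
#' @export
profile_aerobic <- function() {
  cell_line_profile("synthetic_aerobic",
                    per_cell_basal_ocr = 3.8, per_cell_basal_ecar = 1.5,
                    oligo_fraction = 0.55, fccp_multiplier = 1.6,
                    non_mito_fraction = 0.30, stress_ecar_multiplier = 1.3)
}

#' @rdname cell_line_profile
#' @export
profile_glycolytic <- function() {
  cell_line_profile("synthetic_glycolytic",
                    per_cell_basal_ocr = 1.3, per_cell_basal_ecar = 0.9,
                    oligo_fraction = 0.60, fccp_multiplier = 1.45,
                    non_mito_fraction = 0.35, stress_ecar_multiplier = 1.5)
}

#' Cohort simulation configuration
#'
#' Defaults encode the two protocol regimes: the single-spheroid,
#' U-bottom protocol (homogeneous cohorts, cell-count CV ~10%) and the
#' untreated-flask multiple-spheroids protocol (heterogeneous, CV ~50%).
#' Measurement noise is multiplicative at 8% CV; the area-to-cell
#' relation is linear with 0.03 cells/µm² so that 12,500 cells
#' correspond to ~417,000 µm², the scale of single-protocol spheroids
#' seeded at 10,000 cells/well.
#'
#' @param protocol "single" or "multiple".
#' @param n_wells number of sample wells.
#' @param n_background_wells background (no-spheroid) wells.
#' @param seeded_cells cells seeded per well (protocol range
#'   0.5–2 x 1e4).
#' @param growth_factor viable cells at assay time / seeded (> 1:
#'   spheroid formation is accompanied by some division).
#' @param cell_count_cv % CV of the lognormal viable-cell distribution;
#'   default 10 (single) or 50 (multiple).
#' @param area_slope,area_intercept cells = slope * area + intercept.
#' @param area_noise_cv % CV of multiplicative area measurement noise.
#' @param measurement_noise_cv % CV of multiplicative rate noise.
#' @param background_sd SD (pmol/min and mpH/min) of background traces.
#' @param artifact_wells list of `list(well =, index =, magnitude =)`
#'   movement artifacts: a persistent level drop by `magnitude`
#'   (fraction of the current rate) from measurement `index` onward.
#' @param schedule an [injection_schedule()].
#' @param seed mandatory RNG seed: no implicit randomness.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(protocol = c("single", "multiple"),
                          n_wells = 45L, n_background_wells = 4L,
                          seeded_cells = 10000, growth_factor = 1.25,
                          cell_count_cv = NULL,
                          area_slope = 0.03, area_intercept = 0,
                          area_noise_cv = 3, measurement_noise_cv = 8,
                          background_sd = 0.5,
                          artifact_wells = list(),
                          schedule = default_mito_schedule(),
                          seed) {
  protocol <- match.arg(protocol)
  if (missing(seed) || !is_count(seed)) {
    abort_sf("cohort_config requires an integer seed", "sf_config_error")
  }
  if (!is_count(n_wells) || n_wells < 1) {
    abort_sf("n_wells must be a positive integer", "sf_config_error")
  }
  cell_count_cv <- cell_count_cv %||% if (protocol == "single") 10 else 50
  stopifnot(cell_count_cv >= 0, area_noise_cv >= 0, measurement_noise_cv >= 0,
            growth_factor > 0, area_slope > 0)
  structure(list(protocol = protocol, n_wells = as.integer(n_wells),
                 n_background_wells = as.integer(n_background_wells),
                 seeded_cells = seeded_cells, growth_factor = growth_factor,
                 cell_count_cv = cell_count_cv,
                 area_slope = area_slope, area_intercept = area_intercept,
                 area_noise_cv = area_noise_cv,
                 measurement_noise_cv = measurement_noise_cv,
                 background_sd = background_sd,
                 artifact_wells = artifact_wells,
                 schedule = schedule, seed = as.integer(seed)),
            class = "cohort_config")
}

plate_well_ids <- function() {
  as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
}

## lognormal parameterized by mean and CV(%)
rlnorm_mean_cv <- function(n, mean, cv_pct) {
  if (cv_pct == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + (cv_pct / 100)^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

## deterministic kinetics: geometric approach of the rate toward each
## phase target. The first measurement after an injection uses a fast
## "entry" constant (drugs act quickly; that pair spans the injection
## and is never jump-tested), subsequent measurements a gentle "within"
## constant, so genuine within-phase drift steps stay ~15% and are not
## mistaken for movement artifacts
PHASE_APPROACH_K <- list(
  basal = c(entry = 1.0, within = 0.8),
  oligomycin = c(entry = 1.0, within = 0.35),
  fccp = c(entry = 1.5, within = 0.6),
  rot_aa = c(entry = 1.5, within = 0.35)
)

trajectory <- function(schedule, start, targets) {
  ph <- schedule$phases
  out <- numeric(n_measurements(schedule))
  v <- start
  for (i in seq_len(nrow(ph))) {
    k <- PHASE_APPROACH_K[[ph$name[i]]]
    tgt <- targets[[ph$name[i]]]
    for (m in ph$first[i]:ph$last[i]) {
      kk <- if (m == ph$first[i]) k[["entry"]] else k[["within"]]
      v <- tgt + (v - tgt) * exp(-kk)
      out[m] <- v
    }
  }
  out
}

noisy_positive <- function(x, cv_pct, counter) {
  if (cv_pct == 0) return(list(x = x, resampled = counter))
  out <- x * (1 + stats::rnorm(length(x), 0, cv_pct / 100))
  bad <- which(out <= 0)
  tries <- 0
  while (length(bad) > 0 && tries < 100) {
    out[bad] <- x[bad] * (1 + stats::rnorm(length(bad), 0, cv_pct / 100))
    counter <- counter + length(bad)
    bad <- bad[out[bad] <= 0]
    tries <- tries + 1
  }
  list(x = out, resampled = counter)
}

#' Simulate a spheroid cohort with Mito Stress kinetics
#'
#' Per well: a true viable-cell count is drawn lognormal around
#' `seeded_cells * growth_factor` at the protocol's CV; area follows the
#' linear area-cell relation with measurement noise; the OCR series
#' starts ~15% above basal, settles during the basal phase, then decays
#' toward the oligomycin plateau, rises toward the FCCP maximum and
#' falls toward the non-mitochondrial residual (geometric approach per
#' phase), all scaled by the per-cell rates and perturbed by
#' multiplicative noise. ECAR is analogous with its stress multiplier.
#' Background wells carry zero-mean noise. Movement artifacts are
#' persistent level drops at configured indices.
#'
#' @param cfg a [cohort_config()].
#' @param profile a [cell_line_profile()].
#' @return list of class `cohort_sim`:
#'   * `kinetics` — `plate_kinetics` (phases unset, not background-
#'     corrected) including background wells;
#'   * `truth` — per-well data.frame (`well, true_cells, area_um2,
#'     basal_ocr, basal_ecar, artifact, artifact_index`);
#'   * `calibration` — [calibration_points()] from simulated digestion
#'     pools over the seeding range 5k–20k;
#'   * `profile`, `config`; attribute `resampled` counts noise redraws
#'     forced positive.
#' @export
simulate_cohort <- function(cfg, profile = profile_aerobic()) {
  stopifnot(inherits(cfg, "cohort_config"), inherits(profile, "cell_line_profile"))
  set.seed(cfg$seed)
  ids <- plate_well_ids()
  n <- cfg$n_wells
  if (n + cfg$n_background_wells > length(ids)) {
    abort_sf("more wells requested than a 96-well plate holds", "sf_config_error")
  }
  wells <- ids[seq_len(n)]
  bg_wells <- ids[n + seq_len(cfg$n_background_wells)]
  n_meas <- n_measurements(cfg$schedule)
  times <- (seq_len(n_meas)) * 6.5  # ~6.5 min per measurement cycle

  cells <- rlnorm_mean_cv(n, cfg$seeded_cells * cfg$growth_factor, cfg$cell_count_cv)
  area_true <- (cells - cfg$area_intercept) / cfg$area_slope
  area_obs <- area_true * (1 + stats::rnorm(n, 0, cfg$area_noise_cv / 100))

  resampled <- 0L
  art_by_well <- list()
  for (a in cfg$artifact_wells) art_by_well[[a$well]] <- a

  rows <- vector("list", n + cfg$n_background_wells)
  for (i in seq_len(n)) {
    B <- cells[i] / 1000 * profile$per_cell_basal_ocr
    E <- cells[i] / 1000 * profile$per_cell_basal_ecar
    ocr_det <- trajectory(cfg$schedule, start = 1.15 * B,
                          targets = list(basal = B,
                                         oligomycin = profile$oligo_fraction * B,
                                         fccp = profile$fccp_multiplier * B,
                                         rot_aa = profile$non_mito_fraction * B))
    ecar_det <- trajectory(cfg$schedule, start = 1.10 * E,
                           targets = list(basal = E,
                                          oligomycin = E,
                                          fccp = profile$stress_ecar_multiplier * E,
                                          rot_aa = 0.8 * E))
    no <- noisy_positive(ocr_det, cfg$measurement_noise_cv, resampled)
    resampled <- no$resampled
    ne <- noisy_positive(ecar_det, cfg$measurement_noise_cv, resampled)
    resampled <- ne$resampled
    ocr <- no$x; ecar <- ne$x
    a <- art_by_well[[wells[i]]]
    if (!is.null(a)) {
      span <- a$index:n_meas
      ocr[span] <- ocr[span] * (1 - a$magnitude)
      ecar[span] <- ecar[span] * (1 - a$magnitude)
    }
    rows[[i]] <- data.frame(well = wells[i], measurement = seq_len(n_meas),
                            time_min = times, ocr = ocr, ecar = ecar,
                            phase = NA_character_)
  }
  for (j in seq_len(cfg$n_background_wells)) {
    rows[[n + j]] <- data.frame(well = bg_wells[j], measurement = seq_len(n_meas),
                                time_min = times,
                                ocr = stats::rnorm(n_meas, 0, cfg$background_sd),
                                ecar = stats::rnorm(n_meas, 0, cfg$background_sd),
                                phase = NA_character_)
  }
  layout <- data.frame(
    well = c(wells, bg_wells),
    group = c(rep(paste(profile$name, cfg$protocol, sep = "_"), n),
              rep("background", cfg$n_background_wells)),
    is_background = c(rep(FALSE, n), rep(TRUE, cfg$n_background_wells))
  )
  layout <- layout[order(layout$well), , drop = FALSE]
  rownames(layout) <- NULL

  art_idx <- vapply(wells, function(w) {
    a <- art_by_well[[w]]; if (is.null(a)) NA_integer_ else as.integer(a$index)
  }, integer(1))
  truth <- data.frame(well = wells, true_cells = cells,
                      area_um2 = area_obs, area_true_um2 = area_true,
                      basal_ocr = cells / 1000 * profile$per_cell_basal_ocr,
                      basal_ecar = cells / 1000 * profile$per_cell_basal_ecar,
                      artifact = !is.na(art_idx), artifact_index = art_idx)

  ## digestion-pool calibration: pools of 8-15 spheroids per seeding
  ## density over the plated range 5k-20k cells/well
  cal_rows <- list()
  for (seeded in c(5000, 10000, 15000, 20000)) {
    for (p in 1:5) {
      pool <- sample(8:15, 1)
      pc <- rlnorm_mean_cv(pool, seeded * cfg$growth_factor, cfg$cell_count_cv)
      pa <- (pc - cfg$area_intercept) / cfg$area_slope *
        (1 + stats::rnorm(pool, 0, cfg$area_noise_cv / 100))
      cal_rows[[length(cal_rows) + 1L]] <-
        data.frame(predictor = mean(pa), viable_cells = mean(pc), n_pooled = pool)
    }
  }
  cal <- do.call(rbind, cal_rows)
  cal <- calibration_points(cal$predictor, cal$viable_cells, cal$n_pooled, "area")

  structure(
    list(kinetics = new_plate_kinetics(do.call(rbind, rows), layout,
                                       schedule = NULL,
                                       background_corrected = FALSE),
         truth = truth, calibration = cal,
         profile = profile, config = cfg),
    class = "cohort_sim", resampled = resampled
  )
}

#' Write a simulated cohort in the pipeline's CSV/YAML dialects
#'
#' Emits `rates.csv`, `layout.csv`, `schedule.yaml`, `areas.csv`,
#' `calibration.csv` and `truth.csv` under `dir`.
#'
#' @param sim a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "cohort_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_rate_table(sim$kinetics, file.path(dir, "rates.csv"))
  write_sf_csv(sim$kinetics$layout, file.path(dir, "layout.csv"))
  write_schedule(sim$config$schedule, file.path(dir, "schedule.yaml"))
  write_sf_csv(data.frame(well = sim$truth$well,
                          area_um2 = sim$truth$area_um2),
               file.path(dir, "areas.csv"), signif = 6)
  write_sf_csv(data.frame(predictor_value = sim$calibration$predictor,
                          viable_cells = sim$calibration$viable_cells,
                          n_pooled = sim$calibration$n_pooled,
                          method = sim$calibration$method),
               file.path(dir, "calibration.csv"), signif = 6)
  write_sf_csv(sim$truth, file.path(dir, "truth.csv"), signif = 6)
  invisible(dir)
}

## Ramanujan's ellipse perimeter (relative error < 1e-5 for the axis
## ratios used here)
ellipse_perimeter <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

ellipse_axis_ratio_for_roundness <- function(target) {
  if (target >= 1) return(1)
  f <- function(q) {
    a <- sqrt(q); b <- 1 / sqrt(q)
    circularity(pi * a * b, ellipse_perimeter(a, b)) - target
  }
  stats::uniroot(f, c(1 + 1e-9, 200), tol = 1e-10)$root
}

#' Simulate a fluorescence z-stack of one spheroid
#'
#' Draws an ellipse whose area follows the cohort's linear area-cell
#' relation and whose axis ratio is tuned so its analytic circularity
#' hits `roundness_target`; the shape is Gaussian-blurred, replicated
#' over `n_planes` with a Gaussian intensity falloff in z, and additive
#' noise at the requested SNR is added per plane.
#'
#' @param cells viable-cell count (> 0).
#' @param roundness_target analytic circularity of the drawn ellipse, in
#'   (0, 1].
#' @param pixel_size_um µm per pixel.
#' @param seed RNG seed.
#' @param n_planes stack depth (>= 8 mirrors the acquisition protocol).
#' @param snr peak-signal to noise-SD ratio.
#' @param area_slope,area_intercept the cohort's area-cell relation.
#' @param center_offset_px shift of the spheroid center from the image
#'   center, in pixels (for displacement tests).
#' @param canvas_px image side length; chosen automatically if NULL.
#' @param blur_sigma rim softness in pixels.
#' @return list of class `spheroid_image_sim`: `stack` (an
#'   [image_stack()]) and `truth` (`area_um2` of the rasterized mask,
#'   analytic `roundness`, `centroid_um`).
#' @export
simulate_spheroid_image <- function(cells, roundness_target = 1,
                                    pixel_size_um = 4.6, seed = 1L,
                                    n_planes = 8L, snr = 10,
                                    area_slope = 0.03, area_intercept = 0,
                                    center_offset_px = c(0, 0),
                                    canvas_px = NULL, blur_sigma = 2) {
  stopifnot(cells > 0, roundness_target > 0, roundness_target <= 1)
  set.seed(seed)
  area_um2 <- (cells - area_intercept) / area_slope
  area_px <- area_um2 / pixel_size_um^2
  r_eq <- sqrt(area_px / pi)
  q <- ellipse_axis_ratio_for_roundness(roundness_target)
  a <- r_eq * sqrt(q); b <- r_eq / sqrt(q)
  nside <- canvas_px %||% (2L * ceiling(a) + 41L)
  cx <- (nside + 1) / 2 + center_offset_px[1]
  cy <- (nside + 1) / 2 + center_offset_px[2]
  if (cx - a < 3 || cx + a > nside - 2 || cy - b < 3 || cy + b > nside - 2) {
    abort_sf("spheroid exceeds the image bounds", "sf_size_error")
  }
  ## x along columns (major axis), y along rows
  mask <- outer(seq_len(nside), seq_len(nside), function(i, j) {
    ((j - cx) / a)^2 + ((i - cy) / b)^2 <= 1
  })
  base <- blur_gaussian(matrix(as.numeric(mask), nside, nside), blur_sigma)
  falloff <- exp(-0.5 * ((seq_len(n_planes) - (n_planes + 1) / 2) / (n_planes / 3))^2)
  planes <- lapply(falloff, function(f) {
    f * base + matrix(stats::rnorm(nside^2, 0, 1 / snr), nside, nside)
  })
  truth <- list(
    area_um2 = sum(mask) * pixel_size_um^2,
    roundness = circularity(pi * a * b, ellipse_perimeter(a, b)),
    centroid_um = c(x = (cx - 0.5) * pixel_size_um, y = (cy - 0.5) * pixel_size_um)
  )
  structure(list(stack = image_stack(planes, pixel_size_um), truth = truth),
            class = "spheroid_image_sim")
}
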
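## pipeline: config-driven end-to-end runs (simulate -> read -> QC ->
## calibrate -> extract -> phenotype) with a plain-text report bundle.
## Every output is CSV/YAML/Newick/text so runs are byte-reproducible
## from (config, seed).

#' Build a pipeline run configuration
#'
#' @param rates,layout paths to the rate-table and layout CSVs.
#' @param schedule path to the schedule YAML (`NULL` = default
#'   16-measurement Mito Stress schedule).
#' @param areas optional per-well area CSV (`well,area_um2`); required
#'   for per-cell or per-area normalization.
#' @param calibration optional calibration CSV
#'   (`predictor_value,viable_cells,n_pooled,method`).
#' @param displacement optional CSV `well,displacement_um` from pre/post
#'   imaging.
#' @param out_dir output directory for the report bundle.
#' @param background_correction subtract background-well means first
#'   (off by default: instrument exports are usually pre-subtracted).
#' @param theta,delta_um QC thresholds (see [detect_rate_jumps()],
#'   [detect_displacement()]).
#' @param qc_policy "exclude" or "report-only".
#' @param normalization "per_1000_cells", "per_1000_um2" or "per_well".
#' @param size_class_edges 4 ascending cell-count bounds.
#' @param pca,clustering,map analysis toggles.
#' @param k flat cluster count.
#' @param seed recorded in the run log (the analysis itself is
#'   deterministic).
#' @return A `run_config` object.
#' @export
run_config <- function(rates, layout, schedule = NULL, areas = NULL,
                       calibration = NULL, displacement = NULL,
                       out_dir, background_correction = FALSE,
                       theta = 0.4, delta_um = 200,
                       qc_policy = c("exclude", "report-only"),
                       normalization = c("per_1000_cells", "per_1000_um2", "per_well"),
                       size_class_edges = c(7000, 10500, 15500, 22000),
                       pca = TRUE, clustering = TRUE, map = TRUE, k = 2L,
                       seed = 1L) {
  structure(list(rates = rates, layout = layout, schedule = schedule,
                 areas = areas, calibration = calibration,
                 displacement = displacement, out_dir = out_dir,
                 background_correction = background_correction,
                 theta = theta, delta_um = delta_um,
                 qc_policy = match.arg(qc_policy),
                 normalization = match.arg(normalization),
                 size_class_edges = size_class_edges,
                 pca = pca, clustering = clustering, map = map,
                 k = as.integer(k), seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline run configuration from YAML
#'
#' Relative paths are resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @param out_dir overrides the config's output directory if given.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) NULL
    else if (file.exists(p)) p
    else file.path(base, p)
  }
  p <- cfg$paths %||% list()
  run_config(
    rates = resolve(p$rates), layout = resolve(p$layout),
    schedule = resolve(p$schedule), areas = resolve(p$areas),
    calibration = resolve(p$calibration),
    displacement = resolve(p$displacement),
    out_dir = out_dir %||% cfg$out_dir %||% ".",
    background_correction = cfg$background_correction %||% FALSE,
    theta = cfg$qc$theta %||% 0.4,
    delta_um = cfg$qc$delta_um %||% 200,
    qc_policy = cfg$qc$policy %||% "exclude",
    normalization = cfg$normalization %||% "per_1000_cells",
    size_class_edges = unlist(cfg$size_class_edges) %||% c(7000, 10500, 15500, 22000),
    pca = cfg$analysis$pca %||% TRUE,
    clustering = cfg$analysis$clustering %||% TRUE,
    map = cfg$analysis$map %||% TRUE,
    k = cfg$analysis$k %||% 2L,
    seed = cfg$seed %||% 1L
  )
}

#' Validate a run configuration before any computation
#'
#' Fail-fast check that every referenced input path exists.
#'
#' @param cfg a [run_config()].
#' @return `cfg`, invisibly.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  for (f in c("rates", "layout", "schedule", "areas", "calibration",
              "displacement")) {
    p <- cfg[[f]]
    if (!is.null(p) && !file.exists(p)) {
      abort_sf(sprintf("config path '%s' does not exist: %s", f, p),
               "sf_validation_error")
    }
  }
  if (cfg$normalization != "per_well" && is.null(cfg$areas)) {
    abort_sf(sprintf("normalization '%s' needs an areas file", cfg$normalization),
             "sf_validation_error")
  }
  if (cfg$normalization == "per_1000_cells" && is.null(cfg$calibration)) {
    abort_sf("per-cell normalization needs a calibration file",
             "sf_validation_error")
  }
  invisible(cfg)
}

PARAM_COLS <- c("non_mito", "basal_resp", "atp_linked", "proton_leak",
                "maximal_resp", "spare_capacity", "spare_capacity_pct")

#' Run the full analysis pipeline
#'
#' flux IO -> background correction (optional) -> phase labelling -> QC
#' and exclusions -> calibration and size classes -> Mito Stress
#' parameter extraction and normalization -> phenotyping (CV tables,
#' PCA, UPGMA clustering, bioenergetic map). Writes the report bundle
#' under `cfg$out_dir` and returns the pieces invisibly. No well is
#' silently dropped: wells in = records + exclusions + background.
#'
#' @param cfg a validated [run_config()].
#' @return (invisibly) list with `records`, `params`, `qc`, `exclusions`,
#'   `curve`, `cv`, `pca`, `clusters`, `map`, `files`.
#' @export
run_pipeline <- function(cfg) {
  validate_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  stage <- "flux_io"
  incomplete_marker <- file.path(cfg$out_dir, "INCOMPLETE")
  file.create(incomplete_marker)
  on.exit({
    if (file.exists(incomplete_marker)) {
      writeLines(sprintf("pipeline aborted during stage: %s", stage),
                 incomplete_marker)
    }
  })

  pk <- read_rate_table(cfg$rates, cfg$layout)
  schedule <- if (is.null(cfg$schedule)) default_mito_schedule() else read_schedule(cfg$schedule)
  if (cfg$background_correction) pk <- apply_background_correction(pk)
  pk <- assign_phases(pk, schedule)
  wells_in <- setdiff(unique(pk$rates$well),
                      pk$layout$well[pk$layout$is_background])

  stage <- "qc"
  displacement <- if (!is.null(cfg$displacement)) {
    utils::read.csv(cfg$displacement, stringsAsFactors = FALSE)
  } else NULL
  qc <- qc_report(pk, displacement = displacement, theta = cfg$theta,
                  delta_um = cfg$delta_um)
  excl <- apply_exclusions(pk, qc, policy = cfg$qc_policy)
  pk <- excl$kinetics

  stage <- "calibration"
  curve <- NULL
  cells_df <- NULL
  if (!is.null(cfg$areas)) {
    areas <- utils::read.csv(cfg$areas, stringsAsFactors = FALSE)
    if (!all(c("well", "area_um2") %in% names(areas))) {
      abort_sf("areas CSV needs columns well, area_um2", "sf_format_error")
    }
    cells_df <- areas
    if (!is.null(cfg$calibration)) {
      cal <- utils::read.csv(cfg$calibration, stringsAsFactors = FALSE)
      pts <- calibration_points(cal$predictor_value, cal$viable_cells,
                                cal$n_pooled %||% 1L,
                                method = cal$method[1] %||% "area")
      curve <- fit_calibration(pts)
      est <- estimate_cells_from_area(curve, areas$area_um2)
      cells_df$cells_est <- est$cells_est
      cells_df$extrapolated_flag <- est$extrapolated_flag
      cells_df$size_class <- assign_size_class(est$cells_est,
                                               edges = cfg$size_class_edges)
    }
  }

  stage <- "mito_stress"
  params <- extract_params_plate(pk)
  if (is.null(params) || nrow(params) == 0) {
    abort_sf("no wells left for parameter extraction", "sf_pipeline_error")
  }
  raw_params <- params
  if (cfg$normalization != "per_well") {
    i <- match(params$well, cells_df$well)
    denom <- if (cfg$normalization == "per_1000_cells") {
      cells_df$cells_est[i] / 1000
    } else {
      cells_df$area_um2[i] / 1000
    }
    if (anyNA(denom)) {
      abort_sf(sprintf("missing area/cell estimate for well(s): %s",
                       paste(params$well[is.na(denom)], collapse = ", ")),
               "sf_pipeline_error")
    }
    for (f in RATE_FIELDS) params[[f]] <- params[[f]] / denom
    params$basis <- cfg$normalization
  }

  stage <- "phenotyping"
  grp <- pk$layout$group[match(params$well, pk$layout$well)]
  records <- data.frame(well = params$well, cell_line = grp,
                        stringsAsFactors = FALSE)
  if (!is.null(cells_df)) {
    i <- match(records$well, cells_df$well)
    records$area_um2 <- cells_df$area_um2[i]
    if (!is.null(cells_df$cells_est)) {
      records$cells_est <- cells_df$cells_est[i]
      records$size_class <- as.character(cells_df$size_class[i])
      records$extrapolated_flag <- cells_df$extrapolated_flag[i]
    }
  }
  if (is.null(records$size_class)) records$size_class <- "all"
  records <- cbind(records, params[match(records$well, params$well),
                                   c(PARAM_COLS, "last_basal_ocr",
                                     "last_basal_ecar", "stressed_ocr",
                                     "stressed_ecar", "basis", "quality_flag")])

  cv <- cv_summary(records, "cell_line",
                   c(PARAM_COLS, "last_basal_ocr", "last_basal_ecar"))

  pca_res <- NULL; cl_res <- NULL; map_res <- NULL; pm <- NULL
  pheno_cols <- PARAM_COLS[vapply(PARAM_COLS, function(p) {
    !anyNA(records[[p]])
  }, logical(1))]
  if ((cfg$pca || cfg$clustering) && nrow(records) >= 3) {
    m <- as.matrix(records[pheno_cols])
    rownames(m) <- records$well
    pm <- suppressWarnings(minmax_scale(m))
    if (cfg$pca) pca_res <- run_pca(pm, n_components = 2L)
    if (cfg$clustering) cl_res <- run_hclust(pm, k = min(cfg$k, nrow(m)))
  }
  if (cfg$map) map_res <- bioenergetic_map(records)

  stage <- "report"
  wfile <- function(name, df, signif = 6) {
    p <- file.path(cfg$out_dir, name)
    write_sf_csv(df, p, signif = signif)
    files <<- c(files, p)
    p
  }
  wfile("params.csv", params)
  wfile("records.csv", records)
  wfile("qc.csv", as.data.frame(qc))
  wfile("exclusions.csv", excl$exclusions)
  wfile("cv_summary.csv", cv)
  if (!is.null(pca_res)) {
    wfile("pca_scores.csv", data.frame(well = rownames(pca_res$scores),
                                       pca_res$scores))
    wfile("pca_loadings.csv", data.frame(parameter = rownames(pca_res$loadings),
                                         pca_res$loadings))
    wfile("pca_explained.csv",
          data.frame(component = seq_along(pca_res$explained_proportion),
                     proportion = pca_res$explained_proportion))
  }
  if (!is.null(cl_res)) {
    p <- file.path(cfg$out_dir, "dendrogram.nwk")
    write_dendrogram(cl_res, p)
    files <- c(files, p)
    wfile("cluster_labels.csv", data.frame(well = names(cl_res$labels),
                                           cluster = unname(cl_res$labels)))
  }
  if (!is.null(pm)) {
    wfile("scaled_matrix.csv", data.frame(well = rownames(pm$scaled), pm$scaled))
  }
  if (!is.null(map_res)) wfile("bioenergetic_map.csv", map_res)

  log_lines <- c(
    sprintf("spheroflux %s on R %s.%s", as.character(utils::packageVersion("spheroflux")),
            R.version$major, R.version$minor),
    sprintf("seed: %d", cfg$seed),
    sprintf("normalization: %s", cfg$normalization),
    sprintf("qc: theta=%.3g delta_um=%.3g policy=%s", cfg$theta, cfg$delta_um,
            cfg$qc_policy),
    sprintf("wells in: %d sample + %d background", length(wells_in),
            sum(pk$layout$is_background)),
    sprintf("excluded: %d (%s)", nrow(excl$exclusions),
            paste(excl$exclusions$well, collapse = " ")),
    sprintf("records out: %d", nrow(records)),
    if (!is.null(curve)) sprintf("calibration: slope=%.6g intercept=%.6g R2=%.4f",
                                 curve$slope, curve$intercept, curve$r_squared)
  )
  log_path <- file.path(cfg$out_dir, "run_log.txt")
  writeLines(log_lines, log_path)
  files <- c(files, log_path)

  if (nrow(records) + nrow(excl$exclusions) != length(wells_in) &&
      cfg$qc_policy == "exclude") {
    abort_sf("internal accounting error: wells in != records + exclusions",
             "sf_pipeline_error")
  }
  file.remove(incomplete_marker)
  invisible(list(records = records, params = params, raw_params = raw_params,
                 qc = qc, exclusions = excl$exclusions, curve = curve,
                 cv = cv, pca = pca_res, clusters = cl_res, map = map_res,
                 files = files))
}

#' Simulate a cohort and write it as a pipeline-ready dataset
#'
#' @param cfg a [cohort_config()] (or path to a YAML with its fields).
#' @param out_dir dataset directory.
#' @param profile a [cell_line_profile()].
#' @param quiet suppress the truth summary printout.
#' @return (invisibly) the [simulate_cohort()] result.
#' @export
simulate_dataset <- function(cfg, out_dir, profile = profile_aerobic(),
                             quiet = FALSE) {
  if (is.character(cfg)) {
    y <- yaml::read_yaml(cfg)
    y$schedule <- NULL
    y$seed <- y$seed %||% 1L
    cfg <- do.call(cohort_config, y)
  }
  sim <- simulate_cohort(cfg, profile)
  write_cohort(sim, out_dir)
  if (!quiet) {
    cat(sprintf("simulated %d wells (%s protocol, profile %s), %d background\n",
                cfg$n_wells, cfg$protocol, profile$name, cfg$n_background_wells))
    cat(sprintf("true cells: mean %.0f, CV %.1f%%; basal OCR CV %.1f%%\n",
                mean(sim$truth$true_cells), cv_percent(sim$truth$true_cells),
                cv_percent(sim$truth$basal_ocr)))
  }
  invisible(sim)
}

#' Command-line entry point
#'
#' Subcommands: `simulate -c cohort.yaml -o dir [--seed N]`,
#' `analyze -c run.yaml -o dir`, `report dir`. Returns 0 on success, 1
#' on validation errors, 2 on runtime errors (the installed
#' `spheroflux` launcher script exits with this status).
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status.
#' @export
spheroflux_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: spheroflux simulate -c cfg.yaml -o dir | analyze -c cfg.yaml -o dir | report dir"
  if (length(args) < 1) { message(usage); return(1L) }
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  handler <- function(expr) {
    tryCatch(expr,
             sf_validation_error = function(e) { message("validation error: ", conditionMessage(e)); 1L },
             sf_config_error = function(e) { message("validation error: ", conditionMessage(e)); 1L },
             error = function(e) { message("error: ", conditionMessage(e)); 2L })
  }
  switch(cmd,
    simulate = handler({
      cfg_path <- opt("-c"); out <- opt("-o")
      if (is.null(cfg_path) || is.null(out)) { message(usage); return(1L) }
      if (!file.exists(cfg_path)) {
        abort_sf(sprintf("config not found: %s", cfg_path), "sf_validation_error")
      }
      y <- yaml::read_yaml(cfg_path)
      seed_arg <- opt("--seed")
      if (!is.null(seed_arg)) y$seed <- as.integer(seed_arg)
      prof <- switch(y$profile %||% "aerobic",
                     aerobic = profile_aerobic(),
                     glycolytic = profile_glycolytic(),
                     abort_sf("unknown profile", "sf_validation_error"))
      y$profile <- NULL
      cfg <- do.call(cohort_config, y)
      simulate_dataset(cfg, out, profile = prof)
      0L
    }),
    analyze = handler({
      cfg_path <- opt("-c"); out <- opt("-o")
      if (is.null(cfg_path)) { message(usage); return(1L) }
      if (!file.exists(cfg_path)) {
        abort_sf(sprintf("config not found: %s", cfg_path), "sf_validation_error")
      }
      run_pipeline(read_run_config(cfg_path, out_dir = out))
      0L
    }),
    report = handler({
      dir <- args[2]
      if (is.na(dir) || !dir.exists(dir)) {
        abort_sf("report needs an existing run directory", "sf_validation_error")
      }
      log <- file.path(dir, "run_log.txt")
      if (file.exists(log)) writeLines(readLines(log))
      cat("files:", paste(sort(list.files(dir)), collapse = ", "), "\n")
      0L
    }),
    { message(usage); 1L }
  )
}
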
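test_that("noise-free limit collapses all wells onto one trajectory", {
  cfg <- cohort_config("single", n_wells = 5, cell_count_cv = 0,
                       measurement_noise_cv = 0, area_noise_cv = 0, seed = 1)
  sim <- simulate_cohort(cfg)
  pk <- assign_phases(sim$kinetics)
  p <- extract_params_plate(pk)
  expect_equal(cv_percent(c(p$last_basal_ocr, p$last_basal_ocr[1] * 1.0000001)),
               0, tolerance = 1e-4)
  expect_true(all(abs(p$last_basal_ocr - p$last_basal_ocr[1]) < 1e-9))
  ## doubling seeded cells doubles the basal rate (per-cell rates fixed)
  cfg2 <- cohort_config("single", n_wells = 5, seeded_cells = 20000,
                        cell_count_cv = 0, measurement_noise_cv = 0,
                        area_noise_cv = 0, seed = 1)
  p2 <- extract_params_plate(assign_phases(simulate_cohort(cfg2)$kinetics))
  expect_equal(p2$last_basal_ocr / p$last_basal_ocr, rep(2, 5),
               tolerance = 1e-9)
})

test_that("protocol regimes reproduce the homogeneity contrast", {
  ## sample CV of 45 wells fluctuates a few points around its target, so
  ## the regime check uses the median over a small seed panel
  cv_at <- function(protocol, seed) {
    cfg <- cohort_config(protocol, n_wells = 45, seed = seed)
    p <- extract_params_plate(assign_phases(simulate_cohort(cfg)$kinetics))
    cv_percent(p$last_basal_ocr)
  }
  cv_s <- vapply(1:5, function(s) cv_at("single", s), numeric(1))
  expect_gt(stats::median(cv_s), 10)
  expect_lt(max(cv_s), 20)
  cv_m <- vapply(1:5, function(s) cv_at("multiple", s), numeric(1))
  expect_gt(min(cv_m), 35)
})

test_that("simulation is bytewise deterministic in (config, seed)", {
  cfg <- cohort_config("single", n_wells = 8, seed = 123)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$kinetics$rates, s2$kinetics$rates)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_cohort(cohort_config("single", n_wells = 8, seed = 124))
  expect_false(identical(s1$kinetics$rates$ocr, s3$kinetics$rates$ocr))
  expect_error(cohort_config("single", n_wells = 8), class = "sf_config_error")
})

test_that("per-cell basal OCR is recovered from well rates and true cells", {
  cfg <- cohort_config("single", n_wells = 45, seed = 20)
  prof <- profile_aerobic()
  sim <- simulate_cohort(cfg, prof)
  p <- extract_params_plate(assign_phases(sim$kinetics))
  est <- p$last_basal_ocr /
    (sim$truth$true_cells[match(p$well, sim$truth$well)] / 1000)
  noise_sd <- prof$per_cell_basal_ocr * cfg$measurement_noise_cv / 100
  expect_lt(abs(mean(est) - prof$per_cell_basal_ocr), noise_sd)
})

test_that("synthetic images honor the roundness target and truth area", {
  im <- simulate_spheroid_image(12000, roundness_target = 1, seed = 5)
  expect_length(im$stack$planes, 8)
  res <- segment_spheroid(max_projection(im$stack), im$stack$pixel_size_um)
  expect_gte(res$roundness, 0.97)
  expect_lt(abs(res$area_um2 - im$truth$area_um2) / im$truth$area_um2, 0.03)
  expect_lt(centroid_displacement(res, list(centroid_um = im$truth$centroid_um)),
            2 * im$stack$pixel_size_um)

  ## irregular target: analytic truth roundness matches the request and
  ## segmentation tracks it
  im2 <- simulate_spheroid_image(12000, roundness_target = 0.6, seed = 5)
  expect_equal(im2$truth$roundness, 0.6, tolerance = 1e-6)
  res2 <- segment_spheroid(max_projection(im2$stack), im2$stack$pixel_size_um)
  expect_lt(abs(res2$roundness - 0.6), 0.05)

  ## determinism and size guard
  expect_identical(simulate_spheroid_image(9000, seed = 3)$stack$planes,
                   simulate_spheroid_image(9000, seed = 3)$stack$planes)
  expect_error(simulate_spheroid_image(12000, canvas_px = 50, seed = 1),
               class = "sf_size_error")
})

test_that("round vs irregular cohorts order their mean roundness", {
  seg_round <- function(targets, seed0) {
    vapply(seq_along(targets), function(i) {
      im <- simulate_spheroid_image(9000, roundness_target = targets[i],
                                    seed = seed0 + i, snr = 10)
      segment_spheroid(max_projection(im$stack), im$stack$pixel_size_um)$roundness
    }, numeric(1))
  }
  ssp_like <- seg_round(rep(c(0.80, 0.85, 0.9), 2), 100)   # U-bottom cohort
  msp_like <- seg_round(rep(c(0.45, 0.55, 0.65), 2), 200)  # flask cohort
  expect_gt(mean(ssp_like), mean(msp_like))
})

test_that("written cohorts feed the readers losslessly", {
  cfg <- cohort_config("single", n_wells = 6, seed = 9)
  sim <- simulate_cohort(cfg)
  d <- withr::local_tempdir()
  write_cohort(sim, d)
  expect_setequal(list.files(d),
                  c("rates.csv", "layout.csv", "schedule.yaml", "areas.csv",
                    "calibration.csv", "truth.csv"))
  pk <- read_rate_table(file.path(d, "rates.csv"), file.path(d, "layout.csv"))
  expect_equal(pk$rates$ocr, sim$kinetics$rates$ocr, tolerance = 1e-5)
  cal <- utils::read.csv(file.path(d, "calibration.csv"))
  expect_true(all(c("predictor_value", "viable_cells", "n_pooled", "method")
                  %in% names(cal)))
})
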
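test_that("rate jumps flag within-phase drops but never injections", {
  flat <- assign_phases(make_plate(list(A1 = rep(50, 16))))
  j <- detect_rate_jumps(flat)
  expect_false(j$rate_jump)

  ## basal 50, 50, 20: J = 0.6 at index 3, no injection there
  ocr <- c(50, 50, 20, rep(20, 13))
  j <- detect_rate_jumps(assign_phases(make_plate(list(A1 = ocr))))
  expect_true(j$rate_jump)
  expect_equal(j$jump_index, 3L)
  expect_equal(j$max_jump, 0.6)

  ## published-style decline across the oligomycin injection boundary is
  ## exempt: basal ends 47.54, oligomycin starts 41.01-like
  ocr <- c(54.24, 48.90, 47.54, 41.01, 40, 39.5, 39, 38.8,
           60, 61, 61.5, 62, 45, 41, 39.5, 39)
  j <- detect_rate_jumps(assign_phases(make_plate(list(A1 = ocr))))
  expect_false(j$rate_jump)

  unlabeled <- make_plate(list(A1 = rep(50, 16)))
  expect_error(detect_rate_jumps(unlabeled), class = "sf_state_error")
})

test_that("jump detection is scale invariant", {
  set.seed(5)
  base <- abs(rnorm(16, 50, 8))
  for (c_ in c(0.01, 1, 250)) {
    pk <- assign_phases(make_plate(list(A1 = base, A2 = base * c_)))
    j <- detect_rate_jumps(pk, epsilon = 1e-12)
    expect_equal(j$rate_jump[1], j$rate_jump[2])
    expect_equal(j$max_jump[1], j$max_jump[2], tolerance = 1e-9)
  }
})

test_that("displacement thresholding and missing-post handling", {
  near <- list(centroid_um = c(x = 0, y = 0))
  far <- list(centroid_um = c(x = 300, y = 400))
  expect_false(detect_displacement(near, near)$displaced)
  r <- detect_displacement(near, far)  # 500 um > 200 um default
  expect_true(r$displaced)
  expect_equal(r$displacement_um, 500)
  miss <- detect_displacement(near, NULL)
  expect_true(miss$incomplete)
  expect_false(miss$displaced)
})

test_that("displacement screening finds injected movers at 2x threshold", {
  set.seed(21)
  n <- 30
  moved <- sort(sample(n, 6))
  disp <- ifelse(seq_len(n) %in% moved, 400, abs(rnorm(n, 30, 20)))
  pk <- assign_phases(make_plate(stats::setNames(
    replicate(n, rep(50, 16), simplify = FALSE), paste0("A", seq_len(n)))))
  rep_ <- qc_report(pk, displacement = data.frame(
    well = paste0("A", seq_len(n)), displacement_um = disp))
  expect_equal(which(rep_$displaced[match(paste0("A", seq_len(n)), rep_$well)]),
               moved)
})

test_that("exclusions drop flagged wells, keep accounting, honor policy", {
  wells <- stats::setNames(replicate(20, rep(50, 16), simplify = FALSE),
                           paste0("A", 1:20))
  wells$A3[10:16] <- wells$A3[10:16] * 0.3   # artifact inside fccp phase
  wells$A7[6:16] <- wells$A7[6:16] * 0.4
  wells$A11 <- NULL
  wells$A11 <- rep(50, 16)                   # keep 20 wells total
  pk <- assign_phases(make_plate(wells))
  pk$rates <- pk$rates[!(pk$rates$well == "A11" & pk$rates$measurement == 5), ]
  rep_ <- qc_report(pk)
  ex <- apply_exclusions(pk, rep_)
  expect_equal(sort(ex$exclusions$well), c("A11", "A3", "A7"))
  expect_length(unique(ex$kinetics$rates$well), 17)
  expect_match(ex$exclusions$flags[ex$exclusions$well == "A11"], "incomplete")

  ## report-only: nothing removed, flags retained
  ro <- apply_exclusions(pk, rep_, policy = "report-only")
  expect_length(unique(ro$kinetics$rates$well), 20)
  expect_equal(nrow(ro$exclusions), 0)
  expect_equal(nrow(ro$flagged), 3)

  ## no flags anywhere: identity
  clean <- assign_phases(make_plate(list(A1 = rep(50, 16), A2 = rep(40, 16))))
  exc <- apply_exclusions(clean, qc_report(clean))
  expect_equal(exc$kinetics$rates, clean$rates)

  ## all sample wells excluded -> pipeline error
  allbad <- assign_phases(make_plate(list(A1 = c(50, 5, rep(5, 14)))))
  expect_error(apply_exclusions(allbad, qc_report(allbad)),
               class = "sf_pipeline_error")
})

test_that("background wells are never excluded by rate jumps", {
  pk <- assign_phases(make_plate(list(A1 = rep(50, 16),
                                      H12 = rnorm(16, 0, 0.5)),
                                 bg_wells = "H12"))
  rep_ <- qc_report(pk)
  expect_false(rep_$rate_jump[rep_$well == "H12"])
  expect_false(rep_$excluded[rep_$well == "H12"])
})

test_that("excluding artifact wells lowers the cohort's basal-OCR CV", {
  n_art <- 9  # 20% of 45 wells carry movement artifacts
  arts <- lapply(seq_len(n_art), function(i) {
    list(well = spheroflux:::plate_well_ids()[i * 5], index = c(2, 6, 10, 14)[i %% 4 + 1],
         magnitude = 0.6)
  })
  cfg <- cohort_config("multiple", n_wells = 45, artifact_wells = arts, seed = 8)
  pk <- assign_phases(simulate_cohort(cfg)$kinetics)
  before <- extract_params_plate(pk)
  ex <- apply_exclusions(pk, qc_report(pk))
  after <- extract_params_plate(ex$kinetics)
  expect_lt(cv_percent(after$last_basal_ocr), cv_percent(before$last_basal_ocr))
})
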
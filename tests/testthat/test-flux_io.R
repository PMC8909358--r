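test_that("rate tables round-trip and parse independently of row order", {
  cfg <- cohort_config("single", n_wells = 92, n_background_wells = 4, seed = 11)
  d <- write_temp_cohort(cfg)
  pk <- read_rate_table(file.path(d, "rates.csv"), file.path(d, "layout.csv"))
  expect_s3_class(pk, "plate_kinetics")
  expect_length(unique(pk$rates$well), 96)
  expect_length(unique(pk$rates$measurement), 16)
  expect_false(pk$background_corrected)
  expect_true(all(is.na(pk$rates$phase)))

  ## round trip is lossless at the declared 6-significant-digit precision
  f2 <- tempfile(fileext = ".csv")
  write_rate_table(pk, f2)
  pk2 <- read_rate_table(f2, file.path(d, "layout.csv"))
  expect_equal(pk2$rates$ocr, pk$rates$ocr, tolerance = 1e-5)

  ## shuffled rows parse to the identical object
  raw <- utils::read.csv(file.path(d, "rates.csv"))
  set.seed(1)
  shuf <- tempfile(fileext = ".csv")
  utils::write.csv(raw[sample(nrow(raw)), ], shuf, row.names = FALSE)
  expect_equal(read_rate_table(shuf, file.path(d, "layout.csv")), pk)
})

test_that("format, layout and duplicate errors are specific", {
  cfg <- cohort_config("single", n_wells = 4, seed = 2)
  d <- write_temp_cohort(cfg)
  raw <- utils::read.csv(file.path(d, "rates.csv"))

  bad <- tempfile(fileext = ".csv")
  names(raw)[names(raw) == "OCR"] <- "O2"
  utils::write.csv(raw, bad, row.names = FALSE)
  expect_error(read_rate_table(bad, file.path(d, "layout.csv")),
               class = "sf_format_error")
  expect_error(read_rate_table(bad, file.path(d, "layout.csv")), "OCR")

  names(raw)[names(raw) == "O2"] <- "OCR"
  raw$well[1] <- "Z99"
  utils::write.csv(raw, bad, row.names = FALSE)
  expect_error(read_rate_table(bad, file.path(d, "layout.csv")),
               class = "sf_layout_error")

  raw$well[1] <- raw$well[2]  # now duplicates (well, measurement) of row 2?
  raw[1, ] <- raw[2, ]
  utils::write.csv(raw, bad, row.names = FALSE)
  expect_error(read_rate_table(bad, file.path(d, "layout.csv")),
               class = "sf_duplicate_error")
})

test_that("background correction zeroes background means and keeps differences", {
  pk <- make_plate(list(A1 = c(10, 12), A2 = c(7, 9),
                        B1 = c(2, 1), B2 = c(2, 3)),
                   bg_wells = c("B1", "B2"))
  cor <- apply_background_correction(pk)
  expect_equal(well_kinetics(cor, "A1")$ocr, c(10 - 2, 12 - 2))
  ## background wells average to zero at every index
  bg <- cor$rates[cor$rates$well %in% c("B1", "B2"), ]
  expect_equal(as.vector(tapply(bg$ocr, bg$measurement, mean)), c(0, 0))
  ## between-well differences invariant under the common subtraction
  expect_equal(well_kinetics(cor, "A1")$ocr - well_kinetics(cor, "A2")$ocr,
               c(3, 3))
  ## state and configuration errors
  expect_error(apply_background_correction(cor), class = "sf_state_error")
  no_bg <- make_plate(list(A1 = c(1, 2)))
  expect_error(apply_background_correction(no_bg), class = "sf_config_error")
})

test_that("background correction survives a write/read round trip", {
  cfg <- cohort_config("single", n_wells = 6, seed = 5)
  d <- write_temp_cohort(cfg)
  pk <- read_rate_table(file.path(d, "rates.csv"), file.path(d, "layout.csv"))
  cor <- apply_background_correction(pk)
  f <- tempfile(fileext = ".csv")
  write_rate_table(cor, f)
  back <- read_rate_table(f, file.path(d, "layout.csv"))
  expect_equal(back$rates$ocr, cor$rates$ocr, tolerance = 1e-5)
  expect_equal(back$rates$ecar, cor$rates$ecar, tolerance = 1e-5)
})

test_that("phase assignment labels per the schedule and never touches rates", {
  pk <- make_plate(list(A1 = rnorm(16, 50), B1 = rnorm(16, 0)),
                   bg_wells = "B1")
  lab <- assign_phases(pk, default_mito_schedule())
  counts <- table(well_kinetics(lab, "A1")$phase)
  expect_equal(counts[["basal"]], 3)
  expect_equal(counts[["oligomycin"]], 5)
  expect_equal(counts[["fccp"]], 4)
  expect_equal(counts[["rot_aa"]], 4)
  expect_equal(lab$rates$ocr, pk$rates$ocr)
  ## idempotent
  expect_equal(assign_phases(lab, default_mito_schedule()), lab)

  short <- injection_schedule(data.frame(
    name = c("basal", "oligomycin", "fccp", "rot_aa"),
    first = c(1, 4, 9, 13), last = c(3, 8, 12, 15)))
  expect_error(assign_phases(pk, short), class = "sf_schedule_error")

  basal_only <- injection_schedule(data.frame(name = "basal", first = 1, last = 16))
  all_basal <- assign_phases(pk, basal_only)
  expect_true(all(all_basal$rates$phase == "basal"))
})

test_that("injection_schedule validates ordering and contiguity", {
  expect_error(injection_schedule(data.frame(name = c("oligomycin", "basal"),
                                             first = c(1, 4), last = c(3, 8))),
               class = "sf_schedule_error")
  expect_error(injection_schedule(data.frame(name = c("basal", "fccp"),
                                             first = c(1, 5), last = c(3, 8))),
               class = "sf_schedule_error")
  expect_error(injection_schedule(data.frame(name = "basal", first = 2, last = 5)),
               class = "sf_schedule_error")
  ## schedule YAML round trip
  s <- default_mito_schedule()
  f <- tempfile(fileext = ".yaml")
  write_schedule(s, f)
  expect_equal(read_schedule(f)$phases, s$phases)
})

test_that("wells with missing cycles are reported incomplete", {
  pk <- make_plate(list(A1 = rnorm(16, 50), A2 = rnorm(16, 50)))
  pk$rates <- pk$rates[!(pk$rates$well == "A2" & pk$rates$measurement == 7), ]
  expect_equal(incomplete_wells(pk), "A2")
})
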
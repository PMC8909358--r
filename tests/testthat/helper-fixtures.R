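## shared fixtures: exact-moment samples, published summary tables,
## in-memory plates, rasterized shapes, and the brute-force UPGMA oracle

## a deterministic sample with exact mean and exact (n-1) SD
sample_with_moments <- function(n, mean, sd) {
  z <- seq_len(n)
  mean + sd * (z - base::mean(z)) / stats::sd(z)
}

## printed OCR means of the 16 Mito Stress measurements (10k cells/well),
## single-spheroid and multiple-spheroids protocols
TABLE3_SSP <- c(54.24, 48.90, 47.54, 47.97, 46.21, 44.16, 42.54, 41.01,
                73.77, 75.22, 76.33, 77.31, 60.53, 38.72, 28.34, 22.11)
TABLE3_MSP <- c(26.99, 24.64, 24.85, 21.15, 16.79, 14.75, 13.91, 13.82,
                39.51, 35.34, 32.58, 30.55, 17.33, 12.78, 11.97, 11.47)

## printed (mean, sd, cv) rows used by the CV reproduction criterion
PRINTED_CVS <- data.frame(
  mean = c(95997.4, 421135.9, 156971.5, 415612.7, 137404.0, 267606.1,
           333372.0, 483380.8,
           26.20, 45.76, 18.33, 19.26, 13.53,
           26.99, 54.24, 30.55, 77.31, 11.47, 22.11),
  sd = c(48223.0, 36417.5, 94030.3, 73802.6, 54377.4, 34643.6,
         226341.7, 18691.7,
         10.99, 6.68, 4.58, 5.74, 3.19,
         12.56, 9.25, 14.48, 10.28, 6.35, 7.55),
  cv = c(50.2, 8.6, 59.9, 17.8, 39.6, 12.9, 67.9, 3.9,
         41.9, 14.6, 25.0, 29.8, 23.6,
         46.5, 17.1, 47.4, 13.3, 55.4, 34.1)
)

## one-well kinetics data.frame with phases from the default schedule
make_wk <- function(ocr, ecar = rep(1, length(ocr)), well = "A1",
                    schedule = default_mito_schedule()) {
  df <- data.frame(well = well, measurement = seq_along(ocr),
                   time_min = seq_along(ocr) * 6.5, ocr = ocr, ecar = ecar,
                   phase = NA_character_)
  df$phase <- spheroflux:::phase_of_index(schedule, df$measurement)
  df
}

## small in-memory plate from per-well OCR series (list well -> numeric)
make_plate <- function(ocr_by_well, bg_wells = character(),
                       ecar_by_well = NULL) {
  rows <- lapply(names(ocr_by_well), function(w) {
    ocr <- ocr_by_well[[w]]
    ecar <- if (!is.null(ecar_by_well)) ecar_by_well[[w]] else rep(1, length(ocr))
    data.frame(well = w, measurement = seq_along(ocr),
               time_min = seq_along(ocr) * 6.5, ocr = ocr, ecar = ecar,
               phase = NA_character_)
  })
  layout <- data.frame(well = names(ocr_by_well),
                       group = ifelse(names(ocr_by_well) %in% bg_wells,
                                      "background", "sample"),
                       is_background = names(ocr_by_well) %in% bg_wells)
  spheroflux:::new_plate_kinetics(do.call(rbind, rows), layout)
}

disk_mask <- function(r, n = 2 * r + 21, cx = (n + 1) / 2, cy = cx) {
  outer(seq_len(n), seq_len(n), function(i, j) (i - cy)^2 + (j - cx)^2 <= r^2)
}

## brute-force O(n^3) unweighted average-linkage: returns the cophenetic
## distance matrix (merge heights propagated to all cross pairs)
upgma_oracle_cophenetic <- function(dm) {
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    bestd <- Inf; bi <- NA; bj <- NA
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        dv <- mean(dm[clusters[[i]], clusters[[j]]])
        if (dv < bestd) { bestd <- dv; bi <- i; bj <- j }
      }
    }
    a <- clusters[[bi]]; b <- clusters[[bj]]
    coph[a, b] <- bestd; coph[b, a] <- bestd
    clusters[[bi]] <- c(a, b)
    clusters[[bj]] <- NULL
  }
  coph
}

## majority-label purity of a flat clustering
cluster_purity <- function(labels, truth) {
  sum(vapply(split(truth, labels), function(g) max(table(g)), numeric(1))) /
    length(truth)
}

## write a cohort to a temp dir, return the dir
write_temp_cohort <- function(cfg, profile = profile_aerobic()) {
  d <- withr::local_tempdir(.local_envir = parent.frame())
  write_cohort(simulate_cohort(cfg, profile), d)
  d
}
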
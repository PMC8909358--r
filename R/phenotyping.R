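## phenotyping: reproducibility statistics (CV), min-max scaling, PCA,
## average-linkage clustering, group comparisons and bioenergetic maps.

#' Coefficient of variation (%)
#'
#' `100 * sd(x) / mean(x)` with the sample (n - 1) standard deviation —
#' this convention reproduces published CV tables from their printed
#' means and SDs.
#'
#' @param x numeric vector, length >= 2, non-zero mean.
#' @return CV in percent.
#' @export
cv_percent <- function(x) {
  if (length(x) < 2) abort_sf("CV needs at least 2 values", "sf_input_error")
  m <- mean(x)
  if (m == 0) abort_sf("CV undefined for zero mean", "sf_undefined_error")
  100 * stats::sd(x) / m
}

#' CV from summary moments
#' @param mean,sd sample mean and (n - 1) SD.
#' @return CV in percent.
#' @export
cv_from_moments <- function(mean, sd) {
  if (any(mean == 0)) abort_sf("CV undefined for zero mean", "sf_undefined_error")
  100 * sd / mean
}

#' Min-max scale a phenotype matrix to [0, 1] per column
#'
#' Constant columns map to all-zero with a warning (a range of zero has
#' no information to scale). The per-column bounds are retained so the
#' transform is invertible for non-constant columns.
#'
#' @param m numeric matrix or data.frame, >= 2 rows (spheroids x
#'   parameters).
#' @return A `phenotype_matrix`: list with `scaled` (matrix in `[0, 1]`)
#'   and `bounds` (2 x p matrix of per-column min/max).
#' @export
minmax_scale <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) abort_sf("min-max scaling needs >= 2 rows", "sf_input_error")
  lo <- apply(m, 2, min)
  hi <- apply(m, 2, max)
  const <- hi == lo
  if (any(const)) {
    warn_sf(sprintf("constant column(s) mapped to 0: %s",
                    paste(colnames(m)[const] %||% which(const), collapse = ", ")),
            "sf_constant_column_warning")
  }
  rng <- ifelse(const, 1, hi - lo)
  scaled <- sweep(sweep(m, 2, lo, "-"), 2, rng, "/")
  scaled[, const] <- 0
  structure(list(scaled = scaled, bounds = rbind(min = lo, max = hi)),
            class = "phenotype_matrix")
}

#' Invert a min-max scaling
#' @param pm a [minmax_scale()] result.
#' @return matrix on the original scale (constant columns restored to
#'   their constant value).
#' @export
minmax_inverse <- function(pm) {
  stopifnot(inherits(pm, "phenotype_matrix"))
  lo <- pm$bounds["min", ]
  hi <- pm$bounds["max", ]
  sweep(sweep(pm$scaled, 2, hi - lo, "*"), 2, lo, "+")
}

#' Principal component analysis of a scaled phenotype matrix
#'
#' Covariance-based PCA (column centering, no re-standardization: the
#' min-max scaling has already equalized parameter ranges; set
#' `correlation = TRUE` to double-standardize). Loadings carry a
#' deterministic sign convention — the largest-magnitude loading of each
#' component is positive — so repeated runs are bit-identical.
#'
#' @param pm a [minmax_scale()] result (or a plain numeric matrix).
#' @param n_components how many components to retain in `scores` /
#'   `loadings` (explained proportions always cover all components).
#' @param correlation use correlation instead of covariance PCA.
#' @return A `pca_result`: list with `scores`, `loadings`,
#'   `explained_proportion`.
#' @export
run_pca <- function(pm, n_components = 2L, correlation = FALSE) {
  x <- if (inherits(pm, "phenotype_matrix")) pm$scaled else as.matrix(pm)
  if (all(apply(x, 2, stats::var) == 0)) {
    abort_sf("zero total variance: PCA is degenerate", "sf_degenerate_error")
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = correlation)
  prop <- fit$sdev^2 / sum(fit$sdev^2)
  ## sign convention: largest-|loading| entry positive per component
  for (j in seq_len(ncol(fit$rotation))) {
    i <- which.max(abs(fit$rotation[, j]))
    if (fit$rotation[i, j] < 0) {
      fit$rotation[, j] <- -fit$rotation[, j]
      fit$x[, j] <- -fit$x[, j]
    }
  }
  k <- min(n_components, ncol(fit$x))
  structure(
    list(scores = fit$x[, seq_len(k), drop = FALSE],
         loadings = fit$rotation[, seq_len(k), drop = FALSE],
         explained_proportion = prop,
         all_scores = fit$x),
    class = "pca_result"
  )
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerative clustering on Euclidean distances with unweighted
#' average linkage: the distance between two clusters is the mean
#' pairwise distance between their members. Flat labels are obtained by
#' cutting the tree at `k` clusters.
#'
#' @param pm a [minmax_scale()] result or numeric matrix (>= 2 rows).
#' @param k number of flat clusters (`2 <= k <= n`); `NULL` for tree only.
#' @return A `cluster_result`: list with `hclust` (merge tree), `labels`
#'   (flat assignment or NULL), `k`, `metric`, `linkage`.
#' @export
run_hclust <- function(pm, k = 2L) {
  x <- if (inherits(pm, "phenotype_matrix")) pm$scaled else as.matrix(pm)
  if (nrow(x) < 2) abort_sf("clustering needs >= 2 rows", "sf_input_error")
  if (!is.null(k) && k > nrow(x)) {
    abort_sf("k cannot exceed the number of rows", "sf_input_error")
  }
  d <- stats::dist(x, method = "euclidean")
  hc <- stats::hclust(d, method = "average")
  structure(
    list(hclust = hc,
         labels = if (!is.null(k)) stats::cutree(hc, k = k) else NULL,
         k = k, metric = "euclidean", linkage = "average"),
    class = "cluster_result"
  )
}

#' Write a cluster dendrogram as Newick
#' @param cl a [run_hclust()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(cl, path) {
  stopifnot(inherits(cl, "cluster_result"))
  ape::write.tree(ape::as.phylo(cl$hclust), file = path)
  invisible(path)
}

#' Two-sided unpaired t-test between two groups
#'
#' Welch's unequal-variance form by default (`var_equal = TRUE` for
#' Student's). When both groups are constant and equal the comparison is
#' vacuous and p = 1 is returned.
#'
#' @param a,b numeric vectors, each n >= 2.
#' @param var_equal assume equal variances.
#' @return list with `t`, `p_value`, `stars` ("" / "*" / "**" / "***"
#'   at 0.05 / 0.01 / 0.001).
#' @export
compare_groups <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2 || length(b) < 2) {
    abort_sf("each group needs n >= 2", "sf_input_error")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, p_value = 1, stars = ""))
    }
    abort_sf("both groups constant with different means: t undefined",
             "sf_degenerate_error")
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  p <- tt$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  list(t = unname(tt$statistic), p_value = p, stars = stars)
}

#' Per-group CV summary table
#'
#' One row per (group, parameter): n, mean, SD, CV% — the layout of
#' published reproducibility tables.
#'
#' @param df data.frame of per-well records.
#' @param group_col grouping column name.
#' @param param_cols numeric columns to summarize.
#' @return data.frame `group, parameter, n, mean, sd, cv_pct`.
#' @export
cv_summary <- function(df, group_col, param_cols) {
  rows <- list()
  for (g in unique(df[[group_col]])) {
    sub <- df[df[[group_col]] == g, , drop = FALSE]
    for (p in param_cols) {
      v <- sub[[p]]
      v <- v[!is.na(v)]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, parameter = p, n = length(v),
        mean = if (length(v) > 0) mean(v) else NA_real_,
        sd = if (length(v) > 1) stats::sd(v) else NA_real_,
        cv_pct = if (length(v) > 1 && mean(v) != 0) cv_percent(v) else NA_real_
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bioenergetic map: mean OCR vs ECAR under basal and stressed conditions
#'
#' For each (cell line x size class) group, the basal point is the mean
#' of the per-cell last-basal ECAR/OCR pair and the stressed point the
#' mean of the post-FCCP pair (at the FCCP measurement where OCR peaks).
#' Plotting stressed against basal points summarizes metabolic
#' plasticity: aerobic systems move up (OCR), glycolytic ones right
#' (ECAR).
#'
#' @param records data.frame with columns `cell_line`, `size_class`,
#'   `last_basal_ocr`, `last_basal_ecar`, `stressed_ocr`, `stressed_ecar`
#'   (normalized basis expected).
#' @return data.frame, one row per non-empty group:
#'   `cell_line, size_class, n, basal_ecar_mean, basal_ecar_sd,
#'   basal_ocr_mean, basal_ocr_sd, stressed_ecar_mean, stressed_ecar_sd,
#'   stressed_ocr_mean, stressed_ocr_sd`.
#' @export
bioenergetic_map <- function(records) {
  need <- c("cell_line", "size_class", "last_basal_ocr", "last_basal_ecar",
            "stressed_ocr", "stressed_ecar")
  stopifnot(all(need %in% names(records)))
  key <- interaction(records$cell_line, records$size_class, drop = TRUE)
  rows <- lapply(levels(key), function(kv) {
    sub <- records[key == kv, , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    sdv <- function(x) if (length(x) > 1) stats::sd(x) else NA_real_
    data.frame(cell_line = sub$cell_line[1],
               size_class = as.character(sub$size_class[1]),
               n = nrow(sub),
               basal_ecar_mean = mean(sub$last_basal_ecar),
               basal_ecar_sd = sdv(sub$last_basal_ecar),
               basal_ocr_mean = mean(sub$last_basal_ocr),
               basal_ocr_sd = sdv(sub$last_basal_ocr),
               stressed_ecar_mean = mean(sub$stressed_ecar),
               stressed_ecar_sd = sdv(sub$stressed_ecar),
               stressed_ocr_mean = mean(sub$stressed_ocr),
               stressed_ocr_sd = sdv(sub$stressed_ocr))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot a bioenergetic map (base graphics)
#'
#' Basal points are drawn open, stressed points filled, joined by arrows.
#' Intended for interactive use on an open device; the pipeline itself
#' only writes the underlying table.
#'
#' @param map a [bioenergetic_map()] table.
#' @param ... passed to [graphics::plot()].
#' @return `map`, invisibly.
#' @export
plot_bioenergetic_map <- function(map, ...) {
  xr <- range(c(map$basal_ecar_mean, map$stressed_ecar_mean))
  yr <- range(c(map$basal_ocr_mean, map$stressed_ocr_mean))
  graphics::plot(NA, xlim = xr, ylim = yr, xlab = "ECAR (mpH/min/1000 cells)",
                 ylab = "OCR (pmol/min/1000 cells)", ...)
  cols <- seq_len(nrow(map))
  graphics::points(map$basal_ecar_mean, map$basal_ocr_mean, pch = 1, col = cols)
  graphics::points(map$stressed_ecar_mean, map$stressed_ocr_mean, pch = 16, col = cols)
  graphics::arrows(map$basal_ecar_mean, map$basal_ocr_mean,
                   map$stressed_ecar_mean, map$stressed_ocr_mean,
                   length = 0.08, col = cols)
  graphics::legend("topleft", legend = paste(map$cell_line, map$size_class),
                   col = cols, pch = 16, bty = "n", cex = 0.8)
  invisible(map)
}
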
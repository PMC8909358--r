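## morphometry: maximum projection, Otsu segmentation, circularity and
## centroid displacement for single-spheroid fluorescence stacks.
##
## Images are plain numeric matrices (row = y downward, column = x
## rightward, origin at the image corner, coordinates at pixel centers).
## Areas are pixel counts times the pixel area.

#' Construct an image stack
#'
#' @param planes list of numeric matrices, all the same shape (>= 1).
#' @param pixel_size_um pixel edge length in µm (> 0).
#' @param channel one of "tracker_fluorescence", "nuclei", "brightfield".
#' @return An `image_stack` object.
#' @export
image_stack <- function(planes, pixel_size_um,
                        channel = c("tracker_fluorescence", "nuclei", "brightfield")) {
  channel <- match.arg(channel)
  if (!is.list(planes) || length(planes) < 1) {
    abort_sf("an image stack needs at least one plane", "sf_input_error")
  }
  dims <- lapply(planes, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    abort_sf("all planes must share the same shape", "sf_input_error")
  }
  if (!is_scalar_number(pixel_size_um) || pixel_size_um <= 0) {
    abort_sf("pixel_size_um must be a positive number", "sf_input_error")
  }
  structure(list(planes = planes, pixel_size_um = pixel_size_um,
                 channel = channel),
            class = "image_stack")
}

#' Maximum projection of a z-stack
#'
#' `out[i, j] = max_p plane_p[i, j]`.
#'
#' @param stack an [image_stack()].
#' @return numeric matrix.
#' @export
max_projection <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  out <- stack$planes[[1]]
  for (p in stack$planes[-1]) out <- pmax(out, p)
  out
}

#' Otsu's global threshold
#'
#' Maximizes between-class variance over a 256-bin histogram of the
#' intensity range. Suited to high-contrast tracker fluorescence: one
#' bright object on a dark background.
#'
#' @param img numeric matrix.
#' @param n_bins histogram resolution.
#' @return scalar threshold on the intensity scale of `img`.
#' @export
otsu_threshold <- function(img, n_bins = 256L) {
  v <- as.vector(img)
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, breaks, all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  breaks[which.max(between) + 1L]
}

## 4-connected component labelling by iterative minimum-label propagation.
## Converges in O(diameter) sweeps, each vectorised over the image.
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  lab <- matrix(0, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(sum(mask))
  if (all(lab == 0)) return(lab)
  big <- sum(mask) + 1
  repeat {
    l <- lab
    l[l == 0] <- big
    up <- rbind(rep(big, ncol(l)), l[-nrow(l), , drop = FALSE])
    dn <- rbind(l[-1, , drop = FALSE], rep(big, ncol(l)))
    lf <- cbind(rep(big, nrow(l)), l[, -ncol(l), drop = FALSE])
    rt <- cbind(l[, -1, drop = FALSE], rep(big, nrow(l)))
    new <- pmin(l, up, dn, lf, rt)
    new[!mask] <- 0
    if (identical(new, lab)) break
    lab <- new
  }
  ## renumber 1..k by first appearance
  ids <- sort(unique(lab[lab > 0]))
  lab[lab > 0] <- match(lab[lab > 0], ids)
  lab
}

## fill interior holes: background connected to the border stays
## background, everything else becomes foreground
fill_holes <- function(mask) {
  bg <- !mask
  reach <- matrix(FALSE, nrow(mask), ncol(mask))
  reach[1, ] <- bg[1, ]; reach[nrow(mask), ] <- bg[nrow(mask), ]
  reach[, 1] <- bg[, 1]; reach[, ncol(mask)] <- bg[, ncol(mask)]
  repeat {
    up <- rbind(FALSE, reach[-nrow(reach), , drop = FALSE])
    dn <- rbind(reach[-1, , drop = FALSE], FALSE)
    lf <- cbind(FALSE, reach[, -ncol(reach), drop = FALSE])
    rt <- cbind(reach[, -1, drop = FALSE], FALSE)
    new <- bg & (reach | up | dn | lf | rt)
    if (identical(new, reach)) break
    reach <- new
  }
  mask | (bg & !reach)
}

## separable Gaussian blur with zero (dark-background) padding
gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

blur_gaussian <- function(img, sigma) {
  k <- gaussian_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  n <- nrow(img); m <- ncol(img)
  pad <- matrix(0, n + 2L * r, m)
  pad[(r + 1L):(r + n), ] <- img
  tmp <- matrix(0, n, m)
  for (i in seq_along(k)) tmp <- tmp + k[i] * pad[i:(i + n - 1L), , drop = FALSE]
  pad2 <- matrix(0, n, m + 2L * r)
  pad2[, (r + 1L):(r + m)] <- tmp
  out <- matrix(0, n, m)
  for (i in seq_along(k)) out <- out + k[i] * pad2[, i:(i + m - 1L), drop = FALSE]
  out
}

## Marching-squares contour length of the 0.5 level set. The binary mask
## is lightly Gaussian-smoothed first and the crossings are linearly
## interpolated (sub-pixel marching squares); this removes the ~6%
## staircase bias a midpoint polygon on raw binary data would carry.
## Ambiguous saddle cases are resolved by the cell-center value.
mask_perimeter <- function(mask, smooth_sigma = 1.5) {
  pad <- ceiling(3 * smooth_sigma) + 2L
  f <- matrix(0, nrow(mask) + 2L * pad, ncol(mask) + 2L * pad)
  f[(pad + 1L):(pad + nrow(mask)), (pad + 1L):(pad + ncol(mask))] <- as.numeric(mask)
  if (smooth_sigma > 0) f <- blur_gaussian(f, smooth_sigma)
  lev <- 0.5
  ins <- f > lev
  nr <- nrow(f); nc <- ncol(f)
  tl <- ins[-nr, -nc]; tr <- ins[-nr, -1]; br <- ins[-1, -1]; bl <- ins[-1, -nc]
  code <- tl + 2L * tr + 4L * br + 8L * bl
  cells <- which(code > 0L & code < 15L, arr.ind = TRUE)
  if (nrow(cells) == 0) return(0)
  ## edges: T = top, R = right, B = bottom, L = left; per case the contour
  ## joins one (or, in saddles, two) pair(s) of crossed edges
  seg_edges <- list(
    `1` = list(c("L", "T")), `2` = list(c("T", "R")), `3` = list(c("L", "R")),
    `4` = list(c("R", "B")), `5` = NULL, `6` = list(c("T", "B")),
    `7` = list(c("L", "B")), `8` = list(c("B", "L")), `9` = list(c("T", "B")),
    `10` = NULL, `11` = list(c("R", "B")), `12` = list(c("R", "L")),
    `13` = list(c("T", "R")), `14` = list(c("L", "T"))
  )
  cross <- function(v0, v1, p0, p1) p0 + (lev - v0) / (v1 - v0) * (p1 - p0)
  total <- 0
  for (k in seq_len(nrow(cells))) {
    i <- cells[k, 1]; j <- cells[k, 2]
    v <- c(tl = f[i, j], tr = f[i, j + 1], br = f[i + 1, j + 1], bl = f[i + 1, j])
    ## crossing coordinates (x = column axis, y = row axis)
    pts <- list(
      T = c(x = cross(v["tl"], v["tr"], j, j + 1), y = i),
      R = c(x = j + 1, y = cross(v["tr"], v["br"], i, i + 1)),
      B = c(x = cross(v["bl"], v["br"], j, j + 1), y = i + 1),
      L = c(x = j, y = cross(v["tl"], v["bl"], i, i + 1))
    )
    cs <- code[i, j]
    pairs <- if (cs == 5L || cs == 10L) {
      ## saddle: use the center mean to pick the separating diagonal
      if (mean(v) > lev) list(c("T", "R"), c("B", "L"))
      else list(c("L", "T"), c("R", "B"))
    } else {
      seg_edges[[as.character(cs)]]
    }
    for (pr in pairs) {
      a <- pts[[pr[1]]]; b <- pts[[pr[2]]]
      total <- total + sqrt(sum((a - b)^2))
    }
  }
  total
}

#' Circularity from area and perimeter
#'
#' `4 * pi * A / P^2`, clipped to `[0, 1]`; equals 1 for a perfect circle
#' and `pi / 4` for a square.
#'
#' @param area area (any consistent unit).
#' @param perimeter perimeter (same length unit).
#' @return circularity in `[0, 1]`.
#' @export
circularity <- function(area, perimeter) {
  pmin(1, pmax(0, 4 * pi * area / perimeter^2))
}

#' Roundness of a binary mask
#'
#' Circularity `4 * pi * A / P^2` with the perimeter taken from the
#' marching-squares contour of the mask. This is a deliberate proxy for
#' proprietary screen-software "roundness" metrics; it matches the ImageJ
#' circularity convention.
#'
#' @param mask logical matrix with one connected component.
#' @return roundness in `[0, 1]`.
#' @export
roundness <- function(mask) {
  if (!is.matrix(mask) || sum(mask) == 0) {
    abort_sf("roundness needs a non-empty mask", "sf_input_error")
  }
  circularity(sum(mask), mask_perimeter(mask))
}

mask_centroid_um <- function(mask, pixel_size_um) {
  idx <- which(mask, arr.ind = TRUE)
  ## pixel centers: x along columns, y along rows, origin at image corner
  c(x = (mean(idx[, "col"]) - 0.5) * pixel_size_um,
    y = (mean(idx[, "row"]) - 0.5) * pixel_size_um)
}

#' Segment a single spheroid from a 2-D image
#'
#' Global Otsu threshold, keep the largest connected component, fill
#' interior holes (spheroid cores may be dimmer than rims), then measure
#' area, roundness, and centroid. A component touching the image border
#' is flagged as possibly truncated but still measured.
#'
#' @param image numeric matrix (e.g. a [max_projection()]).
#' @param pixel_size_um pixel edge length in µm.
#' @param min_size_px smallest component accepted as a spheroid; pure
#'   noise above the threshold forms only scattered specks, so a largest
#'   component below this size raises the no-spheroid error.
#' @return A `morphometry_result`: list with `area_um2`, `roundness`,
#'   `centroid_um`, `mask_pixel_count`, `border_flag`, `mask`.
#' @export
segment_spheroid <- function(image, pixel_size_um, min_size_px = 100L) {
  stopifnot(is.matrix(image))
  if (!is_scalar_number(pixel_size_um) || pixel_size_um <= 0) {
    abort_sf("pixel_size_um must be a positive number", "sf_input_error")
  }
  thr <- otsu_threshold(image)
  fg <- image > thr
  if (sum(fg) == 0) {
    abort_sf("no foreground above the Otsu threshold (no spheroid found)",
             "sf_no_spheroid_error")
  }
  lab <- label_components(fg)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  if (sizes[keep] < min_size_px) {
    abort_sf(sprintf("largest foreground component (%d px) is below min_size_px (%d): no spheroid found",
                     sizes[keep], min_size_px), "sf_no_spheroid_error")
  }
  mask <- fill_holes(lab == keep)
  border <- any(mask[1, ]) || any(mask[nrow(mask), ]) ||
    any(mask[, 1]) || any(mask[, ncol(mask)])
  n_px <- sum(mask)
  structure(
    list(area_um2 = n_px * pixel_size_um^2,
         roundness = roundness(mask),
         centroid_um = mask_centroid_um(mask, pixel_size_um),
         mask_pixel_count = n_px,
         pixel_size_um = pixel_size_um,
         border_flag = border,
         mask = mask),
    class = "morphometry_result"
  )
}

#' Centroid displacement between two morphometry results
#'
#' Euclidean distance in µm between the pre- and post-assay centroids of
#' the same well, used to detect spheroids that moved during the assay's
#' mixing steps.
#'
#' @param pre,post `morphometry_result`s from the same well and pixel size.
#' @return displacement in µm.
#' @export
centroid_displacement <- function(pre, post) {
  sqrt(sum((pre$centroid_um - post$centroid_um)^2))
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat(sprintf("<morphometry_result> area %.0f um^2, roundness %.3f, centroid (%.1f, %.1f) um%s\n",
              x$area_um2, x$roundness, x$centroid_um["x"], x$centroid_um["y"],
              if (x$border_flag) " [border]" else ""))
  invisible(x)
}

#' Morphometry over a directory of per-well stacks to a CSV table
#'
#' @param results named list of `morphometry_result`s (names = well ids).
#' @param path output CSV
#'   (`well,area_um2,roundness,centroid_x_um,centroid_y_um,border_flag`).
#' @return `path`, invisibly.
#' @export
write_morphometry <- function(results, path) {
  df <- do.call(rbind, lapply(names(results), function(w) {
    r <- results[[w]]
    data.frame(well = w, area_um2 = r$area_um2, roundness = r$roundness,
               centroid_x_um = r$centroid_um["x"],
               centroid_y_um = r$centroid_um["y"],
               border_flag = r$border_flag)
  }))
  rownames(df) <- NULL
  write_sf_csv(df, path, signif = 6)
}
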
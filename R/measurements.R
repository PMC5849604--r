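#' Per-region cell measurements
#'
#' `count_in_roi()` counts cells of a marker whose containing heatmap pixel
#' carries the region label; `density_in_roi()` divides by the region area
#' and reports cells per mm^2 (an empty region yields `NA`, not zero).
#'
#' @param cells Data frame with `marker`, `x_um`, `y_um` (one patient).
#' @param roi_map A `roi_map` from [define_rois()].
#' @param marker Marker label.
#' @param location Measurement region label.
#' @return `count_in_roi()`: integer count; `density_in_roi()`: numeric
#'   density (cells/mm^2) or `NA` for an empty region.
#' @export
count_in_roi <- function(cells, roi_map, marker, location) {
  mask <- roi_pixels(roi_map, location)
  sub <- cells[normalize_marker(cells$marker) == normalize_marker(marker), ,
               drop = FALSE]
  if (nrow(sub) == 0) return(0L)
  idx <- cell_pixel_index(sub, roi_map)
  sum(mask[idx])
}

#' @rdname count_in_roi
#' @export
density_in_roi <- function(cells, roi_map, marker, location) {
  area <- roi_area_mm2(roi_map, location)
  if (area <= 0) return(NA_real_)
  count_in_roi(cells, roi_map, marker, location) / area
}

# linear pixel index of each cell's containing pixel (clamped to the grid)
cell_pixel_index <- function(cells, roi_map) {
  res <- roi_map$resolution
  ny <- roi_map$dim[1]; nx <- roi_map$dim[2]
  j <- pmin(nx, pmax(1L, floor(cells$x_um / res) + 1L))
  i <- pmin(ny, pmax(1L, floor(cells$y_um / res) + 1L))
  cbind(i, j)
}

#' Mean k-nearest-neighbour distance between cell populations
#'
#' For every cell of marker `marker_a` inside the region, the mean
#' Euclidean distance to its `k` nearest cells of `marker_b` is computed
#' (neighbours are searched slide-wide, since relevant partner cells --
#' e.g. vessels near border macrophages -- may lie outside the region);
#' the region average of these means is returned, in microns.
#'
#' @inheritParams count_in_roi
#' @param marker_a,marker_b Markers of the anchor and neighbour population.
#' @param k Number of neighbours (4 or 8).
#' @return Mean distance in microns; `NA` if the region holds no anchor
#'   cells or fewer than `k` neighbour cells exist on the slide.
#' @export
avg_knn_distance <- function(cells, roi_map, marker_a, marker_b, k = 4,
                             location = "ws") {
  a <- cells[normalize_marker(cells$marker) == normalize_marker(marker_a), ,
             drop = FALSE]
  b <- cells[normalize_marker(cells$marker) == normalize_marker(marker_b), ,
             drop = FALSE]
  if (nrow(a) > 0) {
    mask <- roi_pixels(roi_map, location)
    a <- a[mask[cell_pixel_index(a, roi_map)], , drop = FALSE]
  }
  if (nrow(a) == 0 || nrow(b) < k) return(NA_real_)
  mean(knn_mean_dists(a$x_um, a$y_um, b$x_um, b$y_um, k))
}

# per-anchor mean distance to k nearest neighbours; chunked brute force
knn_mean_dists <- function(ax, ay, bx, by, k, chunk = 512L) {
  nA <- length(ax)
  out <- numeric(nA)
  b2 <- bx^2 + by^2
  for (s in seq(1L, nA, by = chunk)) {
    e <- min(nA, s + chunk - 1L)
    d2 <- outer(ax[s:e]^2 + ay[s:e]^2, b2, `+`) -
      2 * (cbind(ax[s:e], ay[s:e]) %*% rbind(bx, by))
    d2[d2 < 0] <- 0
    out[s:e] <- apply(d2, 1, function(r) mean(sqrt(sort.int(r, partial = k)[1:k])))
  }
  out
}

#' Gland co-occurrence (Haralick) correlation
#'
#' Quantifies the joint spatial appearance of gland classes on the heatmap
#' grid. Pixels are classified by dominant gland coverage into gland-type
#' and/or area-tercile classes (plus a `none` class); a symmetric gray-level
#' co-occurrence matrix is accumulated over 8-neighbourhood pixel pairs and
#' the Haralick correlation statistic
#' \deqn{\sum_{ij} (i-\mu_i)(j-\mu_j) p(i,j) / (\sigma_i \sigma_j)}
#' is returned. A degenerate raster (single class) returns 0 with a
#' `degenerate` attribute.
#'
#' @param glands Gland polygon tibble (see [rasterize_objects()]).
#' @param resolution,extent Grid calibration (as in [rasterize_objects()]).
#' @param class_set `"intact_nonintact"` (gland type), `"intact_size"` or
#'   `"nonintact_size"` (area terciles of one type).
#' @param size_breaks Two area cut points (um^2) separating the terciles;
#'   required for the size class sets. Compute them cohort-wide with
#'   [gland_size_breaks()].
#' @return Haralick correlation in `[-1, 1]`.
#' @export
gland_cooccurrence_correlation <- function(glands, resolution = 100,
                                           extent = NULL,
                                           class_set = "intact_nonintact",
                                           size_breaks = NULL) {
  class_set <- match.arg(class_set,
                         c("intact_nonintact", "intact_size", "nonintact_size"))
  glands <- glands %||% tibble::tibble(gland_id = integer(),
                                       gland_class = character(),
                                       x_um = numeric(), y_um = numeric())
  if (class_set == "intact_nonintact") {
    classes <- c("intact", "nonIntact")
    classify <- function(g) g$gland_class
  } else {
    type <- if (class_set == "intact_size") "intact" else "nonIntact"
    if (is.null(size_breaks)) abort("size_breaks required for size class sets")
    glands <- glands[glands$gland_class == type, , drop = FALSE]
    classes <- paste0(type, c("_small", "_medium", "_large"))
    classify <- function(g) {
      areas <- vapply(split(g, g$gland_id),
                      function(p) polygon_area(p$x_um, p$y_um), numeric(1))
      bin <- 1L + findInterval(areas, size_breaks)
      setNames(classes[bin], names(areas))[as.character(g$gland_id)]
    }
  }
  if (nrow(glands) > 0) {
    glands$.cls <- classify(glands)
  } else {
    glands$.cls <- character(0)
  }
  # coverage per class via the gland rasterizer, then argmax per pixel
  cover <- lapply(classes, function(cl) {
    sub <- glands[glands$.cls == cl, , drop = FALSE]
    sub$gland_class <- "nonIntact"  # reuse one channel
    rasterize_objects(NULL, sub, resolution = resolution,
                      extent = extent)$channels$glandfrac_nonIntact
  })
  dims <- vapply(cover, function(m) length(m), numeric(1))
  nmax <- which.max(dims)
  dimref <- dim(cover[[nmax]])
  cover <- lapply(cover, function(m) {
    out <- matrix(0, dimref[1], dimref[2])
    out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    out
  })
  total <- Reduce(`+`, cover)
  lab <- matrix(1L, dimref[1], dimref[2])  # 1 = none
  if (length(classes) > 0 && any(total > 0)) {
    arg <- apply(simplify2array(cover), c(1, 2), which.max)
    lab[total > 0] <- arg[total > 0] + 1L
  }
  haralick_correlation(lab, n_levels = length(classes) + 1L)
}

# symmetric GLCM over the 8-neighbourhood and its Haralick correlation
haralick_correlation <- function(lab, n_levels = max(lab)) {
  ny <- nrow(lab); nx <- ncol(lab)
  P <- matrix(0, n_levels, n_levels)
  offs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  for (o in offs) {
    di <- o[1]; dj <- o[2]
    i1 <- seq_len(ny - abs(di)); j1 <- seq_len(nx - abs(dj))
    i2 <- i1 + abs(di)
    if (dj >= 0) { j1a <- j1; j2 <- j1 + dj } else { j1a <- j1 - dj; j2 <- j1 }
    a <- lab[i1, j1a, drop = FALSE]; b <- lab[i2, j2, drop = FALSE]
    idx <- (as.vector(b) - 1L) * n_levels + as.vector(a)
    tab <- tabulate(idx, nbins = n_levels^2)
    P <- P + matrix(tab, n_levels, n_levels)
  }
  P <- P + t(P)  # symmetric accumulation
  if (sum(P) == 0) return(structure(0, degenerate = TRUE))
  P <- P / sum(P)
  mu_i <- sum(seq_len(nrow(P)) * rowSums(P))
  mu_j <- sum(seq_len(ncol(P)) * colSums(P))
  s_i <- sqrt(sum((seq_len(nrow(P)) - mu_i)^2 * rowSums(P)))
  s_j <- sqrt(sum((seq_len(ncol(P)) - mu_j)^2 * colSums(P)))
  if (s_i == 0 || s_j == 0) return(structure(0, degenerate = TRUE))
  ii <- matrix(seq_len(nrow(P)), nrow(P), ncol(P))
  jj <- t(matrix(seq_len(ncol(P)), ncol(P), nrow(P)))
  sum((ii - mu_i) * (jj - mu_j) * P) / (s_i * s_j)
}

#' Cohort-wide gland-area tercile breaks
#'
#' @param glands Gland polygon tibble across all patients.
#' @return Two cut points (um^2) at the 1/3 and 2/3 quantiles of gland area.
#' @export
gland_size_breaks <- function(glands) {
  areas <- vapply(split(glands, interaction(glands$patient_id %||% 1,
                                            glands$gland_id, drop = TRUE)),
                  function(p) polygon_area(p$x_um, p$y_um), numeric(1))
  unname(quantile(areas, c(1 / 3, 2 / 3), names = FALSE))
}
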
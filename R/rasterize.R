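#' Rasterize object-level tissue into a micron-calibrated heatmap stack
#'
#' Aggregates marker-labelled cell positions and classified gland polygons
#' into a low-resolution multi-channel raster ("hyper-spectral heatmap"):
#' one count channel per marker plus an area-fraction channel per gland
#' class. The grid uses a top-left origin; pixel `(i, j)` covers the
#' half-open square `[(j-1) res, j res) x [(i-1) res, i res)` in microns
#' (x right, y down).
#'
#' @param cells Data frame with columns `marker`, `x_um`, `y_um` (one
#'   patient). May be empty (all-zero count channels).
#' @param glands Data frame of gland polygon vertices with columns
#'   `gland_id`, `gland_class` (`"intact"`/`"nonIntact"`), `x_um`, `y_um`,
#'   vertices ordered within gland. May be empty.
#' @param resolution Grid resolution in microns per pixel (default 100).
#' @param extent Slide extent `c(width_um, height_um)`; defaults to the
#'   tight bounding box of the input objects rounded up to whole pixels.
#' @param subsample Per-axis sub-sampling factor for gland area fractions:
#'   each pixel is probed at `subsample^2` points (default 4).
#' @return An object of class `heatmap_stack`: list with `resolution`,
#'   `extent`, `dim` (rows, cols) and `channels`, a named list of matrices
#'   (`count_<marker>` and `glandfrac_<class>`).
#' @examples
#' cells <- data.frame(marker = "CD8", x_um = 150, y_um = 150)
#' hm <- rasterize_objects(cells, glands = NULL, resolution = 100,
#'                         extent = c(400, 400))
#' hm$channels$count_CD8
#' @export
rasterize_objects <- function(cells, glands, resolution = 100,
                              extent = NULL, subsample = 4) {
  if (resolution <= 0) abort("resolution must be positive")
  cells <- cells %||% tibble::tibble(marker = character(),
                                     x_um = numeric(), y_um = numeric())
  glands <- glands %||% tibble::tibble(gland_id = integer(),
                                       gland_class = character(),
                                       x_um = numeric(), y_um = numeric())
  if (nrow(cells) > 0) assert_cols(cells, c("marker", "x_um", "y_um"), "cells")
  if (nrow(glands) > 0) {
    assert_cols(glands, c("gland_id", "gland_class", "x_um", "y_um"), "glands")
  }
  if (is.null(extent)) {
    xs <- c(cells$x_um, glands$x_um, resolution)
    ys <- c(cells$y_um, glands$y_um, resolution)
    extent <- c(ceiling(max(xs) / resolution) * resolution,
                ceiling(max(ys) / resolution) * resolution)
  }
  nx <- max(1L, as.integer(ceiling(extent[1] / resolution - 1e-9)))
  ny <- max(1L, as.integer(ceiling(extent[2] / resolution - 1e-9)))

  channels <- list()
  for (mk in .markers) {
    sub <- cells[normalize_marker(cells$marker) == mk, , drop = FALSE]
    m <- matrix(0, ny, nx)
    if (nrow(sub) > 0) {
      j <- pmin(nx, pmax(1L, floor(sub$x_um / resolution) + 1L))
      i <- pmin(ny, pmax(1L, floor(sub$y_um / resolution) + 1L))
      tab <- table(factor(i, levels = seq_len(ny)), factor(j, levels = seq_len(nx)))
      m <- matrix(as.numeric(tab), ny, nx)
    }
    channels[[paste0("count_", mk)]] <- m
  }

  # gland area fractions: probe a subpixel lattice with point-in-polygon
  for (cl in c("intact", "nonIntact")) {
    frac <- matrix(0, ny, nx)
    sub <- glands[glands$gland_class == cl, , drop = FALSE]
    if (nrow(sub) > 0) {
      step <- resolution / subsample
      offs <- (seq_len(subsample) - 0.5) * step
      covered <- NULL  # lazy allocation of the subpixel hit lattice
      for (gid in unique(sub$gland_id)) {
        poly <- sub[sub$gland_id == gid, , drop = FALSE]
        if (nrow(poly) < 3) next
        bnd <- cbind(c(poly$x_um, poly$x_um[1]), c(poly$y_um, poly$y_um[1]))
        j0 <- max(1L, floor(min(poly$x_um) / resolution) + 1L)
        j1 <- min(nx, floor(max(poly$x_um) / resolution) + 1L)
        i0 <- max(1L, floor(min(poly$y_um) / resolution) + 1L)
        i1 <- min(ny, floor(max(poly$y_um) / resolution) + 1L)
        if (j1 < j0 || i1 < i0) next
        if (is.null(covered)) {
          covered <- matrix(FALSE, ny * subsample, nx * subsample)
        }
        sj <- as.vector(outer(offs, ((j0 - 1):(j1 - 1)) * resolution, `+`))
        si <- as.vector(outer(offs, ((i0 - 1):(i1 - 1)) * resolution, `+`))
        pts <- cbind(rep(sj, times = length(si)), rep(si, each = length(sj)))
        inside <- mgcv::in.out(bnd, pts)
        if (!any(inside)) next
        cj <- round(pts[inside, 1] / step + 0.5)
        ci <- round(pts[inside, 2] / step + 0.5)
        covered[cbind(ci, cj)] <- TRUE
      }
      if (!is.null(covered)) {
        # average the subpixel hits within each pixel
        for (bi in seq_len(subsample)) {
          for (bj in seq_len(subsample)) {
            frac <- frac + covered[seq(bi, ny * subsample, by = subsample),
                                   seq(bj, nx * subsample, by = subsample)]
          }
        }
        frac <- frac / subsample^2
      }
    }
    channels[[paste0("glandfrac_", cl)]] <- frac
  }

  structure(list(resolution = resolution, extent = extent,
                 dim = c(ny, nx), channels = channels),
            class = "heatmap_stack")
}

#' @export
print.heatmap_stack <- function(x, ...) {
  cat("<heatmap_stack> ", x$dim[1], "x", x$dim[2], " px @ ",
      x$resolution, " um/px; channels: ",
      paste(names(x$channels), collapse = ", "), "\n", sep = "")
  invisible(x)
}
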
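#' Construct the tumor-microenvironment region system
#'
#' Labels every heatmap pixel with one region of the tumor-microenvironment
#' system: `tumor` (interior of the smoothed cancerous-gland support),
#' `innerBorder_in`/`innerBorder_out` (56 um each side of the tumor
#' boundary), `border1` (tight outer band, 112.5 um), `border2` (wide outer
#' band, 225 um), `healthy` (intact-gland support), `stroma` (remaining
#' tissue) and `background` (non-tissue). Labels partition the grid with
#' precedence tumor > innerBorder > border1 > border2 > healthy > stroma.
#'
#' Gland supports are smoothed by morphological opening then closing with a
#' disc structuring element; bands are cut from the Euclidean distance
#' transform of the tumor mask (resolution-independent, rather than
#' iterated structuring elements). A pixel's distance to the tumor boundary
#' is taken as `(d_px - 0.5) * resolution`, the center-to-region-edge
#' distance. Tissue is the union of the smoothed gland supports and all
#' pixels within `tissue_radius` of a pixel containing at least one cell.
#'
#' @param heatmap A `heatmap_stack` from [rasterize_objects()] containing
#'   `glandfrac_*` channels.
#' @param widths Named numeric vector of band widths in microns:
#'   `border1` (112.5), `border2` (225), `inner_half` (56).
#' @param smooth_radius_px Disc radius (pixels) for opening/closing of the
#'   gland supports; 0 disables smoothing. Default 1.
#' @param tissue_radius Radius (um) around cell-bearing pixels counted as
#'   tissue. Default 300.
#' @param support_threshold Minimum gland area fraction for a pixel to
#'   count as gland support. Default 0 (any coverage).
#' @return An object of class `roi_map`: list with `labels` (character
#'   matrix over `.roi_levels`), `resolution`, `dim`, `widths`.
#' @examples
#' glands <- disc_polygon(500, 500, 220, gland_class = "nonIntact")
#' hm <- rasterize_objects(NULL, glands, resolution = 50, extent = c(1000, 1000))
#' table(define_rois(hm)$labels)
#' @export
define_rois <- function(heatmap,
                        widths = c(border1 = 112.5, border2 = 225,
                                   inner_half = 56),
                        smooth_radius_px = 1,
                        tissue_radius = 300,
                        support_threshold = 0) {
  stopifnot(inherits(heatmap, "heatmap_stack"))
  ch <- heatmap$channels
  if (is.null(ch$glandfrac_intact) || is.null(ch$glandfrac_nonIntact)) {
    abort("heatmap lacks gland area-fraction channels")
  }
  res <- heatmap$resolution

  smooth <- function(mask) {
    if (smooth_radius_px <= 0 || !any(mask)) return(mask)
    brush <- EBImage::makeBrush(2 * smooth_radius_px + 1, shape = "disc")
    img <- EBImage::Image(t(mask) * 1)  # EBImage is column-major x,y
    out <- EBImage::closing(EBImage::opening(img, brush), brush)
    t(EBImage::imageData(out)) > 0.5
  }

  tumor <- smooth(ch$glandfrac_nonIntact > support_threshold)
  intact <- smooth(ch$glandfrac_intact > support_threshold)
  healthy <- intact & !tumor

  # tissue mask: gland supports plus a neighborhood of any cell
  # (tissue_radius = Inf declares the whole slide tissue)
  ny <- heatmap$dim[1]; nx <- heatmap$dim[2]
  if (is.infinite(tissue_radius)) {
    tissue <- matrix(TRUE, ny, nx)
  } else {
    cellmask <- Reduce(`+`, ch[grep("^count_", names(ch))]) > 0
    tissue <- tumor | healthy
    if (any(cellmask) && tissue_radius > 0) {
      dcell <- edt_pixels(cellmask)
      tissue <- tissue | ((dcell - 0.5) * res <= tissue_radius)
    }
    tissue <- tissue | cellmask
  }

  labels <- matrix("background", ny, nx)
  labels[tissue] <- "stroma"
  labels[healthy] <- "healthy"

  if (any(tumor)) {
    if (all(tumor)) {
      d_out <- matrix(Inf, ny, nx)  # no non-tumor pixels anyway
      d_in <- matrix(Inf, ny, nx)
    } else {
      d_out <- edt_pixels(tumor)   # distance of non-tumor px to tumor
      d_in <- edt_pixels(!tumor)   # distance of tumor px to non-tumor
    }
    band_out <- function(w) !tumor & tissue & ((d_out - 0.5) * res <= w)
    labels[band_out(widths[["border2"]])] <- "border2"
    labels[band_out(widths[["border1"]])] <- "border1"
    labels[band_out(widths[["inner_half"]])] <- "innerBorder_out"
    labels[tumor] <- "tumor"
    labels[tumor & ((d_in - 0.5) * res <= widths[["inner_half"]])] <-
      "innerBorder_in"
  } else {
    warn("no cancerous glands: tumor-derived regions are empty")
  }

  structure(list(labels = labels, resolution = res,
                 dim = heatmap$dim, widths = widths),
            class = "roi_map")
}

# Euclidean distance (in pixels) of each pixel outside `mask` to the
# nearest pixel inside `mask`, center to center; 0 inside the mask.
edt_pixels <- function(mask) {
  img <- EBImage::Image(t(!mask) * 1)  # distmap: distance to nearest 0-pixel
  t(EBImage::imageData(EBImage::distmap(img, metric = "euclidean")))
}

#' Region membership and area
#'
#' `roi_pixels()` returns the logical pixel mask of a measurement region
#' (outer borders are cumulative: `border2` spans the full 225 um band and
#' contains `border1`, which contains the outer inner-border ring; `ws` is
#' all tissue). `roi_area_mm2()` returns its area in mm^2.
#'
#' @param roi_map A `roi_map` from [define_rois()].
#' @param location A measurement region label (see [phene_name()]).
#' @return `roi_pixels()`: logical matrix; `roi_area_mm2()`: scalar.
#' @export
roi_pixels <- function(roi_map, location) {
  stopifnot(inherits(roi_map, "roi_map"))
  if (!location %in% .locations) abort(paste0("unknown location: ", location))
  matrix(roi_map$labels %in% .location_labels[[location]],
         roi_map$dim[1], roi_map$dim[2])
}

#' @rdname roi_pixels
#' @export
roi_area_mm2 <- function(roi_map, location) {
  sum(roi_pixels(roi_map, location)) * (roi_map$resolution / 1000)^2
}

#' @export
print.roi_map <- function(x, ...) {
  cat("<roi_map> ", x$dim[1], "x", x$dim[2], " px @ ", x$resolution,
      " um/px\n", sep = "")
  print(table(x$labels))
  invisible(x)
}

#' Regular polygon approximating a disc
#'
#' Convenience constructor for gland polygons: a `n_vertices`-gon inscribed
#' in the circle of radius `r` around `(cx, cy)`.
#'
#' @param cx,cy Center in microns.
#' @param r Radius in microns.
#' @param gland_class `"intact"` or `"nonIntact"`.
#' @param gland_id Identifier.
#' @param n_vertices Number of vertices (default 24).
#' @return Tibble of vertices in gland polygon format.
#' @export
disc_polygon <- function(cx, cy, r, gland_class = "nonIntact",
                         gland_id = 1L, n_vertices = 24L) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  tibble::tibble(gland_id = gland_id, gland_class = gland_class,
                 x_um = cx + r * cos(th), y_um = cy + r * sin(th))
}
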
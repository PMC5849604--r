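#' Candidate grammar configuration
#'
#' Defines which phene candidates [build_phene_matrix()] enumerates. The
#' default configuration expands, for the five phenotyped markers and the
#' seven measurement regions: counts and densities per (marker, region);
#' mean 4- and 8-nearest-neighbour distances per ordered marker pair and
#' region; count ratios per ordered marker pair within a region plus a few
#' cross-region pairs anchored on the tumor border; and three gland
#' co-occurrence texture features. This yields 553 candidates -- several
#' hundred, deliberately of the same order as a real discovery pool.
#'
#' @param markers Markers to measure.
#' @param locations Regions to measure in.
#' @param families Measurement families to include.
#' @param dist_ks Neighbour counts for DIST (subset of 4, 8).
#' @param ratio_cross_pairs List of `c(location1, location2)` pairs for
#'   cross-region ratios (in addition to all same-region pairs).
#' @param corr_sets Gland co-occurrence class sets to include.
#' @return A list of class `phene_grammar`.
#' @export
phene_grammar <- function(markers = c("CD3", "CD8", "CD68", "CD163", "CD34"),
                          locations = .locations,
                          families = c("COUNT", "DENSITY", "DIST", "RATIO",
                                       "CORR_HARALICK"),
                          dist_ks = c(4L, 8L),
                          ratio_cross_pairs = list(
                            c("border2", "border1"),
                            c("nonIntact", "border1"),
                            c("border1", "border2")),
                          corr_sets = c("intact_nonintact", "intact_size",
                                        "nonintact_size")) {
  markers <- normalize_marker(markers)
  stopifnot(all(locations %in% .locations))
  structure(list(markers = markers, locations = locations,
                 families = families, dist_ks = as.integer(dist_ks),
                 ratio_cross_pairs = ratio_cross_pairs,
                 corr_sets = corr_sets),
            class = "phene_grammar")
}

#' Enumerate the candidates of a grammar
#'
#' @param grammar A [phene_grammar()].
#' @return A `phene_name` tibble, one row per candidate; the candidate
#'   count is a deterministic function of the grammar.
#' @export
enumerate_candidates <- function(grammar = phene_grammar()) {
  g <- grammar
  rows <- list()
  pairs <- expand.grid(a = g$markers, b = g$markers,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
  for (fam in g$families) {
    if (fam %in% c("COUNT", "DENSITY")) {
      for (mk in g$markers) for (loc in g$locations) {
        rows[[length(rows) + 1L]] <- phene_name(fam, mk, location = loc)
      }
    } else if (fam == "DIST") {
      for (i in seq_len(nrow(pairs))) for (loc in g$locations)
        for (k in g$dist_ks) {
          rows[[length(rows) + 1L]] <-
            phene_name("DIST", pairs$a[i], pairs$b[i], location = loc, k = k)
        }
    } else if (fam == "RATIO") {
      locpairs <- c(lapply(g$locations, function(l) c(l, l)),
                    g$ratio_cross_pairs)
      for (i in seq_len(nrow(pairs))) for (lp in locpairs) {
        rows[[length(rows) + 1L]] <-
          phene_name("RATIO", pairs$a[i], pairs$b[i],
                     location = lp[1], location2 = lp[2])
      }
    } else if (fam == "CORR_HARALICK") {
      for (cs in g$corr_sets) {
        rows[[length(rows) + 1L]] <- phene_name("CORR_HARALICK", class_set = cs)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- out[!duplicated(out$name), , drop = FALSE]
  class(out) <- c("phene_name", class(out))
  out
}

#' Build the patients-by-candidates phene matrix
#'
#' Runs datafication (rasterization + region construction) per patient and
#' evaluates every candidate of the grammar, joining the survival outcome.
#' Ratios with a zero denominator, distances with too few neighbour cells
#' and densities of empty regions are missing values, never silently
#' imputed.
#'
#' @param cells Cell table across patients (`patient_id`, `marker`,
#'   `x_um`, `y_um`).
#' @param glands Gland polygon table across patients (`patient_id`,
#'   `gland_id`, `gland_class`, `x_um`, `y_um`).
#' @param outcomes Survival table (`patient_id`, `dfs_months`, `event`).
#' @param grammar A [phene_grammar()].
#' @param resolution Heatmap resolution in um/px (default 100).
#' @param extent Slide extent in um, shared by all patients; default from
#'   the data.
#' @param ... Passed to [define_rois()].
#' @return A tibble (class `phene_matrix`) with columns `patient_id`,
#'   `dfs_months`, `event` and one numeric column per candidate, named in
#'   the phene grammar; the candidate table is attached as attribute
#'   `"candidates"`.
#' @export
build_phene_matrix <- function(cells, glands, outcomes,
                               grammar = phene_grammar(),
                               resolution = 100, extent = NULL, ...) {
  check_survival_table(outcomes)
  cand <- enumerate_candidates(grammar)
  if (is.null(extent)) {
    extent <- c(max(cells$x_um, glands$x_um), max(cells$y_um, glands$y_um))
    extent <- ceiling(extent / resolution) * resolution
  }
  need_sizes <- any(cand$operation == "CORR_HARALICK" &
                      cand$class_set != "intact_nonintact")
  size_breaks <- if (need_sizes && nrow(glands) > 0) {
    gland_size_breaks(glands)
  } else NULL

  vals <- lapply(outcomes$patient_id, function(pid) {
    patient_candidate_values(
      cells[cells$patient_id == pid, , drop = FALSE],
      glands[glands$patient_id == pid, , drop = FALSE],
      cand, resolution = resolution, extent = extent,
      size_breaks = size_breaks, ...)
  })
  m <- do.call(rbind, vals)
  colnames(m) <- cand$name
  out <- dplyr::bind_cols(
    outcomes[, c("patient_id", "dfs_months", "event")],
    tibble::as_tibble(m)
  )
  attr(out, "candidates") <- cand
  class(out) <- c("phene_matrix", class(out))
  out
}

# evaluate all candidates for one patient's objects
patient_candidate_values <- function(cells, glands, cand, resolution, extent,
                                     size_breaks = NULL, ...) {
  hm <- rasterize_objects(cells, glands, resolution = resolution,
                          extent = extent)
  roi <- suppressWarnings(define_rois(hm, ...))
  counts <- list(); dists <- list()

  count_of <- function(mk, loc) {
    key <- paste(mk, loc)
    if (is.null(counts[[key]])) {
      counts[[key]] <<- count_in_roi(cells, roi, mk, loc)
    }
    counts[[key]]
  }
  # per ordered marker pair: slide-wide per-anchor-cell knn means are
  # computed once, then averaged over anchors in each region
  dist_of <- function(a, b, k, loc) {
    key <- paste(a, b)
    if (is.null(dists[[key]])) {
      asub <- cells[normalize_marker(cells$marker) == a, , drop = FALSE]
      bsub <- cells[normalize_marker(cells$marker) == b, , drop = FALSE]
      entry <- list(n_b = nrow(bsub), idx = NULL, d4 = NULL, d8 = NULL)
      if (nrow(asub) > 0 && nrow(bsub) >= 4) {
        entry$idx <- cell_pixel_index(asub, roi)
        entry$d4 <- knn_mean_dists(asub$x_um, asub$y_um,
                                   bsub$x_um, bsub$y_um, min(4L, nrow(bsub)))
        if (nrow(bsub) >= 8) {
          entry$d8 <- knn_mean_dists(asub$x_um, asub$y_um,
                                     bsub$x_um, bsub$y_um, 8L)
        }
      }
      dists[[key]] <<- entry
    }
    e <- dists[[key]]
    if (e$n_b < k || is.null(e$idx)) return(NA_real_)
    dvec <- if (k == 4L) e$d4 else e$d8
    if (is.null(dvec)) return(NA_real_)
    mask <- roi_pixels(roi, loc)
    sel <- mask[e$idx]
    if (!any(sel)) return(NA_real_)
    mean(dvec[sel])
  }

  vapply(seq_len(nrow(cand)), function(i) {
    r <- cand[i, ]
    switch(r$operation,
      COUNT = as.numeric(count_of(r$arg1, r$location)),
      DENSITY = {
        area <- roi_area_mm2(roi, r$location)
        if (area <= 0) NA_real_ else count_of(r$arg1, r$location) / area
      },
      RATIO = {
        den <- count_of(r$arg2, r$location2)
        if (den == 0) NA_real_ else count_of(r$arg1, r$location) / den
      },
      DIST = dist_of(r$arg1, r$arg2, r$k, r$location),
      CORR_HARALICK = as.numeric(gland_cooccurrence_correlation(
        glands, resolution = resolution, extent = extent,
        class_set = r$class_set, size_breaks = size_breaks))
    )
  }, numeric(1))
}
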
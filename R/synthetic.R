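#' Synthetic cohort configuration
#'
#' Describes the study conditions the generator emulates: a 90-patient
#' prostatectomy cohort with 40 PSA-recurrence events observed over a
#' 2-118 month follow-up window, per-patient tissue maps (clustered
#' cancerous glands, scattered healthy glands, marker-labelled cells at
#' region-dependent densities) and, optionally, planted prognostic phenes.
#'
#' A planted effect `(phene, coef)` couples a per-patient latent score
#' `z ~ N(0,1)` to the hazard (`eta += coef * z`) and to the tissue map:
#' the phene's numerator marker density in its region is multiplied by
#' `exp(effect_coupling * z)` (denominator/neighbour marker by
#' `exp(-effect_coupling * z)`), so the measured phene value carries the
#' planted association. Plantable phenes are COUNT, DENSITY, RATIO and
#' DIST names; CORR_HARALICK names (and names outside the grammar) are
#' rejected.
#'
#' @param n_patients,n_events Cohort size and number of progression events.
#' @param followup_range Follow-up window in months, `c(min, max)`.
#' @param slide_extent Slide size in um, `c(width, height)`.
#' @param resolution Raster resolution (um/px) used to realize cell
#'   placement.
#' @param n_tumor_glands,n_healthy_glands Gland counts per slide.
#' @param gland_radius_meanlog,gland_radius_sdlog Log-normal gland radius
#'   parameters (um).
#' @param tumor_cluster_sd Spatial spread (um) of the cancerous gland
#'   cluster around its random center.
#' @param marker_baseline Named baseline densities (cells/mm^2) per marker.
#' @param region_multiplier Named density multipliers per raw region label
#'   (immune infiltration concentrates at the tumor border).
#' @param planted_effects Data frame with columns `phene` (grammar name)
#'   and `coef` (log-hazard per latent SD), or `NULL`.
#' @param effect_coupling Log-density shift per latent SD (default 0.5).
#' @param frailty_sd SD of the unexplained latent hazard component
#'   (default 0.5: planted effects of |coef| >= 1 dominate the hazard).
#' @param weibull_shape Shape of the Weibull event-time model.
#' @param aggregate_36m If `TRUE`, event times at or below 36 months are
#'   rounded up to 36 (emulating approximate recurrence dating); default
#'   `FALSE`.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 90L,
                          n_events = 40L,
                          followup_range = c(2, 118),
                          slide_extent = c(4000, 4000),
                          resolution = 100,
                          n_tumor_glands = 50L,
                          n_healthy_glands = 60L,
                          gland_radius_meanlog = log(110),
                          gland_radius_sdlog = 0.35,
                          tumor_cluster_sd = 600,
                          marker_baseline = c(CD3 = 60, CD8 = 40, CD68 = 30,
                                              CD163 = 30, CD34 = 50,
                                              negative = 100),
                          region_multiplier = c(background = 0, stroma = 1,
                                                healthy = 0.8, border2 = 1.2,
                                                border1 = 1.5,
                                                innerBorder_out = 1.5,
                                                tumor = 1.2,
                                                innerBorder_in = 1.2),
                          planted_effects = NULL,
                          effect_coupling = 0.5,
                          frailty_sd = 0.5,
                          weibull_shape = 2,
                          aggregate_36m = FALSE) {
  if (n_events > n_patients) abort("n_events must not exceed n_patients")
  if (any(followup_range <= 0) || diff(followup_range) <= 0) {
    abort("followup_range must be a positive increasing interval")
  }
  if (any(marker_baseline < 0)) abort("densities must be non-negative")
  planted <- validate_planted_effects(planted_effects)
  structure(list(
    n_patients = as.integer(n_patients), n_events = as.integer(n_events),
    followup_range = followup_range, slide_extent = slide_extent,
    resolution = resolution, n_tumor_glands = as.integer(n_tumor_glands),
    n_healthy_glands = as.integer(n_healthy_glands),
    gland_radius_meanlog = gland_radius_meanlog,
    gland_radius_sdlog = gland_radius_sdlog,
    tumor_cluster_sd = tumor_cluster_sd,
    marker_baseline = marker_baseline,
    region_multiplier = region_multiplier,
    planted_effects = planted, effect_coupling = effect_coupling,
    frailty_sd = frailty_sd, weibull_shape = weibull_shape,
    aggregate_36m = aggregate_36m
  ), class = "cohort_config")
}

validate_planted_effects <- function(planted) {
  if (is.null(planted) || nrow(as.data.frame(planted)) == 0) {
    return(tibble::tibble(phene = character(), coef = numeric()))
  }
  planted <- tibble::as_tibble(planted)
  assert_cols(planted, c("phene", "coef"), "planted_effects")
  parsed <- parse_phene(planted$phene)  # errors on grammar-invalid names
  if (any(parsed$operation == "CORR_HARALICK")) {
    abort("CORR_HARALICK phenes cannot be planted (no density realization)")
  }
  planted
}

#' Generate a synthetic cohort
#'
#' Draws the full cohort: latent hazards, survival outcomes and
#' per-patient tissue maps. The latent hazard is
#' `eta = sum(coef_j * z_j) + N(0, frailty_sd)`; the `n_events` patients
#' with the largest `eta` progress. Event times are drawn from a Weibull
#' proportional-hazards model given `eta` and mapped monotonically into
#' `followup_range`; censored patients get follow-up uniform in the range
#' and are labelled non-progression throughout the pipeline. Cell
#' placement is an inhomogeneous Poisson process over the patient's region
#' raster with planted per-region density shifts.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; fixed seed gives a bit-identical cohort.
#' @return A list of class `synthetic_cohort`: `cells`, `glands`,
#'   `outcomes` (tibbles across patients), `truth` (planted effects and
#'   per-patient latents) and `config`.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_patients = 4, n_events = 2,
#'                                      slide_extent = c(1500, 1500)),
#'                        seed = 1)
#' coh$outcomes
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, {
    n <- config$n_patients
    planted <- config$planted_effects
    p <- nrow(planted)
    z <- matrix(rnorm(n * p), n, p)
    if (p > 0) colnames(z) <- planted$phene
    eta <- as.numeric(if (p > 0) z %*% planted$coef else rep(0, n)) +
      rnorm(n, 0, config$frailty_sd)

    event <- rep(0L, n)
    event[order(eta, decreasing = TRUE)[seq_len(config$n_events)]] <- 1L

    lo <- config$followup_range[1]; hi <- config$followup_range[2]
    dfs <- runif(n, lo, hi)
    if (config$n_events > 0) {
      idx <- which(event == 1L)
      u <- runif(length(idx))
      t_raw <- (-log(u) / exp(eta[idx]))^(1 / config$weibull_shape)
      # monotone (affine) map of the raw event times into the window
      if (length(idx) > 1 && diff(range(t_raw)) > 0) {
        dfs[idx] <- lo + (hi - lo) * (t_raw - min(t_raw)) / diff(range(t_raw))
      } else {
        dfs[idx] <- (lo + hi) / 2
      }
      if (config$aggregate_36m) {
        agg <- event == 1L & dfs <= 36
        dfs[agg] <- 36
      }
    }
    dfs <- pmin(hi, pmax(lo, dfs))

    pids <- sprintf("P%03d", seq_len(n))
    outcomes <- tibble::tibble(patient_id = pids, dfs_months = dfs,
                               event = event)

    maps <- lapply(seq_len(n), function(i) {
      generate_patient_map(config, z_scores = z[i, ])
    })
    cells <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      dplyr::mutate(maps[[i]]$cells, patient_id = pids[i], .before = 1)
    }))
    glands <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      dplyr::mutate(maps[[i]]$glands, patient_id = pids[i], .before = 1)
    }))

    truth <- list(
      planted_effects = planted,
      latents = dplyr::bind_cols(
        tibble::tibble(patient_id = pids, eta = eta),
        tibble::as_tibble(z, .name_repair = "minimal")
      )
    )
    structure(list(cells = cells, glands = glands, outcomes = outcomes,
                   truth = truth, config = config),
              class = "synthetic_cohort")
  })
}

#' Generate one patient's tissue map
#'
#' Places clustered cancerous and scattered healthy glands, builds the
#' region raster, and realizes marker cells as an inhomogeneous Poisson
#' process whose per-region densities carry the patient's planted shifts.
#' Uses the current RNG stream (called by [simulate_cohort()] under its
#' seed).
#'
#' @param config A [cohort_config()].
#' @param z_scores Named latent scores for the planted phenes (may be
#'   empty).
#' @return List with `cells` and `glands` tibbles and the `roi` map used.
#' @export
generate_patient_map <- function(config, z_scores = numeric(0)) {
  ext <- config$slide_extent
  r_mean <- exp(config$gland_radius_meanlog +
                  config$gland_radius_sdlog^2 / 2)
  if (min(ext) < 6 * r_mean) {
    abort("slide_extent too small for the configured glands")
  }
  # cancerous glands cluster around a random center in the middle half
  ctr <- runif(2, ext / 4, 3 * ext / 4)
  nt <- config$n_tumor_glands
  gl <- list()
  if (nt > 0) {
    gx <- pmin(ext[1] - r_mean, pmax(r_mean, rnorm(nt, ctr[1], config$tumor_cluster_sd)))
    gy <- pmin(ext[2] - r_mean, pmax(r_mean, rnorm(nt, ctr[2], config$tumor_cluster_sd)))
    rr <- exp(rnorm(nt, config$gland_radius_meanlog, config$gland_radius_sdlog))
    for (i in seq_len(nt)) {
      gl[[length(gl) + 1L]] <- disc_polygon(gx[i], gy[i], rr[i],
                                            "nonIntact", gland_id = i)
    }
  }
  nh <- config$n_healthy_glands
  if (nh > 0) {
    hx <- runif(nh, r_mean, ext[1] - r_mean)
    hy <- runif(nh, r_mean, ext[2] - r_mean)
    # keep healthy glands off the tumor cluster core
    far <- sqrt((hx - ctr[1])^2 + (hy - ctr[2])^2) >
      1.2 * config$tumor_cluster_sd
    rr <- exp(rnorm(nh, config$gland_radius_meanlog, config$gland_radius_sdlog))
    for (i in which(far)) {
      gl[[length(gl) + 1L]] <- disc_polygon(hx[i], hy[i], rr[i],
                                            "intact", gland_id = nt + i)
    }
  }
  glands <- dplyr::bind_rows(gl)

  hm <- rasterize_objects(NULL, glands, resolution = config$resolution,
                          extent = ext)
  roi <- suppressWarnings(define_rois(hm, tissue_radius = Inf))
  # tissue_radius Inf: synthetic slides are fully tissue
  roi$labels[roi$labels == "background"] <- "stroma"

  shifts <- planted_density_shifts(config, z_scores)
  px_area_mm2 <- (config$resolution / 1000)^2
  cells <- list()
  for (mk in names(config$marker_baseline)) {
    lam <- config$marker_baseline[[mk]] *
      config$region_multiplier[roi$labels] * px_area_mm2
    sh <- shifts[[mk]]
    if (!is.null(sh)) lam <- lam * sh(roi$labels)
    counts <- rpois(length(lam), lam)
    tot <- sum(counts)
    if (tot > 0) {
      idx <- rep.int(seq_along(counts), counts)
      i <- (idx - 1L) %% roi$dim[1] + 1L
      j <- (idx - 1L) %/% roi$dim[1] + 1L
      cells[[length(cells) + 1L]] <- tibble::tibble(
        marker = mk,
        x_um = (j - 1 + runif(tot)) * config$resolution,
        y_um = (i - 1 + runif(tot)) * config$resolution
      )
    }
  }
  cells <- if (length(cells) > 0) dplyr::bind_rows(cells) else
    tibble::tibble(marker = character(), x_um = numeric(), y_um = numeric())
  list(cells = cells, glands = glands, roi = roi)
}

# per-marker multiplicative density shift functions label-vector -> factor
planted_density_shifts <- function(config, z_scores) {
  planted <- config$planted_effects
  if (nrow(planted) == 0) return(list())
  parsed <- parse_phene(planted$phene)
  cpl <- config$effect_coupling
  shifts <- list()
  add <- function(marker, labels, factor_per_cell) {
    force(marker); force(labels); force(factor_per_cell)
    prev <- shifts[[marker]]
    shifts[[marker]] <<- function(lab) {
      f <- if (is.null(prev)) rep(1, length(lab)) else prev(lab)
      f * ifelse(lab %in% labels, factor_per_cell, 1)
    }
  }
  for (i in seq_len(nrow(parsed))) {
    z <- z_scores[[i]]
    r <- parsed[i, ]
    up <- exp(cpl * z); dn <- exp(-cpl * z)
    if (r$operation %in% c("COUNT", "DENSITY")) {
      add(r$arg1, .location_labels[[r$location]], up)
    } else if (r$operation == "RATIO") {
      add(r$arg1, .location_labels[[r$location]], up)
      add(r$arg2, .location_labels[[r$location2]], dn)
    } else if (r$operation == "DIST") {
      # more neighbours -> shorter distances: value falls as z rises
      add(r$arg2, unique(unlist(.location_labels)), dn)
    }
  }
  shifts
}

#' Write / read a synthetic cohort as plain-text files
#'
#' Cells and outcomes are CSV; glands are a GeoJSON FeatureCollection of
#' polygons with `patient_id`, `gland_id` and `gland_class` properties.
#'
#' @param cohort A `synthetic_cohort` (or compatible list).
#' @param dir Output directory (created if needed).
#' @return `write_cohort()` the directory, invisibly; `read_cohort()` a
#'   list with `cells`, `glands`, `outcomes`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$outcomes, file.path(dir, "outcomes.csv"),
                   row.names = FALSE)
  keys <- unique(cohort$glands[, c("patient_id", "gland_id", "gland_class")])
  features <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    poly <- cohort$glands[cohort$glands$patient_id == k$patient_id &
                            cohort$glands$gland_id == k$gland_id, ]
    ring <- cbind(poly$x_um, poly$y_um)
    ring <- rbind(ring, ring[1, ])
    list(type = "Feature",
         properties = list(patient_id = k$patient_id,
                           gland_id = k$gland_id,
                           gland_class = k$gland_class),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       file.path(dir, "glands.geojson"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  cells <- tibble::as_tibble(utils::read.csv(file.path(dir, "cells.csv")))
  outcomes <- tibble::as_tibble(utils::read.csv(file.path(dir, "outcomes.csv")))
  gj <- jsonlite::read_json(file.path(dir, "glands.geojson"))
  glands <- dplyr::bind_rows(lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    ring <- ring[-length(ring)]  # drop closing vertex
    tibble::tibble(
      patient_id = f$properties$patient_id,
      gland_id = f$properties$gland_id,
      gland_class = f$properties$gland_class,
      x_um = vapply(ring, function(v) as.numeric(v[[1]]), numeric(1)),
      y_um = vapply(ring, function(v) as.numeric(v[[2]]), numeric(1))
    )
  }))
  list(cells = cells, glands = glands, outcomes = outcomes)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", x$config$n_patients, " patients, ",
      sum(x$outcomes$event), " events, ", nrow(x$cells), " cells, ",
      nrow(x$truth$planted_effects), " planted effect(s)\n", sep = "")
  invisible(x)
}
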
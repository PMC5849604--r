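test_that("cohort honours size, event count and follow-up window", {
  cfg <- cohort_config(n_patients = 30, n_events = 13,
                       slide_extent = c(1600, 1600),
                       n_tumor_glands = 8, n_healthy_glands = 8)
  coh <- simulate_cohort(cfg, seed = 2)
  expect_equal(nrow(coh$outcomes), 30)
  expect_equal(sum(coh$outcomes$event), 13)
  expect_true(all(coh$outcomes$dfs_months >= 2 &
                    coh$outcomes$dfs_months <= 118))
  # every patient appears in all three tables
  expect_setequal(unique(coh$cells$patient_id), coh$outcomes$patient_id)
  expect_setequal(unique(coh$glands$patient_id), coh$outcomes$patient_id)
  # all markers present; coordinates inside the slide
  expect_true(all(coh$cells$x_um >= 0 & coh$cells$x_um <= 1600))
  expect_true(all(coh$cells$marker %in% phenescan:::.markers))
})

test_that("generation is deterministic in the seed", {
  cfg <- tiny_cohort_config()
  a <- simulate_cohort(cfg, seed = 7)
  b <- simulate_cohort(cfg, seed = 7)
  d <- simulate_cohort(cfg, seed = 8)
  expect_identical(a[c("cells", "glands", "outcomes")],
                   b[c("cells", "glands", "outcomes")])
  expect_false(identical(a$cells$x_um, d$cells$x_um))
})

test_that("without planted effects the linear predictor is flat", {
  coh <- simulate_cohort(tiny_cohort_config(), seed = 3)
  expect_equal(nrow(coh$truth$planted_effects), 0)
  # latent hazard is pure frailty: no phene column exists in the truth
  expect_equal(ncol(coh$truth$latents), 2)  # patient_id + eta only
})

test_that("invalid planted phenes are rejected at config time", {
  expect_error(tiny_cohort_config(
    planted = data.frame(phene = "CORR Haralick on intact & non-intact glands",
                         coef = 1)), "cannot be planted")
  expect_error(tiny_cohort_config(
    planted = data.frame(phene = "RATIO nonsense", coef = 1)),
    "cannot parse")
  expect_error(cohort_config(n_patients = 10, n_events = 11),
               "n_events")
})

test_that("a zero-density marker yields no cells", {
  cfg <- tiny_cohort_config(
    marker_baseline = c(CD3 = 0, CD8 = 40, CD68 = 0, CD163 = 0,
                        CD34 = 40, negative = 0))
  coh <- simulate_cohort(cfg, seed = 4)
  expect_equal(sum(coh$cells$marker == "CD3"), 0)
  expect_gt(sum(coh$cells$marker == "CD8"), 0)
})

test_that("homogeneous cell counts stay within the Poisson envelope", {
  # glandless slide, flat multiplier 1 everywhere: count ~ Poisson(lambda A)
  cfg <- cohort_config(n_patients = 2, n_events = 1,
                       slide_extent = c(2000, 2000),
                       n_tumor_glands = 0, n_healthy_glands = 0,
                       marker_baseline = c(CD3 = 0, CD8 = 25, CD68 = 0,
                                           CD163 = 0, CD34 = 0,
                                           negative = 0),
                       region_multiplier = c(background = 1, stroma = 1,
                                             healthy = 1, border2 = 1,
                                             border1 = 1,
                                             innerBorder_out = 1, tumor = 1,
                                             innerBorder_in = 1))
  lamA <- 25 * 4  # 25 / mm^2 over 4 mm^2
  withr::with_seed(12, {
    hits <- vapply(1:100, function(i) {
      m <- suppressWarnings(generate_patient_map(cfg))
      abs(nrow(m$cells) - lamA) <= 4 * sqrt(lamA)
    }, logical(1))
  })
  expect_gte(mean(hits), 0.95)
})

test_that("planted negative count effect lowers the count in progressors", {
  cfg <- cohort_config(n_patients = 50, n_events = 22,
                       slide_extent = c(1600, 1600),
                       n_tumor_glands = 10, n_healthy_glands = 10,
                       planted_effects = data.frame(phene = "#CD8_border1",
                                                    coef = -1.3))
  coh <- simulate_cohort(cfg, seed = 6)
  counts <- vapply(coh$outcomes$patient_id, function(pid) {
    cells <- coh$cells[coh$cells$patient_id == pid, ]
    glands <- coh$glands[coh$glands$patient_id == pid, ]
    hm <- rasterize_objects(cells, glands, resolution = 100,
                            extent = cfg$slide_extent)
    roi <- suppressWarnings(define_rois(hm, tissue_radius = Inf))
    count_in_roi(cells, roi, "CD8", "border1")
  }, numeric(1))
  ev <- coh$outcomes$event
  expect_lt(mean(counts[ev == 1]), mean(counts[ev == 0]))
})

test_that("36-month aggregation rounds early event times when enabled", {
  cfg <- tiny_cohort_config(aggregate_36m = TRUE)
  coh <- simulate_cohort(cfg, seed = 9)
  ev_times <- coh$outcomes$dfs_months[coh$outcomes$event == 1]
  expect_true(all(ev_times >= 36))
})

test_that("cohort files round-trip through CSV and GeoJSON", {
  coh <- simulate_cohort(tiny_cohort_config(), seed = 10)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(as.data.frame(back$outcomes),
               as.data.frame(coh$outcomes))
  expect_equal(nrow(back$cells), nrow(coh$cells))
  expect_equal(back$glands$x_um, coh$glands$x_um, tolerance = 1e-8)
  expect_setequal(unique(back$glands$gland_class),
                  unique(coh$glands$gland_class))
})
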
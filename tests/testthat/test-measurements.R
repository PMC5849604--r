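test_that("region counts match hand-labelled pixels and partition to ws", {
  tumor <- matrix(FALSE, 4, 4)
  tumor[2:3, 2:3] <- TRUE
  roi <- define_rois(mask_heatmap(tumor, res = 100), smooth_radius_px = 0,
                     tissue_radius = Inf)
  # three cells: pixel (2,2) = tumor core/inner, (1,1) = outer band, (4,4)
  cells <- tibble::tibble(marker = c("CD8", "CD8", "CD34"),
                          x_um = c(150, 50, 350),
                          y_um = c(150, 50, 350))
  expect_equal(count_in_roi(cells, roi, "CD8", "nonIntact"), 1)
  expect_equal(count_in_roi(cells, roi, "CD8", "border1"), 1)
  expect_equal(count_in_roi(cells, roi, "CD68", "ws"), 0)
  # raw labels partition, so disjoint-region counts sum to the ws count
  raw_regions <- c("nonIntact", "intact", "stroma")
  outer_only <- sum(roi$labels %in% c("innerBorder_out", "border1",
                                      "border2"))
  expect_equal(count_in_roi(cells, roi, "CD8", "ws"), 2)
  expect_equal(count_in_roi(cells, roi, "CD34", "ws"), 1)
})

test_that("density is count over region area, missing for empty regions", {
  tumor <- matrix(FALSE, 4, 4); tumor[2:3, 2:3] <- TRUE
  roi <- define_rois(mask_heatmap(tumor, res = 1000), smooth_radius_px = 0,
                     tissue_radius = Inf)
  # 4 tumor pixels at 1 mm^2 each; 10 cells inside
  cells <- tibble::tibble(marker = "CD8",
                          x_um = stats::runif(10, 1000, 3000),
                          y_um = stats::runif(10, 1000, 3000))
  expect_equal(density_in_roi(cells, roi, "CD8", "nonIntact"), 10 / 4)
  expect_identical(density_in_roi(cells, roi, "CD8", "intact"), NA_real_)
  # definitional cross-check on a random layout
  expect_equal(density_in_roi(cells, roi, "CD8", "ws"),
               count_in_roi(cells, roi, "CD8", "ws") /
                 roi_area_mm2(roi, "ws"))
})

test_that("knn distances match hand values, contracts and brute force", {
  tumor <- matrix(TRUE, 1, 1)
  roi <- define_rois(mask_heatmap(tumor, res = 1e6), smooth_radius_px = 0,
                     tissue_radius = Inf)  # one giant pixel: ws = everything
  a <- tibble::tibble(marker = "CD68", x_um = 0, y_um = 0)
  b <- tibble::tibble(marker = "CD34", x_um = c(1, 2, 3, 4, 9), y_um = 0)
  cells <- dplyr::bind_rows(a, b)
  expect_equal(avg_knn_distance(cells, roi, "CD68", "CD34", k = 4), 2.5)
  # fewer neighbours than k is missing, as is an empty anchor set
  expect_identical(avg_knn_distance(dplyr::bind_rows(a, b[1:3, ]), roi,
                                    "CD68", "CD34", k = 4), NA_real_)
  expect_identical(avg_knn_distance(b, roi, "CD68", "CD34", k = 4),
                   NA_real_)

  # brute-force full pairwise sort oracle on random points
  withr::with_seed(31, {
    pa <- tibble::tibble(marker = "CD68", x_um = stats::runif(50, 0, 500),
                         y_um = stats::runif(50, 0, 500))
    pb <- tibble::tibble(marker = "CD34", x_um = stats::runif(80, 0, 500),
                         y_um = stats::runif(80, 0, 500))
    got <- avg_knn_distance(dplyr::bind_rows(pa, pb), roi, "CD68", "CD34",
                            k = 8)
    per_a <- vapply(seq_len(50), function(i) {
      d <- sort(sqrt((pb$x_um - pa$x_um[i])^2 + (pb$y_um - pa$y_um[i])^2))
      mean(d[1:8])
    }, numeric(1))
    expect_equal(got, mean(per_a), tolerance = 1e-10)
  })
})

test_that("haralick correlation matches manual co-occurrence arithmetic", {
  # 3x3 two-class checkerboard, manual GLCM over the 8-neighbourhood
  lab <- matrix(c(1, 2, 1, 2, 1, 2, 1, 2, 1), 3, 3)
  got <- phenescan:::haralick_correlation(lab, n_levels = 2)
  P <- matrix(0, 2, 2)
  for (i in 1:3) for (j in 1:3) {
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      i2 <- i + di; j2 <- j + dj
      if (i2 < 1 || i2 > 3 || j2 < 1 || j2 > 3) next
      P[lab[i, j], lab[i2, j2]] <- P[lab[i, j], lab[i2, j2]] + 1
    }
  }
  P <- P / sum(P)
  mi <- sum(1:2 * rowSums(P)); mj <- sum(1:2 * colSums(P))
  si <- sqrt(sum((1:2 - mi)^2 * rowSums(P)))
  sj <- sqrt(sum((1:2 - mj)^2 * colSums(P)))
  manual <- sum(outer(1:2 - mi, 1:2 - mj) * P) / (si * sj)
  expect_equal(got, manual, tolerance = 1e-12)
  expect_lt(got, 0)  # checkerboard: unlike classes adjoin

  # degenerate single-class raster returns the flagged 0
  one <- phenescan:::haralick_correlation(matrix(1, 4, 4), n_levels = 2)
  expect_equal(as.numeric(one), 0)
  expect_true(attr(one, "degenerate"))
})

test_that("gland co-occurrence is computed from polygons end to end", {
  glands <- dplyr::bind_rows(
    disc_polygon(250, 250, 200, "intact", gland_id = 1),
    disc_polygon(750, 750, 200, "nonIntact", gland_id = 2),
    disc_polygon(250, 750, 150, "nonIntact", gland_id = 3)
  )
  v <- gland_cooccurrence_correlation(glands, resolution = 100,
                                      extent = c(1000, 1000))
  expect_true(v >= -1 && v <= 1)
  # size variant needs breaks
  expect_error(gland_cooccurrence_correlation(glands, resolution = 100,
                                              extent = c(1000, 1000),
                                              class_set = "nonintact_size"),
               "size_breaks")
  brk <- gland_size_breaks(dplyr::mutate(glands, patient_id = "P1"))
  v2 <- gland_cooccurrence_correlation(glands, resolution = 100,
                                       extent = c(1000, 1000),
                                       class_set = "nonintact_size",
                                       size_breaks = brk)
  expect_true(v2 >= -1 && v2 <= 1)
})
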
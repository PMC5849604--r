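make_ranking <- function(acc, p = NULL, phenes = NULL) {
  k <- length(acc)
  if (is.null(phenes)) phenes <- paste0("#CD8_border", seq_len(k))
  if (is.null(p)) p <- rep(0.01, k)
  tibble::tibble(
    phene = phenes,
    operator = ">=", mean_threshold = 1,
    cv_accuracy = acc,
    cv_logrank_p = p,
    top5_count = rev(seq_len(k)), n_folds = 20,
    unrankable = FALSE, rank = seq_len(k)
  )
}

test_that("accuracy floor removes at-chance candidates inclusively", {
  r <- make_ranking(c(0.9, 0.5, 0.49, 0.51, NA))
  out <- accuracy_filter(r)
  expect_setequal(out$phene, r$phene[c(1, 4)])  # 0.50 itself removed
  log <- attr(out, "removed")
  expect_equal(nrow(log), 3)
  expect_true(all(log$stage == "accuracy_filter"))
  # floor 0 keeps everything rankable
  expect_equal(nrow(accuracy_filter(make_ranking(c(0.6, 0.7)), floor = 0)), 2)
})

test_that("correlation filter keeps the higher-ranked member of a pair", {
  pm <- noise_phene_matrix(n = 30, n_cand = 4, seed = 2)
  pm$dup <- pm[["#CD8_border1"]]
  r <- make_ranking(c(0.9, 0.8, 0.7, 0.6, 0.55),
                    phenes = c("#CD8_border1", "#CD8_border2",
                               "#CD8_border3", "#CD8_border4", "dup"))
  out <- correlation_filter(pm, r)
  expect_false("dup" %in% out$phene)
  expect_true("#CD8_border1" %in% out$phene)
  expect_match(attr(out, "removed")$reason, "#CD8_border1")
})

test_that("filter decisions match exhaustive pair enumeration", {
  withr::with_seed(77, {
    pm <- noise_phene_matrix(n = 40, n_cand = 4, seed = 76)
    pm$planted <- 0.9 * scale(pm[["#CD8_border2"]])[, 1] +
      sqrt(1 - 0.81) * stats::rnorm(40)
    nm <- c(paste0("#CD8_border", 1:4), "planted")
    r <- make_ranking(seq(0.9, 0.5, length.out = 5), phenes = nm)
    out <- correlation_filter(pm, r, max_abs_corr = 0.75)
    # oracle: greedy scan over the full correlation matrix in rank order
    cm <- cor(as.matrix(pm[nm]))
    kept <- character(0)
    for (ph in nm) {
      if (all(abs(cm[ph, kept]) < 0.75)) kept <- c(kept, ph)
    }
    expect_identical(out$phene, kept)
  })
})

test_that("zero-variance columns are kept but flagged", {
  pm <- noise_phene_matrix(n = 20, n_cand = 2, seed = 30)
  pm$flat <- 1
  r <- make_ranking(c(0.8, 0.7, 0.6),
                    phenes = c("#CD8_border1", "flat", "#CD8_border2"))
  out <- correlation_filter(pm, r)
  expect_true("flat" %in% out$phene)
  expect_true("flat" %in% attr(out, "zero_variance"))
})

test_that("Holm step-down reproduces the hand decision sequence", {
  # 0.001 < .05/4, 0.01 < .05/3, 0.03 >= .05/2 stops
  res <- multiple_testing_correct(c(0.001, 0.01, 0.03, 0.04),
                                  method = "holm_bonferroni")
  expect_equal(res$significant, c(TRUE, TRUE, FALSE, FALSE))
  # all p = 1: nothing significant under any method
  for (m in c("holm_bonferroni", "bonferroni", "benjamini_hochberg")) {
    expect_false(any(multiple_testing_correct(rep(1, 5),
                                              method = m)$significant))
  }
  # single test: all three reduce to p < alpha
  for (m in c("holm_bonferroni", "bonferroni", "benjamini_hochberg")) {
    expect_true(multiple_testing_correct(0.04, method = m)$significant)
    expect_false(multiple_testing_correct(0.06, method = m)$significant)
  }
})

test_that("significant sets nest: Bonferroni within Holm within BH", {
  withr::with_seed(55, {
    for (b in 1:200) {
      p <- stats::runif(sample(3:30, 1))^sample(1:3, 1)
      bon <- multiple_testing_correct(p, "bonferroni")$significant
      hol <- multiple_testing_correct(p, "holm_bonferroni")$significant
      bh <- multiple_testing_correct(p, "benjamini_hochberg")$significant
      expect_true(all(!bon | hol))  # bonferroni subset of holm
      expect_true(all(!hol | bh))   # holm subset of BH
    }
  })
})

test_that("CART counts find dominant splitters and respect tree bounds", {
  pm <- noise_phene_matrix(n = 40, n_cand = 5, seed = 61)
  pm$strong <- pm$event * 2 + withr::with_seed(62, stats::rnorm(40, 0, 0.05))
  sub <- c("strong", paste0("#CD8_border", 1:5))
  counts <- cart_subset_selection(pm, sub, depth = 2)
  expect_equal(counts$phene[1], "strong")
  expect_equal(counts$cart_count[1], 40)       # selected in every fold
  expect_true(all(counts$cart_count <= 40))
  # a depth-2 tree uses at most 3 distinct features
  expect_error(cart_subset_selection(pm, "strong"), "at least two")
})

test_that("the selection pipeline composes stages and logs removals", {
  pm <- noise_phene_matrix(n = 40, n_cand = 6, seed = 90)
  pm$strong <- pm$event + withr::with_seed(91, stats::rnorm(40, 0, 0.1))
  pm$echo <- pm$strong + withr::with_seed(92, stats::rnorm(40, 0, 0.01))
  r <- suppressMessages(loocv_rank(pm))
  sel <- select_phenes(pm, r, alpha = 0.05)
  expect_s3_class(sel, "phene_selection")
  # the echoed copy is removed by the correlation filter, not selected
  expect_false(all(c("strong", "echo") %in% sel$significant$phene))
  accounted <- c(sel$significant$phene, sel$removed$phene)
  expect_setequal(accounted, r$phene)          # removal log is complete
  expect_true("strong" %in% sel$significant$phene ||
                "echo" %in% sel$significant$phene)
  g <- glance(sel)
  expect_equal(g$n_significant, nrow(sel$significant))
})
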
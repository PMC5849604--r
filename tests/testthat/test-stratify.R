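test_that("confusion accuracy identities hold", {
  expect_equal(confusion_accuracy(matrix(c(10, 0, 0, 10), 2)), 1)
  expect_equal(confusion_accuracy(matrix(c(0, 5, 5, 0), 2)), 0)
  cm <- confusion_matrix(c(0, 0, 1, 1), c(0, 1, 1, 1))
  expect_equal(cm["0", "1"], 1)
  expect_equal(confusion_accuracy(cm), 0.75)
  expect_error(confusion_accuracy(matrix(0, 2, 2)), "empty")
})

test_that("uni-variate stratification is internally consistent", {
  pm <- noise_phene_matrix(n = 30, n_cand = 3, seed = 44)
  pm$oracle <- pm$event + withr::with_seed(45, stats::rnorm(30, 0, 1e-4))
  res <- univariate_stratify(pm, "oracle")
  expect_equal(res$accuracy, 1)
  expect_equal(res$confusion["0", "1"] + res$confusion["1", "0"], 0)
  # accuracy recomputes from the confusion matrix
  expect_equal(res$accuracy, confusion_accuracy(res$confusion))
  # one prediction per patient
  expect_equal(nrow(res$predictions), 30)
  expect_true(all(!is.na(res$predictions$pred)))
  # a noise phene still yields a complete, consistent result
  res2 <- univariate_stratify(pm, "#CD8_border1")
  ok <- !is.na(res2$predictions$pred)
  expect_equal(res2$accuracy,
               mean(res2$predictions$pred[ok] ==
                      res2$predictions$truth[ok]))
})

test_that("clustering recovers separated profiles and its distance identities", {
  withr::with_seed(50, {
    n <- 30
    y <- rep(c(0, 1), each = 15)
    pm <- tibble::tibble(patient_id = sprintf("S%02d", 1:n),
                         dfs_months = stats::runif(n, 2, 118),
                         event = y)
    # two well-separated blobs aligned with the labels, opposite signs so
    # patient profiles are anti-correlated between classes
    for (j in 1:4) {
      pm[[paste0("#CD8_border", j)]] <-
        (2 * y - 1) * c(3, -3, 2.5, -2.5)[j] + stats::rnorm(n, 0, 0.3)
    }
    res <- cluster_stratify(pm, paste0("#CD8_border", 1:4))
    expect_equal(res$accuracy, 1)
    # z-scoring leaves each used column with mean 0 and unit variance
    Z <- scale(as.matrix(pm[paste0("#CD8_border", 1:4)]))
    expect_true(all(abs(colMeans(Z)) < 1e-12))
    expect_true(all(abs(apply(Z, 2, sd) - 1) < 1e-12))
    # 1 - Pearson distance: self = 0, exact negation = 2
    prof <- Z[1, ]
    expect_equal(1 - cor(prof, prof), 0)
    expect_equal(1 - cor(prof, -prof), 2)
  })
})

test_that("zero-variance phenes are dropped from clustering with a warning", {
  pm <- noise_phene_matrix(n = 20, n_cand = 3, seed = 51)
  pm$flat <- 5
  expect_warning(res <- cluster_stratify(pm, c("#CD8_border1",
                                               "#CD8_border2", "flat")),
                 "zero-variance")
  expect_s3_class(res, "stratification_result")
})

test_that("supervised methods honour the LOOCV contract", {
  withr::with_seed(52, {
    n <- 24
    y <- rep(c(0, 1), each = 12)
    pm <- tibble::tibble(patient_id = sprintf("S%02d", 1:n),
                         dfs_months = stats::runif(n, 2, 118),
                         event = y)
    pm$f1 <- (2 * y - 1) * 2 + stats::rnorm(n, 0, 0.2)  # wide margin
    pm$f2 <- stats::rnorm(n)
    for (m in c("bayes", "cart_depth2", "knn5", "linear", "svm_linear",
                "svm_rbf")) {
      res <- supervised_stratify(pm, c("f1", "f2"), method = m)
      expect_equal(nrow(res$predictions), n, info = m)
      expect_true(all(!is.na(res$predictions$pred)), info = m)
      expect_equal(res$accuracy, confusion_accuracy(res$confusion),
                   info = m)
    }
    # linearly separable with margin: the linear SVM is perfect
    res <- supervised_stratify(pm, c("f1", "f2"), method = "svm_linear")
    expect_equal(res$accuracy, 1)
  })
  expect_error(supervised_stratify(noise_phene_matrix(20, 2, seed = 1),
                                   "#CD8_border1", method = "nope"))
})

test_that("knn predictions match a brute-force majority vote", {
  withr::with_seed(53, {
    n <- 12
    y <- rep(c(0, 1), 6)
    pm <- tibble::tibble(patient_id = sprintf("S%02d", 1:n),
                         dfs_months = stats::runif(n, 2, 118),
                         event = y)
    pm$f1 <- stats::rnorm(n); pm$f2 <- stats::rnorm(n)
    res <- supervised_stratify(pm, c("f1", "f2"), method = "knn5")
    X <- as.matrix(pm[c("f1", "f2")])
    for (i in seq_len(n)) {
      tr <- setdiff(seq_len(n), i)
      mu <- colMeans(X[tr, ]); sg <- apply(X[tr, ], 2, sd)
      ztr <- sweep(sweep(X[tr, ], 2, mu), 2, sg, "/")
      zte <- (X[i, ] - mu) / sg
      d <- sqrt(colSums((t(ztr) - zte)^2))
      vote <- y[tr][order(d)[1:5]]
      if (mean(vote) != 0.5) {  # class::knn breaks exact ties at random
        expect_equal(res$predictions$pred[i], as.integer(mean(vote) > 0.5))
      }
    }
  })
})
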
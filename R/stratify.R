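#' Confusion matrix and accuracy
#'
#' `confusion_matrix()` tabulates true vs predicted class (rows = true,
#' columns = predicted; 0 = non-progression, 1 = progression);
#' `confusion_accuracy()` returns the fraction of correctly classified
#' patients, `(TN + TP) / total`.
#'
#' @param truth,pred Binary class vectors (0/1).
#' @param cm A 2x2 confusion matrix.
#' @return `confusion_matrix()`: a 2x2 matrix; `confusion_accuracy()`: a
#'   fraction in `[0, 1]`.
#' @examples
#' cm <- matrix(c(38, 3, 12, 37), 2, dimnames = list(true = 0:1, pred = 0:1))
#' confusion_accuracy(cm)  # (38 + 37) / 90
#' @export
confusion_matrix <- function(truth, pred) {
  tab <- table(factor(truth, levels = c(0, 1)),
               factor(pred, levels = c(0, 1)))
  m <- matrix(as.numeric(tab), 2, 2,
              dimnames = list(true = c("0", "1"), pred = c("0", "1")))
  m
}

#' @rdname confusion_matrix
#' @export
confusion_accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) abort("empty confusion matrix")
  (cm[1, 1] + cm[2, 2]) / total
}

# assemble a stratification result from aggregated predictions
make_stratification_result <- function(method, phenes, pred, extra = list()) {
  ok <- !is.na(pred)
  truth <- phenes$event
  cm <- confusion_matrix(truth[ok], pred[ok])
  acc <- confusion_accuracy(cm)
  surv <- phenes[, c("patient_id", "dfs_months", "event")]
  p <- if (length(unique(pred[ok])) == 2) {
    logrank_test(surv[ok, ], pred[ok])$p.value
  } else NA_real_
  km <- lapply(split(surv[ok, ], pred[ok]), km_curve)
  structure(c(list(
    method = method,
    predictions = tibble::tibble(patient_id = phenes$patient_id,
                                 truth = truth, pred = pred),
    accuracy = acc, logrank_p = p, confusion = cm, km = km
  ), extra), class = "stratification_result")
}

#' Uni-variate threshold stratification
#'
#' Leave-one-out cross-validation of a single phene: per fold the
#' threshold model is optimized on the training patients
#' ([optimize_threshold()]) and the held-out patient is classified
#' non-progression when `value OP threshold`; the aggregated out-of-fold
#' predictions yield the accuracy, log-rank p-value, confusion matrix and
#' per-group Kaplan-Meier curves.
#'
#' @param phenes A phene matrix tibble.
#' @param phene Name of the phene column to stratify on.
#' @return A `stratification_result`.
#' @export
univariate_stratify <- function(phenes, phene) {
  check_survival_table(phenes)
  if (!phene %in% phene_cols(phenes)) abort(paste0("unknown phene: ", phene))
  v <- phenes[[phene]]
  n <- nrow(phenes)
  pred <- rep(NA_integer_, n)
  any_model <- FALSE
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    m <- optimize_threshold_core(v[tr], phenes$dfs_months[tr],
                                 phenes$event[tr])
    if (!m$unrankable && !is.na(v[i])) {
      any_model <- TRUE
      pred[i] <- predict_threshold(m$operator, m$threshold, v[i])
    }
  }
  if (!any_model) abort(paste0("phene is unrankable: ", phene))
  make_stratification_result(paste0("univariate:", phene), phenes, pred)
}

#' Unsupervised stratification by hierarchical clustering
#'
#' Z-scores the selected phene columns (zero-variance columns are dropped
#' with a warning), clusters patients bottom-up with distance
#' 1 - Pearson correlation between patient profiles (average linkage) and
#' cuts the tree after the top-most branching into two clusters. The two
#' clusters are mapped to progression / non-progression by majority true
#' label -- an evaluation-time mapping only; no cross-validation is used
#' since clustering never sees the labels, but the mapping makes the
#' reported accuracy optimistic relative to the supervised results.
#'
#' @param phenes A phene matrix tibble.
#' @param subset Phene names to cluster on (>= 2).
#' @return A `stratification_result` (with `cluster` assignments in
#'   `predictions`).
#' @export
cluster_stratify <- function(phenes, subset) {
  check_survival_table(phenes)
  subset <- intersect(subset, phene_cols(phenes))
  X <- as.matrix(phenes[subset])
  sds <- apply(X, 2, sd, na.rm = TRUE)
  if (any(sds == 0 | is.na(sds))) {
    warn(paste0("dropping zero-variance phene(s): ",
                paste(subset[sds == 0 | is.na(sds)], collapse = ", ")))
    X <- X[, sds > 0 & !is.na(sds), drop = FALSE]
  }
  if (ncol(X) < 2) abort("need at least two informative phenes")
  Z <- scale(X)
  Z[is.na(Z)] <- 0  # missing values sit at the column mean after z-scoring
  D <- as.dist(1 - cor(t(Z)))
  cl <- cutree(hclust(D, method = "average"), k = 2)
  # majority-truth mapping of the two main clusters
  mean1 <- mean(phenes$event[cl == 1]); mean2 <- mean(phenes$event[cl == 2])
  pred <- if (mean1 >= mean2) as.integer(cl == 1) else as.integer(cl == 2)
  make_stratification_result("hierarchical_clustering", phenes, pred,
                             extra = list(cluster = cl))
}

#' Supervised multi-variate stratification
#'
#' Leave-one-out cross-validation of a multi-variate classifier on the
#' selected phenes, with the binary event flag as target. Features are
#' z-scored with fold-training statistics only (no leakage); missing
#' values are imputed at the training mean (0 after z-scoring). Methods:
#' Gaussian naive Bayes, CART (depth 2, Gini, minimum leaf 5), k-nearest
#' neighbours (k = 5), a least-squares linear predictor thresholded at
#' 0.5, and support vector machines with linear or radial basis function
#' kernel (cost 1; RBF bandwidth from the median pairwise training
#' distance).
#'
#' @param phenes A phene matrix tibble.
#' @param subset Phene names to use as features.
#' @param method One of `"bayes"`, `"cart_depth2"`, `"knn5"`, `"linear"`,
#'   `"svm_linear"`, `"svm_rbf"`.
#' @return A `stratification_result`.
#' @export
supervised_stratify <- function(phenes, subset,
                                method = c("bayes", "cart_depth2", "knn5",
                                           "linear", "svm_linear",
                                           "svm_rbf")) {
  method <- match.arg(method)
  check_survival_table(phenes)
  subset <- intersect(subset, phene_cols(phenes))
  if (length(subset) < 1) abort("no phenes to stratify on")
  X <- as.matrix(phenes[subset])
  y <- phenes$event
  n <- nrow(X)
  pred <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (length(unique(y[tr])) < 2) abort("a training fold has a single class")
    mu <- colMeans(X[tr, , drop = FALSE], na.rm = TRUE)
    sg <- apply(X[tr, , drop = FALSE], 2, sd, na.rm = TRUE)
    sg[sg == 0 | is.na(sg)] <- 1
    ztr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sg, "/")
    zte <- (X[i, ] - mu) / sg
    ztr[is.na(ztr)] <- 0; zte[is.na(zte)] <- 0
    pred[i] <- fit_predict_one(method, ztr, y[tr], zte)
  }
  make_stratification_result(method, phenes, pred)
}

fit_predict_one <- function(method, ztr, ytr, zte) {
  df_tr <- as.data.frame(ztr)
  names(df_tr) <- paste0("x", seq_len(ncol(ztr)))
  df_te <- as.data.frame(t(zte))
  names(df_te) <- names(df_tr)
  yf <- factor(ytr, levels = c(0, 1))
  switch(method,
    bayes = {
      fit <- e1071::naiveBayes(df_tr, yf)
      as.integer(as.character(predict(fit, df_te)))
    },
    cart_depth2 = {
      ctl <- rpart::rpart.control(maxdepth = 2, minbucket = 5, minsplit = 10,
                                  cp = 0, xval = 0, maxsurrogate = 0,
                                  maxcompete = 0)
      fit <- rpart::rpart(y ~ ., data = cbind(df_tr, y = yf),
                          method = "class", control = ctl)
      as.integer(as.character(predict(fit, df_te, type = "class")))
    },
    knn5 = {
      as.integer(as.character(
        class::knn(df_tr, df_te, yf, k = min(5L, nrow(df_tr)))))
    },
    linear = {
      fit <- lm(y ~ ., data = cbind(df_tr, y = as.numeric(ytr)))
      as.integer(predict(fit, df_te) >= 0.5)
    },
    svm_linear = {
      fit <- e1071::svm(df_tr, yf, kernel = "linear", cost = 1, scale = FALSE)
      as.integer(as.character(predict(fit, df_te)))
    },
    svm_rbf = {
      d <- dist(ztr)
      med <- median(d[d > 0])
      if (!is.finite(med) || med == 0) med <- 1
      fit <- e1071::svm(df_tr, yf, kernel = "radial", cost = 1,
                        gamma = 1 / (2 * med^2), scale = FALSE)
      as.integer(as.character(predict(fit, df_te)))
    }
  )
}

#' @export
print.stratification_result <- function(x, ...) {
  cat("<stratification_result> ", x$method, ": accuracy ",
      round(x$accuracy, 3), ", log-rank p ",
      signif(x$logrank_p, 3), "\n", sep = "")
  print(x$confusion)
  invisible(x)
}

#' @exportS3Method
tidy.stratification_result <- function(x, ...) x$predictions

#' @exportS3Method
glance.stratification_result <- function(x, ...) {
  tibble::tibble(method = x$method, accuracy = x$accuracy,
                 logrank_p = x$logrank_p,
                 n = sum(!is.na(x$predictions$pred)),
                 tn = x$confusion[1, 1], fp = x$confusion[1, 2],
                 fn = x$confusion[2, 1], tp = x$confusion[2, 2])
}

#' @exportS3Method
autoplot.stratification_result <- function(object, ...) {
  df <- dplyr::bind_rows(lapply(names(object$km), function(g) {
    k <- object$km[[g]]
    tibble::tibble(group = g, time = c(0, k$time), surv = c(1, k$surv))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(title = object$method,
                  x = "disease-free survival time (months)",
                  y = "survival probability",
                  colour = "predicted group")
}
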
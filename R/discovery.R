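#' Survival cutpoint optimization for one phene candidate
#'
#' Scans candidate thresholds -- midpoints of consecutive sorted unique
#' values restricted to the closed interval between the medians of the two
#' event classes -- and, for each threshold and operator direction,
#' computes the log-rank p-value of the induced two-group split and the
#' classification accuracy (a patient is classified non-progression when
#' `value OP threshold`; the binary event flag is the class label, so
#' censored patients count as non-progression). The returned model
#' maximizes the classification accuracy, with ties broken by the smaller
#' log-rank p-value, then by the smaller threshold. (A pure minimum-p rule
#' systematically prefers splitting off the few earliest events -- under
#' perfect separation it never selects the separating threshold -- so
#' accuracy leads and the p-value arbitrates among equally accurate
#' cutpoints.)
#'
#' @param values Numeric candidate values, aligned with `outcomes` rows;
#'   missing entries are excluded pairwise.
#' @param outcomes Survival table (`patient_id`, `dfs_months`, `event`).
#' @param layout Optional precomputed [survival_layout()] of the complete
#'   cases (internal fast path).
#' @return A one-row tibble of class `threshold_model`: `operator`
#'   (`">="` or `"<"`), `threshold`, `train_accuracy`, `train_logrank_p`,
#'   `n_used`, `unrankable`. When no valid threshold exists (one event
#'   class absent, all values identical, equal class medians, or no
#'   midpoint between the medians) the model is flagged `unrankable` with
#'   `NA` estimates.
#' @examples
#' out <- data.frame(patient_id = 1:6, dfs_months = c(4, 6, 8, 60, 70, 80),
#'                   event = c(1, 1, 1, 0, 0, 0))
#' optimize_threshold(c(1, 2, 3, 10, 11, 12), out)
#' @export
optimize_threshold <- function(values, outcomes, layout = NULL) {
  res <- optimize_threshold_core(values, outcomes$dfs_months,
                                 outcomes$event, layout = layout)
  out <- tibble::tibble(operator = res$operator, threshold = res$threshold,
                        train_accuracy = res$train_accuracy,
                        train_logrank_p = res$train_logrank_p,
                        n_used = res$n_used, unrankable = res$unrankable)
  class(out) <- c("threshold_model", class(out))
  out
}

# allocation-light scan used in the cross-validation / permutation loops
optimize_threshold_core <- function(values, time, event, layout = NULL) {
  keep <- !is.na(values)
  v <- values[keep]
  ev <- event[keep]
  unrankable <- list(operator = NA_character_, threshold = NA_real_,
                     train_accuracy = NA_real_, train_logrank_p = NA_real_,
                     n_used = length(v), unrankable = TRUE)
  if (length(v) < 2 || length(unique(ev)) < 2) return(unrankable)
  rng <- range(v)
  if (rng[1] == rng[2]) return(unrankable)
  med <- c(median(v[ev == 1]), median(v[ev == 0]))
  if (med[1] == med[2]) return(unrankable)
  uv <- sort(unique(v))
  mids <- (uv[-1] + uv[-length(uv)]) / 2
  lohi <- sort(med)
  thr <- mids[mids >= lohi[1] & mids <= lohi[2]]
  if (length(thr) == 0) return(unrankable)

  if (is.null(layout)) {
    layout <- survival_layout(time[keep], ev)
  }
  G <- outer(v, thr, `>=`) * 1
  sc <- logrank_scan(layout, G)
  # accuracy of ">=": predicted progression when value < threshold
  acc_ge <- colMeans(ev * (1 - G) + (1 - ev) * G)
  op <- ifelse(acc_ge >= 1 - acc_ge, ">=", "<")
  acc <- pmax(acc_ge, 1 - acc_ge)
  best <- order(-acc, sc$p, thr)[1]
  list(operator = op[best], threshold = thr[best],
       train_accuracy = acc[best], train_logrank_p = sc$p[best],
       n_used = length(v), unrankable = FALSE)
}

# apply a threshold model: 1 = progression, 0 = non-progression
predict_threshold <- function(operator, threshold, values) {
  nonprog <- if (operator == ">=") values >= threshold else values < threshold
  as.integer(!nonprog)
}

#' Leave-one-out cross-validated phene ranking
#'
#' For each of the n leave-one-out folds, every candidate's threshold is
#' optimized on the n-1 training patients; candidates are ranked within
#' the fold by training accuracy (ties by training p-value) and their
#' membership of the fold's top 5 recorded; the held-out patient is
#' classified with the fold's model. Per candidate the n out-of-fold
#' predictions are aggregated into a cross-validated accuracy, a log-rank
#' p-value on the predicted groups, a top-5 robustness count, the mean
#' threshold and the majority operator direction across folds. The final
#' ranking orders by cv accuracy (descending), top-5 count (descending),
#' then cv p-value (ascending); unrankable candidates come last.
#'
#' Candidates missing in more than `max_missing` of patients are dropped
#' before ranking.
#'
#' @param phenes A phene matrix tibble ([build_phene_matrix()]): columns
#'   `patient_id`, `dfs_months`, `event` plus one column per candidate.
#' @param max_missing Maximum tolerated fraction of missing values per
#'   candidate (default 0.2).
#' @return A tibble of class `phene_ranking`: `phene`, `operator`,
#'   `mean_threshold`, `cv_accuracy`, `cv_logrank_p`, `top5_count`,
#'   `n_folds`, `unrankable`, `rank`. The n-by-candidates matrix of
#'   out-of-fold predictions is attached as attribute `"predictions"`.
#' @export
loocv_rank <- function(phenes, max_missing = 0.2) {
  check_survival_table(phenes)
  cols <- phene_cols(phenes)
  miss <- vapply(phenes[cols], function(x) mean(is.na(x)), numeric(1))
  dropped <- cols[miss > max_missing]
  if (length(dropped) > 0) {
    inform(paste0(length(dropped), " candidate(s) dropped (>",
                  round(100 * max_missing), "% missing)"))
    cols <- setdiff(cols, dropped)
  }
  n <- nrow(phenes)
  C <- length(cols)
  if (n < 4 || min(table(phenes$event)) < 2) {
    abort("need at least two patients per event class")
  }
  V <- as.matrix(phenes[cols])
  time <- phenes$dfs_months; ev <- phenes$event

  pred <- matrix(NA_integer_, n, C, dimnames = list(NULL, cols))
  thr_sum <- numeric(C); thr_n <- integer(C)
  op_ge <- integer(C)
  top5 <- integer(C)
  rankable_folds <- integer(C)

  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    layout_tr <- survival_layout(time[tr], ev[tr])
    acc_f <- rep(NA_real_, C); p_f <- rep(NA_real_, C)
    for (jc in seq_len(C)) {
      vals <- V[tr, jc]
      m <- optimize_threshold_core(vals, time[tr], ev[tr],
                                   layout = if (anyNA(vals)) NULL else layout_tr)
      if (!m$unrankable) {
        acc_f[jc] <- m$train_accuracy
        p_f[jc] <- m$train_logrank_p
        thr_sum[jc] <- thr_sum[jc] + m$threshold
        thr_n[jc] <- thr_n[jc] + 1L
        op_ge[jc] <- op_ge[jc] + (m$operator == ">=")
        rankable_folds[jc] <- rankable_folds[jc] + 1L
        if (!is.na(V[i, jc])) {
          pred[i, jc] <- predict_threshold(m$operator, m$threshold, V[i, jc])
        }
      }
    }
    ok <- which(!is.na(acc_f))
    if (length(ok) > 0) {
      ord <- ok[order(-acc_f[ok], p_f[ok])]
      top <- head(ord, 5L)
      top5[top] <- top5[top] + 1L
    }
  }

  cv_acc <- vapply(seq_len(C), function(jc) {
    ok <- !is.na(pred[, jc])
    if (!any(ok)) NA_real_ else mean(pred[ok, jc] == ev[ok])
  }, numeric(1))
  cv_p <- vapply(seq_len(C), function(jc) {
    ok <- !is.na(pred[, jc])
    if (sum(ok) < 2 || length(unique(pred[ok, jc])) < 2) return(NA_real_)
    logrank_test(phenes[ok, c("patient_id", "dfs_months", "event")],
                 pred[ok, jc])$p.value
  }, numeric(1))

  out <- tibble::tibble(
    phene = cols,
    operator = ifelse(rankable_folds == 0, NA_character_,
                      ifelse(op_ge >= rankable_folds / 2, ">=", "<")),
    mean_threshold = ifelse(thr_n > 0, thr_sum / thr_n, NA_real_),
    cv_accuracy = cv_acc,
    cv_logrank_p = cv_p,
    top5_count = top5,
    n_folds = n,
    unrankable = rankable_folds == 0
  )
  ord <- order(out$unrankable, -out$cv_accuracy, -out$top5_count,
               out$cv_logrank_p, out$phene)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  attr(out, "predictions") <- pred[, ord, drop = FALSE]
  attr(out, "dropped") <- dropped
  class(out) <- c("phene_ranking", class(out))
  out
}

#' Permutation null for the phene ranking
#'
#' Shuffles the patient-to-outcome alignment `n_perm` times; after each
#' shuffle every candidate's threshold is optimized on the full permuted
#' data (no cross-validation, matching how the observed training ranking
#' is built) and the top-ranked candidate's accuracy and p-value are
#' recorded. Per observed candidate, the empirical p-value is
#' `(1 + #{permutations with top accuracy >= observed accuracy}) /
#' (n_perm + 1)`, so it never falls below the add-one bound.
#'
#' @inheritParams loocv_rank
#' @param n_perm Number of permutations (default 100).
#' @param seed Optional seed for the shuffles.
#' @return A list of class `permutation_null`: `top_accuracy` and `top_p`
#'   (length `n_perm`), `observed` (tibble with each candidate's full-data
#'   training accuracy and empirical p), `n_perm`.
#' @export
permutation_null <- function(phenes, n_perm = 100, seed = NULL,
                             max_missing = 0.2) {
  check_survival_table(phenes)
  cols <- phene_cols(phenes)
  miss <- vapply(phenes[cols], function(x) mean(is.na(x)), numeric(1))
  cols <- cols[miss <= max_missing]
  V <- as.matrix(phenes[cols])
  outc <- phenes[, c("patient_id", "dfs_months", "event")]
  n <- nrow(phenes)

  scan_all <- function(perm) {
    time_p <- outc$dfs_months[perm]; ev_p <- outc$event[perm]
    layout_p <- survival_layout(time_p, ev_p)
    acc <- rep(NA_real_, length(cols)); p <- rep(NA_real_, length(cols))
    for (jc in seq_along(cols)) {
      m <- optimize_threshold_core(V[, jc], time_p, ev_p,
                                   layout = if (anyNA(V[, jc])) NULL else layout_p)
      if (!m$unrankable) {
        acc[jc] <- m$train_accuracy; p[jc] <- m$train_logrank_p
      }
    }
    list(acc = acc, p = p)
  }

  obs <- scan_all(seq_len(n))
  perms <- with_seed(seed, {
    lapply(seq_len(n_perm), function(b) scan_all(sample.int(n)))
  })
  top_of <- function(s) {
    ok <- which(!is.na(s$acc))
    if (length(ok) == 0) return(c(NA_real_, NA_real_))
    j <- ok[order(-s$acc[ok], s$p[ok])][1]
    c(s$acc[j], s$p[j])
  }
  tops <- vapply(perms, top_of, numeric(2))
  top_accuracy <- tops[1, ]; top_p <- tops[2, ]

  emp_p <- vapply(obs$acc, function(a) {
    if (is.na(a)) return(NA_real_)
    (1 + sum(top_accuracy >= a, na.rm = TRUE)) / (n_perm + 1)
  }, numeric(1))

  structure(list(
    top_accuracy = top_accuracy, top_p = top_p,
    observed = tibble::tibble(phene = cols,
                              observed_accuracy = obs$acc,
                              observed_p = obs$p,
                              empirical_p = emp_p),
    n_perm = n_perm
  ), class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat("<permutation_null> ", x$n_perm, " shuffles; top accuracy mean ",
      round(mean(x$top_accuracy, na.rm = TRUE), 3), " (sd ",
      round(sd(x$top_accuracy, na.rm = TRUE), 3), ")\n", sep = "")
  invisible(x)
}

#' @exportS3Method
tidy.permutation_null <- function(x, ...) x$observed

#' @exportS3Method
glance.permutation_null <- function(x, ...) {
  tibble::tibble(n_perm = x$n_perm,
                 mean_top_accuracy = mean(x$top_accuracy, na.rm = TRUE),
                 sd_top_accuracy = sd(x$top_accuracy, na.rm = TRUE),
                 mean_top_p = mean(x$top_p, na.rm = TRUE),
                 sd_top_p = sd(x$top_p, na.rm = TRUE))
}

#' @exportS3Method
tidy.phene_ranking <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @exportS3Method
autoplot.phene_ranking <- function(object, top_n = 20, ...) {
  df <- head(tibble::as_tibble(object), top_n)
  df$phene <- factor(df$phene, levels = rev(df$phene))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cv_accuracy, y = .data$phene)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "cross-validated accuracy", y = NULL)
}
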
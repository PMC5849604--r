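#' Remove poor-performing candidates
#'
#' Drops candidates whose cross-validated accuracy is at or below the
#' floor (default 50%: no better than guessing), together with unrankable
#' candidates. Every removal is logged.
#'
#' @param ranking A `phene_ranking` from [loocv_rank()].
#' @param floor Accuracy floor; candidates with `cv_accuracy <= floor` are
#'   removed (strict `<=`).
#' @return The reduced ranking, with a tibble of removals (`phene`,
#'   `stage`, `reason`) in attribute `"removed"`.
#' @export
accuracy_filter <- function(ranking, floor = 0.5) {
  drop <- is.na(ranking$cv_accuracy) | ranking$cv_accuracy <= floor
  removed <- tibble::tibble(
    phene = as.character(ranking$phene[drop]),
    stage = rep("accuracy_filter", sum(drop)),
    reason = ifelse(is.na(ranking$cv_accuracy[drop]), "unrankable",
                    paste0("cv_accuracy <= ", floor))
  )
  removed$reason <- as.character(removed$reason)
  out <- ranking[!drop, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Decorrelate the candidate pool
#'
#' Walks the candidates in rank order and drops any candidate whose
#' absolute Pearson correlation with an already-kept candidate reaches the
#' maximum allowed absolute correlation (default 0.75), keeping the
#' higher-ranked member of each correlated pair. Zero-variance columns are
#' treated as correlation 0 (kept, flagged).
#'
#' @param phenes The phene matrix the ranking was computed on.
#' @param ranking A (possibly filtered) `phene_ranking`.
#' @param max_abs_corr Removal threshold on `|r|` (default 0.75;
#'   candidates with `|r| >= max_abs_corr` to a kept one are removed).
#' @return The reduced ranking; removals (with the blocking partner named)
#'   in attribute `"removed"`.
#' @export
correlation_filter <- function(phenes, ranking, max_abs_corr = 0.75) {
  kept <- character(0)
  removed <- list()
  flagged <- character(0)
  for (i in seq_len(nrow(ranking))) {
    ph <- ranking$phene[i]
    v <- phenes[[ph]]
    if (sd(v, na.rm = TRUE) == 0 || all(is.na(v))) {
      flagged <- c(flagged, ph)
      kept <- c(kept, ph)  # zero variance: correlation 0 by convention
      next
    }
    blocker <- NA_character_
    for (kp in kept) {
      r <- suppressWarnings(cor(v, phenes[[kp]],
                                use = "pairwise.complete.obs"))
      if (!is.na(r) && abs(r) >= max_abs_corr) { blocker <- kp; break }
    }
    if (is.na(blocker)) {
      kept <- c(kept, ph)
    } else {
      removed[[length(removed) + 1L]] <- tibble::tibble(
        phene = ph, stage = "correlation_filter",
        reason = paste0("|r| >= ", max_abs_corr, " with ", blocker))
    }
  }
  out <- ranking[ranking$phene %in% kept, , drop = FALSE]
  attr(out, "removed") <- dplyr::bind_rows(removed)
  attr(out, "zero_variance") <- flagged
  out
}

#' Multiple-testing correction
#'
#' Flags significant candidates under Holm-Bonferroni step-down (FWER),
#' single-step Bonferroni (FWER) or Benjamini-Hochberg step-up (FDR)
#' control at level `alpha`, and reports the effective corrected level:
#' the per-comparison threshold at which the chosen procedure stopped.
#'
#' @param pvals Numeric p-values in `[0, 1]` (`NA` allowed, never
#'   significant).
#' @param method `"holm_bonferroni"`, `"bonferroni"` or
#'   `"benjamini_hochberg"`.
#' @param alpha Family-wise / false-discovery level (default 0.05).
#' @return A tibble with `p.value`, `p.adjusted`, `significant`, plus the
#'   scalar attribute `"alpha_corr"`.
#' @export
multiple_testing_correct <- function(pvals,
                                     method = c("holm_bonferroni",
                                                "bonferroni",
                                                "benjamini_hochberg"),
                                     alpha = 0.05) {
  method <- match.arg(method)
  if (length(pvals) == 0) {
    out <- tibble::tibble(p.value = numeric(), p.adjusted = numeric(),
                          significant = logical())
    attr(out, "alpha_corr") <- alpha
    return(out)
  }
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  radj <- switch(method, holm_bonferroni = "holm",
                 bonferroni = "bonferroni", benjamini_hochberg = "BH")
  padj <- p.adjust(pvals, method = radj)
  sig <- !is.na(padj) & padj < alpha
  m <- sum(!is.na(pvals))
  k <- sum(sig)
  alpha_corr <- switch(method,
    bonferroni = alpha / m,
    holm_bonferroni = alpha / (m - k + 1),  # level of the first retained test
    benjamini_hochberg = if (k > 0) k * alpha / m else alpha / m
  )
  out <- tibble::tibble(p.value = pvals, p.adjusted = padj,
                        significant = sig)
  attr(out, "alpha_corr") <- alpha_corr
  out
}

#' CART selection-frequency subset selection
#'
#' Runs leave-one-out cross-validation in which each fold trains a
#' depth-limited classification tree (Gini splits, minimum leaf size 5)
#' on the binary event labels over the supplied phenes, and counts per
#' phene how many folds selected it at any split node. Phenes never
#' selected get count 0 and are excluded from the returned subset.
#'
#' @param phenes Phene matrix restricted (by `subset`) to the significant
#'   candidates.
#' @param subset Character vector of phene names to offer to the trees.
#' @param depth Maximum tree depth (default 2: at most 3 split nodes).
#' @param min_leaf Minimum observations per leaf (default 5).
#' @return A tibble `phene`, `cart_count` (folds selected, descending),
#'   restricted to phenes with count >= 1; the number of usable folds in
#'   attribute `"n_folds"`, skipped degenerate folds in `"skipped"`.
#' @export
cart_subset_selection <- function(phenes, subset, depth = 2, min_leaf = 5) {
  check_survival_table(phenes)
  subset <- intersect(subset, phene_cols(phenes))
  if (length(subset) < 2) abort("need at least two candidate phenes")
  X <- as.data.frame(phenes[subset])
  safe <- paste0("x", seq_along(subset))
  names(X) <- safe
  X$.y <- factor(phenes$event, levels = c(0, 1))
  n <- nrow(X)
  counts <- setNames(integer(length(subset)), subset)
  skipped <- 0L
  ctl <- rpart::rpart.control(maxdepth = depth, minbucket = min_leaf,
                              minsplit = 2 * min_leaf, cp = 0, xval = 0,
                              maxsurrogate = 0, maxcompete = 0)
  for (i in seq_len(n)) {
    tr <- X[-i, , drop = FALSE]
    if (length(unique(tr$.y)) < 2) { skipped <- skipped + 1L; next }
    fit <- rpart::rpart(.y ~ ., data = tr, method = "class", control = ctl)
    used <- setdiff(unique(as.character(fit$frame$var)), "<leaf>")
    counts[subset[match(used, safe)]] <-
      counts[subset[match(used, safe)]] + 1L
  }
  out <- tibble::tibble(phene = names(counts), cart_count = unname(counts))
  out <- out[out$cart_count > 0, , drop = FALSE]
  out <- out[order(-out$cart_count, out$phene), ]
  attr(out, "n_folds") <- n - skipped
  attr(out, "skipped") <- skipped
  out
}

#' Full phene selection pipeline
#'
#' Applies, in fixed order: the accuracy filter, the correlation filter,
#' multiple-testing correction of the cross-validated log-rank p-values,
#' and (when at least two candidates survive) CART selection-frequency
#' subset selection.
#'
#' @inheritParams correlation_filter
#' @inheritParams multiple_testing_correct
#' @inheritParams accuracy_filter
#' @inheritParams cart_subset_selection
#' @return A list of class `phene_selection`: `significant` (ranking rows
#'   of the significant set with adjusted p-values), `cart_counts`,
#'   `removed` (full removal log across stages), `alpha_corr`, `method`,
#'   `alpha`.
#' @export
select_phenes <- function(phenes, ranking, floor = 0.5, max_abs_corr = 0.75,
                          method = "holm_bonferroni", alpha = 0.05,
                          depth = 2, min_leaf = 5) {
  st1 <- accuracy_filter(ranking, floor = floor)
  st2 <- correlation_filter(phenes, st1, max_abs_corr = max_abs_corr)
  removed <- dplyr::bind_rows(attr(st1, "removed"), attr(st2, "removed"))
  mtc <- multiple_testing_correct(st2$cv_logrank_p, method = method,
                                  alpha = alpha)
  sig <- dplyr::bind_cols(
    tibble::as_tibble(st2)[, c("phene", "operator", "mean_threshold",
                               "cv_accuracy", "cv_logrank_p", "top5_count",
                               "rank")],
    mtc[, c("p.adjusted", "significant")]
  )
  removed <- dplyr::bind_rows(removed, tibble::tibble(
    phene = sig$phene[!sig$significant],
    stage = "multiple_testing",
    reason = paste0("adjusted p >= ", alpha)))
  sig <- sig[sig$significant, , drop = FALSE]
  cart <- NULL
  if (nrow(sig) >= 2) {
    cart <- cart_subset_selection(phenes, sig$phene, depth = depth,
                                  min_leaf = min_leaf)
  }
  structure(list(significant = sig, cart_counts = cart, removed = removed,
                 alpha_corr = attr(mtc, "alpha_corr"),
                 method = method, alpha = alpha),
            class = "phene_selection")
}

#' @export
print.phene_selection <- function(x, ...) {
  cat("<phene_selection> ", nrow(x$significant), " significant phene(s) (",
      x$method, ", alpha ", x$alpha, "); ",
      if (is.null(x$cart_counts)) 0L else nrow(x$cart_counts),
      " CART-selected\n", sep = "")
  invisible(x)
}

#' @exportS3Method
tidy.phene_selection <- function(x, ...) {
  out <- x$significant
  if (!is.null(x$cart_counts)) {
    out <- dplyr::left_join(out, x$cart_counts, by = "phene")
    out$cart_count[is.na(out$cart_count)] <- 0L
  }
  out
}

#' @exportS3Method
glance.phene_selection <- function(x, ...) {
  tibble::tibble(n_significant = nrow(x$significant),
                 n_cart_selected = if (is.null(x$cart_counts)) 0L else
                   nrow(x$cart_counts),
                 n_removed = nrow(x$removed),
                 alpha = x$alpha, alpha_corr = x$alpha_corr,
                 method = x$method)
}
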
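#' Run the full discovery pipeline
#'
#' Orchestrates simulate -> dataficate/candidates -> rank -> permute ->
#' select -> stratify on a synthetic cohort, with one global seed fanned
#' out into independent per-stage streams and a manifest of content
#' digests for reproducibility (same config + seed gives identical
#' digests).
#'
#' @param config A [cohort_config()].
#' @param grammar A [phene_grammar()] defining the candidate pool.
#' @param seed Global integer seed.
#' @param n_perm Permutations for the null (default 100).
#' @param alpha,method Multiple-testing level and procedure
#'   (see [select_phenes()]).
#' @param stratify_methods Supervised methods to evaluate on the selected
#'   set (see [supervised_stratify()]); clustering is always included when
#'   at least two phenes are selected.
#' @param cohort Optionally, a precomputed `synthetic_cohort` (the
#'   simulate stage is then skipped and `config` ignored).
#' @param phenes Optionally, a precomputed phene matrix (skips
#'   simulation and datafication); useful for re-running downstream stages
#'   in isolation.
#' @return A list of class `phenomics_run`: `cohort`, `phenes`, `ranking`,
#'   `null` (permutation null), `selection`, `stratification` (list of
#'   `stratification_result`), and `manifest` (stage digests, seeds,
#'   config snapshot).
#' @export
run_phenomics <- function(config = cohort_config(),
                          grammar = phene_grammar(),
                          seed = 1L,
                          n_perm = 100,
                          alpha = 0.05,
                          method = "holm_bonferroni",
                          stratify_methods = c("bayes", "cart_depth2",
                                               "knn5", "linear",
                                               "svm_linear", "svm_rbf"),
                          cohort = NULL,
                          phenes = NULL) {
  seeds <- derive_seeds(seed, 3,
                        labels = c("simulate", "permute", "stratify"))
  manifest <- list(seed = seed, stage_seeds = as.list(seeds),
                   package_version = as.character(utils::packageVersion("phenescan")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   digests = list())
  if (is.null(phenes)) {
    if (is.null(cohort)) {
      cohort <- simulate_cohort(config, seed = seeds[["simulate"]])
    }
    manifest$digests$cohort <- rlang::hash(cohort[c("cells", "glands",
                                                    "outcomes")])
    phenes <- build_phene_matrix(cohort$cells, cohort$glands,
                                 cohort$outcomes, grammar = grammar,
                                 resolution = cohort$config$resolution,
                                 extent = cohort$config$slide_extent)
  }
  manifest$config <- if (!is.null(cohort)) cohort$config else config
  manifest$digests$phenes <- rlang::hash(as.data.frame(phenes))

  ranking <- loocv_rank(phenes)
  manifest$digests$ranking <- rlang::hash(as.data.frame(ranking))

  null <- permutation_null(phenes, n_perm = n_perm,
                           seed = seeds[["permute"]])
  manifest$digests$null <- rlang::hash(null$top_accuracy)

  selection <- select_phenes(phenes, ranking, alpha = alpha, method = method)
  manifest$digests$selection <- rlang::hash(as.data.frame(selection$significant))

  strat <- list()
  sel_set <- if (!is.null(selection$cart_counts) &&
                 nrow(selection$cart_counts) >= 2) {
    selection$cart_counts$phene
  } else {
    selection$significant$phene
  }
  if (nrow(selection$significant) >= 1) {
    top <- selection$significant$phene[which.max(selection$significant$cv_accuracy)]
    strat$univariate <- univariate_stratify(phenes, top)
  }
  if (length(sel_set) >= 2) {
    strat$clustering <- cluster_stratify(phenes, sel_set)
    for (m in stratify_methods) {
      strat[[m]] <- with_seed(seeds[["stratify"]],
                              supervised_stratify(phenes, sel_set, method = m))
    }
  }
  manifest$digests$stratification <-
    rlang::hash(lapply(strat, function(s) s$predictions))

  structure(list(cohort = cohort, phenes = phenes, ranking = ranking,
                 null = null, selection = selection,
                 stratification = strat, manifest = manifest),
            class = "phenomics_run")
}

#' @export
print.phenomics_run <- function(x, ...) {
  cat("<phenomics_run> seed ", x$manifest$seed, "\n", sep = "")
  cat("  candidates: ", length(phene_cols(x$phenes)), "\n", sep = "")
  top <- x$ranking[1, ]
  cat("  top phene: ", top$phene, " (cv accuracy ",
      round(top$cv_accuracy, 3), ", p ", signif(top$cv_logrank_p, 3),
      ")\n", sep = "")
  print(x$selection)
  for (s in x$stratification) {
    cat("  ", s$method, ": accuracy ", round(s$accuracy, 3),
        ", log-rank p ", signif(s$logrank_p, 3), "\n", sep = "")
  }
  invisible(x)
}

#' @exportS3Method
glance.phenomics_run <- function(x, ...) {
  tibble::tibble(
    seed = x$manifest$seed,
    n_patients = nrow(x$phenes),
    n_events = sum(x$phenes$event),
    n_candidates = length(phene_cols(x$phenes)),
    top_phene = x$ranking$phene[1],
    top_cv_accuracy = x$ranking$cv_accuracy[1],
    top_cv_logrank_p = x$ranking$cv_logrank_p[1],
    n_significant = nrow(x$selection$significant),
    n_cart_selected = if (is.null(x$selection$cart_counts)) 0L else
      nrow(x$selection$cart_counts),
    null_mean_top_accuracy = mean(x$null$top_accuracy, na.rm = TRUE)
  )
}
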
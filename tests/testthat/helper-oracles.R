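# Shared fixtures and independent brute-force oracles.

# random right-censored survival table
random_surv_table <- function(n, event_frac = 0.5, seed = NULL) {
  gen <- function() {
    tibble::tibble(
      patient_id = sprintf("S%03d", seq_len(n)),
      dfs_months = round(stats::rexp(n, rate = 1 / 30), 2) + 1,
      event = stats::rbinom(n, 1, event_frac)
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# reference log-rank chi-square via direct hypergeometric tabulation,
# written independently of the package's vectorized layout machinery
logrank_oracle <- function(time, event, group) {
  et <- sort(unique(time[event == 1]))
  u <- 0; v <- 0
  for (t in et) {
    n_t <- sum(time >= t)
    n1 <- sum(time >= t & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    u <- u + d1 - d * n1 / n_t
    if (n_t > 1) {
      v <- v + d * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d) / (n_t - 1)
    }
  }
  if (v == 0) return(list(chisq = 0, p = 1))
  list(chisq = u^2 / v, p = stats::pchisq(u^2 / v, 1, lower.tail = FALSE))
}

# exhaustive cutpoint oracle: scan every midpoint between the class
# medians with the reference log-rank; same tie-breaking contract
cutpoint_oracle <- function(values, time, event) {
  # same contract: accuracy first, then p, then smaller threshold
  keep <- !is.na(values)
  v <- values[keep]; tm <- time[keep]; ev <- event[keep]
  if (length(unique(ev)) < 2 || length(unique(v)) < 2) return(NULL)
  med <- sort(c(median(v[ev == 1]), median(v[ev == 0])))
  if (med[1] == med[2]) return(NULL)
  uv <- sort(unique(v))
  mids <- (uv[-1] + uv[-length(uv)]) / 2
  thr <- mids[mids >= med[1] & mids <= med[2]]
  if (length(thr) == 0) return(NULL)
  rows <- lapply(thr, function(th) {
    g <- as.numeric(v >= th)
    lr <- logrank_oracle(tm, ev, g)
    acc_ge <- mean(ev == as.numeric(v < th))
    op <- if (acc_ge >= 1 - acc_ge) ">=" else "<"
    data.frame(threshold = th, p = lr$p, acc = max(acc_ge, 1 - acc_ge),
               op = op)
  })
  df <- do.call(rbind, rows)
  df[order(-df$acc, df$p, df$threshold)[1], ]
}

# brute-force region bands from center-to-center pixel distances
roi_band_oracle <- function(tumor, res, width) {
  ny <- nrow(tumor); nx <- ncol(tumor)
  idx <- which(tumor, arr.ind = TRUE)
  out <- matrix(FALSE, ny, nx)
  if (nrow(idx) == 0) return(out)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    if (tumor[i, j]) next
    d <- sqrt(min((idx[, 1] - i)^2 + (idx[, 2] - j)^2))
    out[i, j] <- (d - 0.5) * res <= width
  }
  out
}

# heatmap stack wrapping a hand-built tumor mask
mask_heatmap <- function(tumor, res, intact = NULL) {
  ny <- nrow(tumor); nx <- ncol(tumor)
  zero <- matrix(0, ny, nx)
  ch <- setNames(rep(list(zero), length(phenescan:::.markers)),
                 paste0("count_", phenescan:::.markers))
  ch$glandfrac_nonIntact <- tumor * 1
  ch$glandfrac_intact <- if (is.null(intact)) zero else intact * 1
  structure(list(resolution = res, extent = c(nx * res, ny * res),
                 dim = c(ny, nx), channels = ch),
            class = "heatmap_stack")
}

# small phene matrix of pure-noise candidates for mining-stage tests
noise_phene_matrix <- function(n = 40, n_cand = 12, event_frac = 0.45,
                               seed = 1) {
  withr::with_seed(seed, {
    pm <- tibble::tibble(
      patient_id = sprintf("S%03d", seq_len(n)),
      dfs_months = round(stats::runif(n, 2, 118), 1),
      event = stats::rbinom(n, 1, event_frac)
    )
    while (length(unique(pm$event)) < 2 || min(table(pm$event)) < 3) {
      pm$event <- stats::rbinom(n, 1, event_frac)
    }
    for (j in seq_len(n_cand)) {
      pm[[paste0("#CD8_border", j)]] <- stats::rnorm(n)
    }
    pm
  })
}

# compact configs for spatial tests (small slides keep runtime low)
tiny_cohort_config <- function(..., planted = NULL) {
  cohort_config(n_patients = 8, n_events = 4,
                slide_extent = c(1600, 1600),
                n_tumor_glands = 10, n_healthy_glands = 10,
                planted_effects = planted, ...)
}
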
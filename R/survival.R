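#' Kaplan-Meier product-limit estimator
#'
#' Estimates the disease-free survival function from a survival table.
#' Implemented from first principles (product-limit over distinct times,
#' events before censorings at ties) because the cutpoint optimizer calls
#' the same machinery millions of times with incremental group updates.
#'
#' @param data A data frame with columns `patient_id`, `dfs_months`
#'   (positive), `event` (0 = censored, 1 = progression).
#' @return A tibble of class `phenescan_km` with one row per distinct
#'   observed time: `time`, `n_risk`, `n_event`, `n_censor`, `surv`.
#'   Survival starts at 1 (an implicit time-0 row is not stored) and is
#'   non-increasing.
#' @examples
#' km_curve(data.frame(patient_id = 1:3, dfs_months = c(5, 10, 15),
#'                     event = c(1, 0, 1)))
#' @export
km_curve <- function(data) {
  check_survival_table(data)
  if (nrow(data) == 0) abort("empty survival table")
  tt <- sort(unique(data$dfs_months))
  n_event <- vapply(tt, function(t) sum(data$dfs_months == t & data$event == 1), 0)
  n_censor <- vapply(tt, function(t) sum(data$dfs_months == t & data$event == 0), 0)
  n_risk <- vapply(tt, function(t) sum(data$dfs_months >= t), 0)
  surv <- cumprod(1 - n_event / n_risk)
  out <- tibble::tibble(time = tt, n_risk = n_risk, n_event = n_event,
                        n_censor = n_censor, surv = surv)
  class(out) <- c("phenescan_km", class(out))
  out
}

# Precompute the risk-set layout of a survival table once so that many
# group assignments can be scored against it cheaply.
# Returns, over the m distinct event times (ascending):
#   d        events at each time (both groups pooled)
#   n_risk   subjects at risk
#   at_risk  m x n 0/1 matrix: subject j at risk at event time i
#   ev_at    m x n 0/1 matrix: subject j has an event at time i
survival_layout <- function(time, event) {
  et <- sort(unique(time[event == 1]))
  m <- length(et)
  n <- length(time)
  if (m == 0) {
    return(list(n = n, m = 0))
  }
  at_risk <- matrix(0, m, n)
  ev_at <- matrix(0, m, n)
  for (i in seq_len(m)) {
    at_risk[i, ] <- as.numeric(time >= et[i])
    ev_at[i, ] <- as.numeric(time == et[i] & event == 1)
  }
  list(n = n, m = m, event_times = et,
       d = rowSums(ev_at), n_risk = rowSums(at_risk),
       at_risk = at_risk, ev_at = ev_at)
}

# Score K candidate group assignments at once against a layout.
# g: n x K matrix (0/1; membership of "group 1").
# Returns list(chisq, p), each length K. Assignments where the log-rank
# variance is zero (empty group or no events) score chisq 0, p 1.
logrank_scan <- function(layout, g) {
  g <- as.matrix(g)
  K <- ncol(g)
  if (layout$m == 0) {
    return(list(chisq = rep(0, K), p = rep(1, K)))
  }
  n1 <- layout$at_risk %*% g          # m x K: group-1 at-risk counts
  d1 <- layout$ev_at %*% g            # m x K: group-1 events
  d <- layout$d
  nr <- layout$n_risk
  frac <- n1 / nr
  e1 <- d * frac
  vterm <- d * frac * (1 - frac) * ifelse(nr > 1, (nr - d) / (nr - 1), 0)
  u <- colSums(d1 - e1)
  v <- colSums(vterm)
  chisq <- ifelse(v > 0, u^2 / v, 0)
  p <- ifelse(v > 0, pchisq(chisq, df = 1, lower.tail = FALSE), 1)
  list(chisq = chisq, p = p)
}

#' Two-group log-rank test
#'
#' Standard log-rank test comparing survival between two groups, using the
#' hypergeometric expectation and variance of group-1 events at each
#' distinct event time, with the statistic referred to a chi-square
#' distribution on 1 degree of freedom.
#'
#' @inheritParams km_curve
#' @param group A vector with two levels (or 0/1) aligned with rows of
#'   `data`; both groups must be non-empty.
#' @return A one-row tibble: `statistic` (chi-square), `p.value`,
#'   `n`, `n_events`. If no events are present the statistic is 0 and
#'   the p-value 1.
#' @examples
#' tab <- data.frame(patient_id = 1:6, dfs_months = c(3, 5, 7, 9, 11, 13),
#'                   event = c(1, 1, 1, 0, 1, 0))
#' logrank_test(tab, group = c(1, 1, 1, 0, 0, 0))
#' @export
logrank_test <- function(data, group) {
  check_survival_table(data)
  if (length(group) != nrow(data)) abort("group length must match data rows")
  lev <- unique(group)
  if (length(lev) != 2) abort("exactly two non-empty groups are required")
  g <- as.numeric(group == lev[[2]])
  layout <- survival_layout(data$dfs_months, data$event)
  sc <- logrank_scan(layout, matrix(g, ncol = 1))
  tibble::tibble(statistic = sc$chisq[1], p.value = sc$p[1],
                 n = nrow(data), n_events = sum(data$event))
}

#' @exportS3Method
autoplot.phenescan_km <- function(object, ...) {
  df <- tibble::tibble(time = c(0, object$time), surv = c(1, object$surv))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "disease-free survival time (months)",
                  y = "survival probability")
}
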
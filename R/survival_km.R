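validate_cohort <- function(cohort) {
  stopifnot(all(c("time", "event", "marker") %in% names(cohort)))
  if (any(cohort$time <= 0)) stop("follow-up times must be > 0")
  if (!all(cohort$event %in% c(0, 1))) stop("event must be 0 or 1")
  if (any(!is.finite(cohort$marker))) stop("marker values must be finite")
  invisible(cohort)
}

#' Kaplan-Meier product-limit estimate
#'
#' `S(t)` is the product over event times up to `t` of `(1 - d_i / n_i)`;
#' censored-only times reduce the risk set but leave `S` unchanged.
#'
#' @param cohort data.frame with `time` and `event` (1 = event,
#'   0 = censored); a `marker` column is allowed and ignored.
#' @return data.frame with one row per distinct observed time: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`.
#' @export
km_estimate <- function(cohort) {
  stopifnot(all(c("time", "event") %in% names(cohort)))
  ut <- sort(unique(cohort$time))
  n_risk <- vapply(ut, function(t) sum(cohort$time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(cohort$time == t & cohort$event == 1), numeric(1))
  n_censor <- vapply(ut, function(t) sum(cohort$time == t & cohort$event == 0), numeric(1))
  survival <- cumprod(1 - n_event / n_risk)
  data.frame(time = ut, n_risk = n_risk, n_event = n_event,
             n_censor = n_censor, survival = survival)
}

# presorted scaffolding shared by every log-rank evaluation on one cohort
logrank_prep <- function(time, event) {
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]
  ut <- unique(t_s[e_s == 1])
  n <- length(t_s)
  pos <- findInterval(ut, t_s, left.open = TRUE)   # #{t < ut_j}
  n_risk <- n - pos
  ev <- which(e_s == 1)
  ev_t_idx <- match(t_s[ev], ut)
  d <- as.vector(rowsum(rep(1, length(ev)), ev_t_idx))
  list(ord = ord, n = n, ut = ut, pos = pos, n_risk = n_risk, d = d, ev = ev,
       ev_t_idx = ev_t_idx)
}

# O, E, V for group-1 membership g (logical, original order)
logrank_core <- function(prep, g) {
  g_s <- g[prep$ord]
  csp <- c(0, cumsum(g_s))
  n1 <- sum(g_s) - csp[prep$pos + 1L]
  d1 <- as.vector(rowsum(as.numeric(g_s[prep$ev]), prep$ev_t_idx))
  nr <- prep$n_risk; d <- prep$d
  E1 <- sum(d * n1 / nr)
  vterm <- d * (n1 / nr) * (1 - n1 / nr) * ifelse(nr > 1, (nr - d) / (nr - 1), 0)
  list(O1 = sum(d1), E1 = E1, V = sum(vterm), O2 = sum(d) - sum(d1),
       E2 = sum(d) - E1)
}

#' Log-rank test of marker-dichotomized survival
#'
#' Splits the cohort at `cutoff` (group 1 = marker > cutoff, "high";
#' group 2 = marker <= cutoff, "low"), accumulates observed and expected
#' events and the hypergeometric variance over distinct event times, and
#' reports `chi_square = (O1 - E1)^2 / V` against chi-square with 1 df.
#' The hazard ratio is `(O1/E1) / (O2/E2)`, high over low.
#'
#' @param cohort data.frame with `time`, `event`, `marker`.
#' @param cutoff marker threshold.
#' @return a `logrank_result` list: `chi_square`, `p`, `O1`, `E1`, `O2`,
#'   `E2`, `hazard_ratio`, `n_low`, `n_high`, `cutoff`.
#' @export
logrank <- function(cohort, cutoff) {
  validate_cohort(cohort)
  g <- cohort$marker > cutoff
  if (!any(g) || all(g)) stop("degenerate split: a group has zero members")
  prep <- logrank_prep(cohort$time, cohort$event)
  s <- logrank_core(prep, g)
  chi <- if (s$V > 0) (s$O1 - s$E1)^2 / s$V else 0
  structure(list(chi_square = chi,
                 p = pchisq(chi, df = 1, lower.tail = FALSE),
                 O1 = s$O1, E1 = s$E1, O2 = s$O2, E2 = s$E2,
                 hazard_ratio = (s$O1 / s$E1) / (s$O2 / s$E2),
                 n_high = sum(g), n_low = sum(!g), cutoff = cutoff),
            class = "logrank_result")
}

#' Data-driven marker cut-off optimization
#'
#' Evaluates the log-rank test at every distinct marker value whose split
#' leaves the low group's fraction inside `quantile_range`, and returns the
#' cut-off minimizing the p-value (ties break toward the cut-off nearest
#' the marker median). The minimum over many candidate splits is biased
#' toward small p-values; an optional permutation correction re-optimizes
#' on marker-shuffled cohorts and reports the empirical p of the observed
#' minimum.
#'
#' @param cohort data.frame with `time`, `event`, `marker`.
#' @param quantile_range admissible range for the low-group fraction.
#' @param correction `"none"` or `"permutation"`.
#' @param n_perm permutations for the correction.
#' @param seed integer seed for the correction.
#' @return list with `cutoff`, `result` (the [logrank()] at the optimum),
#'   `n_candidates`, and `p_corrected` (`NA` without correction).
#' @export
optimize_cutoff <- function(cohort, quantile_range = c(0.10, 0.90),
                            correction = c("none", "permutation"),
                            n_perm = 500L, seed = 1L) {
  correction <- match.arg(correction)
  validate_cohort(cohort)
  prep <- logrank_prep(cohort$time, cohort$event)
  n <- nrow(cohort)

  min_p_scan <- function(marker) {
    vals <- sort(unique(marker))
    frac_low <- vapply(vals, function(v) sum(marker <= v), numeric(1)) / n
    cand <- vals[frac_low >= quantile_range[1] & frac_low <= quantile_range[2] &
                   frac_low < 1]
    if (!length(cand)) stop("degenerate split: no admissible cut-off in range")
    ps <- vapply(cand, function(v) {
      s <- logrank_core(prep, marker <= v)
      chi <- if (s$V > 0) (s$O1 - s$E1)^2 / s$V else 0
      pchisq(chi, df = 1, lower.tail = FALSE)
    }, numeric(1))
    best <- which(ps == min(ps))
    if (length(best) > 1) {
      med <- median(marker)
      best <- best[order(abs(cand[best] - med))][1]
    }
    list(cutoff = cand[best], p = min(ps), n_candidates = length(cand))
  }

  obs <- min_p_scan(cohort$marker)
  p_corrected <- NA_real_
  if (correction == "permutation") {
    null_min <- with_substream(seed, "cutoff_permutation", {
      vapply(seq_len(n_perm), function(i) {
        min_p_scan(sample(cohort$marker))$p
      }, numeric(1))
    })
    p_corrected <- (1 + sum(null_min <= obs$p)) / (n_perm + 1)
  }
  list(cutoff = obs$cutoff, result = logrank(cohort, obs$cutoff),
       n_candidates = obs$n_candidates, p_corrected = p_corrected)
}
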
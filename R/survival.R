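#' Kaplan-Meier product-limit estimate
#'
#' First-principles product-limit estimator. At tied times events
#' precede censorings (the standard convention), i.e. a subject
#' censored at t is still at risk for an event at t. Greenwood
#' standard errors are reported alongside.
#'
#' @param time follow-up times (months), strictly positive.
#' @param event event indicator: 1 = event observed, 0 = censored.
#' @return a [KaplanMeier-class] object.
#' @examples
#' km <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
#' kmTable(km)
#' @export
kmEstimate <- function(time, event) {
  if (length(time) < 1L) stop("at least one record required", call. = FALSE)
  if (any(!is.finite(time)) || any(time <= 0))
    stop("times must be positive", call. = FALSE)
  if (!all(event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (event)", call. = FALSE)
  n <- length(time)
  tt <- sort(unique(time))
  nEvent <- vapply(tt, function(t) sum(time == t & event == 1), integer(1L))
  nCensor <- vapply(tt, function(t) sum(time == t & event == 0), integer(1L))
  nRisk <- vapply(tt, function(t) sum(time >= t), integer(1L))
  surv <- cumprod(1 - nEvent / nRisk)
  # Greenwood: Var(S) = S^2 * sum d_i / (n_i (n_i - d_i))
  terms <- ifelse(nRisk > nEvent, nEvent / (nRisk * (nRisk - nEvent)), 0)
  se <- surv * sqrt(cumsum(terms))
  se[surv == 0] <- 0
  new("KaplanMeier", time = as.numeric(tt), nRisk = nRisk,
      nEvent = nEvent, nCensor = nCensor, surv = surv, se = se,
      n = as.integer(n))
}

#' Survival probability at a horizon
#'
#' Step-function lookup S(horizon); S(0) = 1. When the horizon
#' exceeds the last observed follow-up, the last value is returned
#' with `extrapolated = TRUE`.
#'
#' @param curve a [KaplanMeier-class] object.
#' @param horizon time in the same units as the curve (default 60
#'   months, the five-year horizon).
#' @return list with `prob` and `extrapolated`.
#' @export
survivalAt <- function(curve, horizon = 60) {
  if (horizon < 0) stop("horizon must be >= 0", call. = FALSE)
  idx <- sum(curve@time <= horizon)
  prob <- if (idx == 0L) 1 else curve@surv[idx]
  list(prob = prob,
       extrapolated = length(curve@time) > 0L &&
         horizon > max(curve@time))
}

#' Two-group log-rank test
#'
#' First-principles log-rank chi-square (1 df): expected events are
#' accumulated over the shared distinct event times with the usual
#' hypergeometric variance; p comes from the upper chi-square tail.
#' An optional permutation p-value shuffles group labels with a fixed
#' seed.
#'
#' @param time,event follow-up times and event indicators.
#' @param group two-level grouping vector.
#' @param nPermutations if > 0, also compute a permutation p-value.
#' @param seed RNG seed for the permutations.
#' @return list with `statistic`, `df`, `p.value`, `observed`,
#'   `expected` (per group), and `p.permutation` when requested.
#' @export
logrankTest <- function(time, event, group, nPermutations = 0L,
                        seed = 1L) {
  lev <- unique(group)
  if (length(lev) != 2L)
    stop("exactly two groups required", call. = FALSE)
  if (sum(event) == 0)
    stop("log-rank undefined without any event", call. = FALSE)
  stat_fun <- function(g1) {
    dtimes <- sort(unique(time[event == 1]))
    O1 <- E1 <- V <- 0
    for (t in dtimes) {
      atrisk <- time >= t
      n_i <- sum(atrisk)
      n1_i <- sum(atrisk & g1)
      d_i <- sum(time == t & event == 1)
      d1_i <- sum(time == t & event == 1 & g1)
      O1 <- O1 + d1_i
      E1 <- E1 + d_i * n1_i / n_i
      if (n_i > 1)
        V <- V + d_i * (n1_i / n_i) * (1 - n1_i / n_i) *
          (n_i - d_i) / (n_i - 1)
    }
    c(O1 = O1, E1 = E1, V = V)
  }
  g1 <- group == lev[1L]
  s <- stat_fun(g1)
  stat <- if (s["V"] > 0) unname((s["O1"] - s["E1"])^2 / s["V"]) else 0
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  res <- list(statistic = stat, df = 1L, p.value = p,
              observed = c(sum(event[g1]), sum(event[!g1])),
              expected = c(unname(s["E1"]), sum(event) - unname(s["E1"])))
  if (nPermutations > 0L) {
    perm_stats <- with_seed(seed, vapply(seq_len(nPermutations), function(i) {
      gp <- sample(g1)
      sp <- stat_fun(gp)
      if (sp["V"] > 0) unname((sp["O1"] - sp["E1"])^2 / sp["V"]) else 0
    }, numeric(1L)))
    res$p.permutation <- mean(perm_stats >= stat - 1e-12)
  }
  res
}

.check_cohort <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("time", "event", "covariate") %in% names(records)))
  if (anyNA(records$covariate))
    stop("covariate missing for some records", call. = FALSE)
  records
}

#' Dichotomise a cohort at the covariate mean
#'
#' The mean split used for methylation-stratified survival: low
#' group is covariate < mean, high group is covariate >= mean, then a
#' log-rank test compares the two survival curves.
#'
#' @param records data.frame with `time`, `event`, `covariate`.
#' @return a [SurvivalCutoff-class] with `method = "mean_split"`.
#' @export
splitByMean <- function(records) {
  records <- .check_cohort(records)
  x <- records$covariate
  if (length(unique(x)) < 2L)
    stop("degenerate split: all covariate values identical", call. = FALSE)
  thr <- mean(x)
  high <- x >= thr
  lr <- logrankTest(records$time, records$event, high)
  new("SurvivalCutoff", threshold = thr, method = "mean_split",
      nLow = sum(!high), nHigh = sum(high),
      statistic = lr$statistic, p = lr$p.value, nTested = 1L)
}

#' Best-cutoff scan over observed covariate values
#'
#' Evaluates every observed covariate value within the
#' `[lowerQ, upperQ]` quantile range as a candidate threshold (split:
#' `< t` vs `>= t`) and returns the threshold minimising the log-rank
#' p-value — the "auto select best cutoff" strategy of survival web
#' tools. The returned p is the minimum over `nTested` candidate
#' splits and is NOT adjusted for that selection; treat it as
#' descriptive.
#'
#' @param records data.frame with `time`, `event`, `covariate`.
#' @param lowerQ,upperQ quantile bounds for candidate thresholds.
#' @return a [SurvivalCutoff-class] with `method = "best_cutoff"`.
#' @export
bestCutoffScan <- function(records, lowerQ = 0.1, upperQ = 0.9) {
  records <- .check_cohort(records)
  x <- records$covariate
  if (nrow(records) < 20L)
    warning("fewer than 20 records; cutoff scan is unstable")
  qs <- quantile(x, c(lowerQ, upperQ), names = FALSE, type = 7)
  cand <- sort(unique(x[x >= qs[1L] & x <= qs[2L]]))
  cand <- cand[vapply(cand, function(t) any(x < t) && any(x >= t),
                      logical(1L))]
  if (length(cand) == 0L)
    stop("degenerate covariate: no valid threshold in quantile range",
         call. = FALSE)
  ps <- stats_v <- numeric(length(cand))
  for (i in seq_along(cand)) {
    high <- x >= cand[i]
    lr <- logrankTest(records$time, records$event, high)
    ps[i] <- lr$p.value
    stats_v[i] <- lr$statistic
  }
  best <- which.min(ps)  # ties: smallest threshold
  thr <- cand[best]
  high <- x >= thr
  new("SurvivalCutoff", threshold = thr, method = "best_cutoff",
      nLow = sum(!high), nHigh = sum(high),
      statistic = stats_v[best], p = ps[best],
      nTested = length(cand))
}

#' Per-group KM curves for a dichotomised cohort
#'
#' Convenience wrapper: splits at a threshold and estimates one
#' [KaplanMeier-class] curve per group.
#'
#' @param records data.frame with `time`, `event`, `covariate`.
#' @param threshold covariate threshold (low `< t`, high `>= t`).
#' @return list with `low` and `high` KaplanMeier curves.
#' @export
kmByGroup <- function(records, threshold) {
  records <- .check_cohort(records)
  high <- records$covariate >= threshold
  if (!any(high) || all(high))
    stop("threshold leaves a group empty", call. = FALSE)
  list(low = kmEstimate(records$time[!high], records$event[!high]),
       high = kmEstimate(records$time[high], records$event[high]))
}
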
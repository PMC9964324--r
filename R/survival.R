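#' Kaplan-Meier survival curve
#'
#' Product-limit estimator \eqn{S(t) = \prod_{t_i \le t} (1 - d_i / n_i)}
#' over the distinct event times, with censored subjects leaving the risk
#' set after their recorded time (events precede censorings at tied times).
#' The median survival is the earliest time at which S falls to 0.5 or
#' below, `NA` when the curve never reaches 0.5.
#'
#' @param records A `SurvivalRecords` data.frame (see [survival_records()]),
#'   optionally carrying a `group` column.
#' @param group Optional group label: fit only that group's records.
#' @return A data.frame of class `KMCurve`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`; attribute `median_survival`.
#' @export
km_fit <- function(records, group = NULL) {
  stopifnot(is.data.frame(records))
  if (!is.null(group)) {
    if (!"group" %in% colnames(records)) stop("records carry no group column")
    records <- records[records$group == group, , drop = FALSE]
  }
  if (nrow(records) == 0L) stop("no records to fit")
  if (any(records$time < 0)) stop("negative survival time")
  sf <- survival::survfit(
    survival::Surv(time, event) ~ 1,
    data = records[, c("time", "event")]
  )
  out <- data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                    n_censor = sf$n.censor, survival = sf$surv)
  med <- out$time[out$survival <= 0.5]
  attr(out, "median_survival") <- if (length(med)) min(med) else NA_real_
  class(out) <- c("KMCurve", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param curve A `KMCurve` from [km_fit()].
#' @param times Numeric vector of evaluation times.
#' @return S(t) at each requested time (1 before the first event).
#' @export
km_survival_at <- function(curve, times) {
  vapply(times, function(t) {
    i <- curve$time <= t
    if (!any(i)) 1 else curve$survival[max(which(i))]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Unweighted log-rank: at each distinct event time the observed events in
#' group 1 are compared with the hypergeometric expectation, and
#' `chi_sq = (sum(O1 - E1))^2 / sum(V)` is referred to chi-square(1).
#'
#' @param records A `SurvivalRecords` data.frame with a `group` column (see
#'   [dichotomize_by_expression()]).
#' @param group_label Column holding the two group labels.
#' @return A list of class `LogRankResult`: `chi_sq`, `df`, `p`,
#'   `group_sizes`.
#' @export
logrank_test <- function(records, group_label = "group") {
  stopifnot(is.data.frame(records))
  g <- records[[group_label]]
  if (is.null(g)) stop("records carry no '", group_label, "' column")
  levs <- unique(g)
  if (length(levs) != 2L) stop("log-rank test requires exactly 2 groups")
  if (any(table(g) == 0L)) stop("empty group")
  if (sum(records$event) == 0L) stop("no events observed in either group")
  dat <- data.frame(time = records$time, event = records$event, g = g)
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ g, data = dat)
  chi <- unname(sd_fit$chisq)
  structure(list(chi_sq = chi, df = 1L,
                 p = stats::pchisq(chi, df = 1L, lower.tail = FALSE),
                 group_sizes = table(g)),
            class = "LogRankResult")
}

#' @export
print.LogRankResult <- function(x, ...) {
  cat(sprintf("log-rank: chi-square = %.4g (1 df), p = %.4g\n", x$chi_sq, x$p))
  invisible(x)
}

#' Dichotomize a cohort by expression
#'
#' Median split on the covariate: `high` when covariate > median, `low`
#' otherwise (ties, including the median subject at odd n, go low).
#'
#' @param records A `SurvivalRecords` data.frame with a numeric `covariate`.
#' @param quantile Split quantile (default 0.5, the median).
#' @return The records with a `group` column in \{"high", "low"\}.
#' @export
dichotomize_by_expression <- function(records, quantile = 0.5) {
  stopifnot(is.data.frame(records))
  if (nrow(records) < 4L) stop("need >= 4 subjects to dichotomize")
  if (anyNA(records$covariate)) stop("missing covariate values")
  cut <- stats::quantile(records$covariate, quantile, names = FALSE)
  if (all(records$covariate == records$covariate[1L])) {
    stop("constant covariate: no split possible")
  }
  records$group <- ifelse(records$covariate > cut, "high", "low")
  if (length(unique(records$group)) < 2L) {
    stop("degenerate split at quantile ", quantile)
  }
  records
}
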
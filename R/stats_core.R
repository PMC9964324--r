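#' Two-sided Wilcoxon rank-sum test
#'
#' The test behind every two-group index comparison. Uses the exact rank-sum
#' null distribution when the combined sample size is at most `exact_limit`
#' and the pooled data are tie-free; otherwise the tie-corrected normal
#' approximation with continuity correction.
#'
#' @param a,b Numeric vectors, each non-empty.
#' @param exact_limit Combined-n threshold for the exact path (default 12).
#' @return A list of class `TestResult`: `statistic` (rank-sum W of `a`),
#'   `p`, `method`, `exact` flag.
#' @export
wilcoxon_rank_sum <- function(a, b, exact_limit = 12L) {
  if (length(a) < 1L || length(b) < 1L) stop("both groups must be non-empty")
  pooled <- c(a, b)
  ties <- anyDuplicated(pooled) > 0L
  use_exact <- (length(pooled) <= exact_limit) && !ties
  na <- length(a)
  if (all(pooled == pooled[1L])) {
    # total ties: no evidence either way
    res <- list(statistic = na * length(b) / 2 + na * (na + 1) / 2, p = 1)
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided",
                         exact = use_exact, correct = TRUE)
    )
    # wilcox.test reports Mann-Whitney U; convert to the rank sum of `a`
    res <- list(statistic = unname(ht$statistic) + na * (na + 1) / 2,
                p = min(1, ht$p.value))
  }
  structure(list(statistic = res$statistic, p = res$p,
                 method = "wilcoxon_rank_sum", exact = use_exact),
            class = "TestResult")
}

#' Kruskal-Wallis omnibus test
#'
#' Tie-corrected Kruskal-Wallis H with chi-square(k-1) reference. All values
#' identical across groups gives H = 0, p = 1 by convention.
#'
#' @param groups List of >= 2 non-empty numeric vectors.
#' @return A `TestResult` with `statistic` = H and `df` attribute.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need >= 2 groups")
  if (any(lengths(groups) == 0L)) stop("empty group")
  pooled <- unlist(groups, use.names = FALSE)
  if (all(pooled == pooled[1L])) {
    return(structure(list(statistic = 0, p = 1, df = length(groups) - 1L,
                          method = "kruskal_wallis", exact = FALSE),
                     class = "TestResult"))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- stats::kruskal.test(pooled, g)
  structure(list(statistic = unname(ht$statistic), p = min(1, ht$p.value),
                 df = unname(ht$parameter), method = "kruskal_wallis",
                 exact = FALSE),
            class = "TestResult")
}

#' Pearson correlation test
#'
#' Pearson r with the Student-t reference on n - 2 degrees of freedom.
#' A constant input vector is a degenerate case reported as r = 0, p = 1
#' with a flag rather than an error, so module-trait screens over many
#' traits survive constant columns.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A `TestResult` with `statistic` = r, plus `t`, `df`, `degenerate`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(statistic = 0, p = 1, t = 0, df = n - 2L,
                          method = "pearson", exact = FALSE,
                          degenerate = TRUE),
                     class = "TestResult"))
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    tval <- sign(r) * Inf
    p <- .Machine$double.xmin
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- max(2 * stats::pt(-abs(tval), df = n - 2), .Machine$double.xmin)
  }
  structure(list(statistic = r, p = p, t = tval, df = n - 2L,
                 method = "pearson", exact = FALSE, degenerate = FALSE),
            class = "TestResult")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with enforced monotonicity; output order matches
#' input order and values are capped at 1.
#'
#' @param p_values Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (anyNA(p_values) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Map a p-value to a significance code
#'
#' Figure-legend convention: `****` p < 0.0001, `***` p < 0.001, `**`
#' p < 0.01, `*` p < 0.05, `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of codes.
#' @export
significance_code <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g%s\n", x$method, x$statistic,
              x$p, if (isTRUE(x$exact)) " (exact)" else ""))
  invisible(x)
}
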
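#' Empirical-Bayes moderated t differential expression
#'
#' Two-group comparison (curcumin vs control) within one cell line on
#' log2-scale intensities. Per gene, the pooled residual variance s^2 with
#' d = n1 + n2 - 2 degrees of freedom is shrunk toward a prior variance s0^2
#' estimated from all genes:
#'
#' \deqn{\tilde{s}^2 = \frac{d_0 s_0^2 + d s^2}{d_0 + d}, \qquad
#'       t = \frac{\Delta}{\tilde{s}\sqrt{1/n_1 + 1/n_2}}}
#'
#' with p-values from the t distribution on d0 + d degrees of freedom and
#' Benjamini-Hochberg adjustment across all genes. The prior (d0, s0^2) is
#' estimated by the method of moments on log s^2 (digamma/trigamma
#' matching); when the observed variance of log s^2 does not exceed its
#' sampling component, d0 is infinite and every moderated variance equals
#' s0^2. A gene is called differentially expressed when |log2FC| > 1 and
#' adjusted p < 0.05 (`lfc_threshold` and `alpha` gates).
#'
#' @param expr A log-intensity [expression_matrix()].
#' @param meta `SampleMetadata` with `treatment` (and `cell_line` when
#'   `cell_line` is given) columns.
#' @param cell_line Optional cell line to subset to; `NULL` uses all samples.
#' @param treatment_levels Length-2 character vector, reference group first;
#'   log2FC is mean(second) - mean(first).
#' @param lfc_threshold Absolute log2 fold-change gate (default 1).
#' @param alpha Adjusted-p gate (default 0.05).
#' @param d0 Optional fixed prior degrees of freedom (0 recovers the
#'   ordinary pooled t; `Inf` fully pools variances); estimated when `NULL`.
#' @return A data.frame of class `DEResult`: `gene_id`, `log2fc`, `t_mod`,
#'   `p`, `p_adj`, `is_deg`, `direction`; attributes `d0` and `s0_sq` carry
#'   the fitted prior.
#' @export
moderated_t_test <- function(expr, meta, cell_line = NULL,
                             treatment_levels = c("control", "curcumin"),
                             lfc_threshold = 1, alpha = 0.05, d0 = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$mode != "log_intensity") {
    stop("moderated t requires log-intensity mode")
  }
  meta <- align_metadata(expr, meta)
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(cell_line)) {
    if (!"cell_line" %in% colnames(meta)) stop("metadata lacks cell_line")
    keep <- meta$cell_line == cell_line
  }
  grp <- meta$treatment[keep]
  if (!all(treatment_levels %in% grp)) {
    stop("treatment groups absent in selection: ",
         paste(setdiff(treatment_levels, grp), collapse = ", "))
  }
  x1 <- expr$values[, keep & meta$treatment == treatment_levels[1L], drop = FALSE]
  x2 <- expr$values[, keep & meta$treatment == treatment_levels[2L], drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 samples per treatment group")

  lfc <- rowMeans(x2) - rowMeans(x1)
  d <- n1 + n2 - 2L
  s2 <- (rowSums((x1 - rowMeans(x1))^2) + rowSums((x2 - rowMeans(x2))^2)) / d

  prior <- fit_ebayes_prior(s2, d, d0 = d0)
  d0 <- prior$d0; s0_sq <- prior$s0_sq
  if (is.infinite(d0)) {
    s2_mod <- rep(s0_sq, length(s2))
    df_total <- Inf
  } else {
    s2_mod <- (d0 * s0_sq + d * s2) / (d0 + d)
    df_total <- d0 + d
  }
  se <- sqrt(s2_mod * (1 / n1 + 1 / n2))
  t_mod <- ifelse(se > 0, lfc / se, 0)
  p <- ifelse(se > 0, 2 * stats::pt(-abs(t_mod), df = df_total), 1)
  if (any(se == 0)) {
    message(sum(se == 0), " genes with zero moderated variance: p set to 1")
  }
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  p_adj <- bh_adjust(p)
  is_deg <- abs(lfc) > lfc_threshold & p_adj < alpha
  direction <- ifelse(!is_deg, "none", ifelse(lfc > 0, "up", "down"))
  out <- data.frame(gene_id = gene_ids(expr), log2fc = unname(lfc),
                    t_mod = unname(t_mod), p = unname(p),
                    p_adj = unname(p_adj), is_deg = unname(is_deg),
                    direction = unname(direction), stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  class(out) <- c("DEResult", "data.frame")
  out
}

#' Estimate the empirical-Bayes variance prior
#'
#' Method-of-moments fit of the scaled-F model s^2 ~ s0^2 F(d, d0) on the
#' log scale: with z = log s^2 and e = z - digamma(d/2) + log(d/2), the
#' excess variance of e over trigamma(d/2) determines d0 through the inverse
#' trigamma; a non-positive excess means no detectable gene-to-gene variance
#' heterogeneity and yields d0 = Inf.
#'
#' @param s2 Per-gene residual variances (zero-variance genes are excluded
#'   from the fit but still receive the prior downstream).
#' @param d Residual degrees of freedom per gene (scalar).
#' @param d0 Optional fixed prior degrees of freedom (0 disables moderation,
#'   Inf fully pools); when given, only s0_sq is estimated.
#' @return List with `d0` and `s0_sq`.
#' @export
fit_ebayes_prior <- function(s2, d, d0 = NULL) {
  pos <- s2[s2 > 0]
  if (length(pos) < 2L) {
    return(list(d0 = Inf, s0_sq = if (length(pos)) stats::median(pos) else 1))
  }
  z <- log(pos)
  e <- z - digamma(d / 2) + log(d / 2)
  if (!is.null(d0)) {
    if (d0 == 0) return(list(d0 = 0, s0_sq = exp(mean(e))))
    if (is.infinite(d0)) return(list(d0 = Inf, s0_sq = exp(mean(e))))
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    return(list(d0 = d0, s0_sq = s0_sq))
  }
  evar <- sum((e - mean(e))^2) / (length(e) - 1L) - trigamma(d / 2)
  if (!is.finite(evar) || evar <= 0) {
    return(list(d0 = Inf, s0_sq = exp(mean(e))))
  }
  d0 <- 2 * trigamma_inverse(evar)
  if (!is.finite(d0) || d0 <= 0) return(list(d0 = Inf, s0_sq = exp(mean(e))))
  s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

# Newton solve of trigamma(y) = x, monotone decreasing on (0, Inf).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) < 1e-8 * y) break
  }
  y
}

#' Intersect differentially expressed genes across cell lines
#'
#' Genes called differentially expressed in every supplied result, sorted
#' lexicographically. Direction agreement is not required: membership
#' overlap only.
#'
#' @param results Named list (one `DEResult` per cell line), length >= 2.
#' @return Character vector of common DEG ids.
#' @export
intersect_degs <- function(results) {
  if (!is.list(results) || length(results) < 2L) {
    stop("need DE results from >= 2 cell lines")
  }
  sets <- lapply(results, function(r) r$gene_id[r$is_deg])
  sort(Reduce(intersect, sets), method = "radix")
}
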
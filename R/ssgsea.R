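#' Single-sample GSEA enrichment scores
#'
#' Per-sample, rank-based enrichment of each gene set: within a sample, genes
#' are ranked by expression in descending order (the highest-expressed gene
#' gets absolute rank N, the lowest rank 1; ties broken by gene id so results
#' are platform-deterministic). Walking down the ranked list, the enrichment
#' score is the integrated difference between the rank-weighted in-set
#' cumulative distribution and the uniform out-of-set cumulative
#' distribution:
#'
#' \deqn{ES(S) = \sum_{i=1}^{N} \left[ P_{in}(i) - P_{out}(i) \right]}
#'
#' with \eqn{P_{in}(i) = \sum_{g \in S, pos(g) \le i} r_g^\alpha / \sum_{g
#' \in S} r_g^\alpha} and \eqn{P_{out}(i) = |\{g \notin S, pos(g) \le i\}| /
#' (N - |S|)}. Because only ranks enter, the score is invariant under any
#' strictly monotone transform of a sample's expression values.
#'
#' @param expr An [expression_matrix()].
#' @param sets A list of [gene_set()] objects (or a single one). Set genes
#'   absent from the matrix are ignored; sets with no gene present are
#'   dropped with a warning.
#' @param alpha Non-negative rank-weighting exponent; 0.25 is the canonical
#'   ssGSEA weight, 0 weights all set genes equally.
#' @return A data.frame of class `EnrichmentScoreTable` in long format:
#'   `gene_set`, `sample_id`, `es`, `n_set_genes_present`.
#' @export
ssgsea_scores <- function(expr, sets, alpha = 0.25) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (inherits(sets, "GeneSet")) sets <- list(sets)
  if (!is.numeric(alpha) || alpha < 0) stop("alpha must be >= 0")
  gids <- gene_ids(expr)
  present <- lapply(sets, function(s) intersect(s$genes, gids))
  n_pres <- lengths(present)
  if (any(n_pres == 0L)) {
    dropped <- vapply(sets[n_pres == 0L], `[[`, character(1), "name")
    warning("dropping gene sets with no genes present: ",
            paste(dropped, collapse = ", "))
    sets <- sets[n_pres > 0L]
    present <- present[n_pres > 0L]
    n_pres <- n_pres[n_pres > 0L]
  }
  if (length(sets) == 0L) stop("no gene set retains any gene in the matrix")
  n_genes <- length(gids)
  samples <- sample_ids(expr)
  set_names <- vapply(sets, `[[`, character(1), "name")

  es <- matrix(NA_real_, nrow = length(sets), ncol = length(samples))
  for (j in seq_along(samples)) {
    x <- expr$values[, j]
    # descending expression; ties broken lexicographically by gene id
    ord <- order(-x, gids, method = "radix")
    ranks_abs <- rev(seq_len(n_genes))       # N, N-1, ..., 1 down the list
    ordered_ids <- gids[ord]
    for (k in seq_along(sets)) {
      in_set <- ordered_ids %in% present[[k]]
      w <- ifelse(in_set, ranks_abs^alpha, 0)
      p_in <- cumsum(w) / sum(w)
      n_out <- n_genes - n_pres[k]
      p_out <- if (n_out == 0L) rep(0, n_genes) else cumsum(!in_set) / n_out
      es[k, j] <- sum(p_in - p_out)
    }
  }
  out <- data.frame(
    gene_set = rep(set_names, times = length(samples)),
    sample_id = rep(samples, each = length(sets)),
    es = as.vector(es),
    n_set_genes_present = rep(n_pres, times = length(samples)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("EnrichmentScoreTable", "data.frame")
  out
}

#' Normalize enrichment scores across samples
#'
#' Per-set normalization of the ES values across the samples of the table.
#' A zero-variance set normalizes to all zeros rather than NaN.
#'
#' @param table An `EnrichmentScoreTable` from [ssgsea_scores()].
#' @param method `"zscore"` ((es - mean)/sd), `"minmax"`
#'   ((es - min)/(max - min)), or `"none"`.
#' @return The table with `es` replaced by normalized values.
#' @export
normalize_scores <- function(table, method = c("zscore", "minmax", "none")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(table), all(c("gene_set", "es") %in% colnames(table)))
  if (nrow(table) == 0L) stop("empty enrichment score table")
  if (method == "none") return(table)
  out <- table
  for (s in unique(table$gene_set)) {
    i <- table$gene_set == s
    v <- table$es[i]
    out$es[i] <- normalize_vector(v, method)
  }
  out
}

normalize_vector <- function(v, method) {
  if (method == "none") return(v)
  if (length(v) < 2L || stats::sd(v) == 0) return(rep(0, length(v)))
  if (method == "zscore") (v - mean(v)) / stats::sd(v)
  else (v - min(v)) / (max(v) - min(v))
}
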
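#' Score a potential index per cell
#'
#' Single-cell counts are library-size normalized to counts per million and
#' log-transformed (`log2(1 + CPM)`) per cell before ranking — a minimal,
#' rank-preserving preprocessing — and the index is then computed per cell
#' with joint normalization across all cells in the call. Cells with zero
#' total count carry no ranking information and are dropped with a warning.
#'
#' @param expr A counts-mode [expression_matrix()] (genes x cells).
#' @param defn An `IndexDefinition`, e.g. [cpi_definition()].
#' @param alpha ssGSEA rank-weighting exponent.
#' @param meta Optional `SampleMetadata` with per-cell labels (e.g.
#'   `subcluster`), carried into the result.
#' @return An `IndexResult` data.frame, one row per retained cell.
#' @export
score_cells <- function(expr, defn, alpha = 0.25, meta = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$mode != "counts") stop("score_cells requires counts mode")
  if (ncol(expr$values) == 0L || nrow(expr$values) == 0L) {
    stop("empty expression matrix")
  }
  totals <- colSums(expr$values)
  if (any(totals == 0)) {
    warning("dropping ", sum(totals == 0), " cells with zero total count")
    expr <- expression_matrix(
      expr$values[, totals > 0, drop = FALSE], "counts")
    totals <- totals[totals > 0]
  }
  cpm <- sweep(expr$values, 2L, totals, "/") * 1e6
  logged <- expression_matrix(log2(1 + cpm), "log_intensity")
  compute_index(logged, defn, alpha = alpha, meta = meta)
}

#' Compare a per-cell index across subclusters
#'
#' Kruskal-Wallis omnibus across all subclusters (with >= `min_cells`
#' cells; smaller ones are excluded with a warning), followed — when the
#' omnibus is significant at `omnibus_alpha` — by all pairwise two-sided
#' Wilcoxon rank-sum tests with Benjamini-Hochberg adjustment across the
#' pairs jointly.
#'
#' @param results An `IndexResult` from [score_cells()].
#' @param labels Per-cell subcluster labels: a named vector, or `NULL` to
#'   use the `subcluster` column of `results`.
#' @param min_cells Minimum cells per subcluster (default 3).
#' @param omnibus_alpha Gate for running the pairwise tests (default 0.05).
#' @return A list of class `SubclusterIndexSummary`: `summary` data.frame
#'   (`subcluster`, `n_cells`, `median_index`, `iqr`), `omnibus`
#'   (`TestResult`), `pairwise` (long data.frame with BH-adjusted p and
#'   significance codes, or `NULL`), `p_matrix` (symmetric adjusted-p
#'   matrix, or `NULL`).
#' @export
compare_subclusters <- function(results, labels = NULL, min_cells = 3L,
                                omnibus_alpha = 0.05) {
  stopifnot(is.data.frame(results))
  if (is.null(labels)) labels <- results$subcluster
  if (is.null(labels)) stop("no subcluster labels available")
  if (!is.null(names(labels))) {
    labels <- labels[results$sample_id]
  }
  labels <- as.character(labels)
  if (anyNA(labels)) stop("missing subcluster label for some cells")
  counts <- table(labels)
  small <- names(counts)[counts < min_cells]
  if (length(small)) {
    warning("excluding subclusters with < ", min_cells, " cells: ",
            paste(small, collapse = ", "))
    keep <- !(labels %in% small)
    results <- results[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  levs <- sort(unique(labels), method = "radix")
  if (length(levs) < 2L) stop("need >= 2 subclusters with enough cells")
  values <- split(results$index_value, factor(labels, levels = levs))
  summary_df <- data.frame(
    subcluster = levs,
    n_cells = vapply(values, length, integer(1)),
    median_index = vapply(values, stats::median, numeric(1)),
    iqr = vapply(values, stats::IQR, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  omnibus <- kruskal_wallis(values)
  pairwise <- NULL
  p_matrix <- NULL
  if (omnibus$p < omnibus_alpha) {
    prs <- utils::combn(levs, 2L, simplify = FALSE)
    raw <- vapply(prs, function(pr) {
      wilcoxon_rank_sum(values[[pr[1L]]], values[[pr[2L]]])$p
    }, numeric(1))
    adj <- bh_adjust(raw)
    pairwise <- data.frame(
      group_a = vapply(prs, `[`, character(1), 1L),
      group_b = vapply(prs, `[`, character(1), 2L),
      p = raw, p_adj = adj,
      significance_code = significance_code(adj),
      stringsAsFactors = FALSE
    )
    p_matrix <- matrix(NA_real_, length(levs), length(levs),
                       dimnames = list(levs, levs))
    for (i in seq_along(prs)) {
      p_matrix[prs[[i]][1L], prs[[i]][2L]] <- adj[i]
      p_matrix[prs[[i]][2L], prs[[i]][1L]] <- adj[i]
    }
    diag(p_matrix) <- 1
  }
  structure(list(summary = summary_df, omnibus = omnibus,
                 pairwise = pairwise, p_matrix = p_matrix),
            class = "SubclusterIndexSummary")
}
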
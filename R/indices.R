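#' Built-in cuproptosis index definition
#'
#' The CPI is defined over the essential cuproptosis genes: positive
#' components PDX1, LIAS, LIPT1, DLD, DLAT, PDHA1, PDHB (lipoylation and
#' pyruvate-dehydrogenase machinery whose activity enables copper-induced
#' death) and negative components MTF1, GLS, CDKN2A (suppressors). The
#' `"fdx1"` variant replaces PDX1 with FDX1, the ferredoxin named by the
#' cuproptosis literature; both lists are shipped because the two symbols
#' circulate for the same component set and the choice is left to the user.
#'
#' @param variant `"printed"` (default, with PDX1) or `"fdx1"`.
#' @param normalization Normalization applied to the index across samples.
#' @return An `IndexDefinition`: list with `name`, `pair`, `normalization`.
#' @export
cpi_definition <- function(variant = c("printed", "fdx1"),
                           normalization = c("zscore", "minmax")) {
  variant <- match.arg(variant)
  normalization <- match.arg(normalization)
  pos <- c("PDX1", "LIAS", "LIPT1", "DLD", "DLAT", "PDHA1", "PDHB")
  if (variant == "fdx1") pos[pos == "PDX1"] <- "FDX1"
  neg <- c("MTF1", "GLS", "CDKN2A")
  index_definition("CPI",
                   gene_set_pair("CPI", gene_set("CUPROPTOSIS_POS", pos),
                                 gene_set("CUPROPTOSIS_NEG", neg)),
                   normalization)
}

#' Define a potential index
#'
#' An index is a directional gene-set pair plus a normalization rule. The
#' FPI has no hard-coded gene list here: ferroptosis driver/suppressor sets
#' are supplied as data (e.g. via [read_gene_set_pair()]).
#'
#' @param name Index name (`"FPI"`, `"CPI"`, or custom).
#' @param pair A [gene_set_pair()].
#' @param normalization `"zscore"` or `"minmax"`.
#' @return An `IndexDefinition`.
#' @export
index_definition <- function(name, pair,
                             normalization = c("zscore", "minmax")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(pair, "GeneSetPair"))
  structure(list(name = name, pair = pair, normalization = normalization),
            class = "IndexDefinition")
}

#' Compute a potential index per sample
#'
#' The index is the normalized difference between the ssGSEA enrichment of
#' the positive components and that of the negative components:
#' `raw_difference = ES(positive) - ES(negative)` per sample, then
#' normalized across all samples supplied to the call (z-score by default).
#' Samples that should be normalized separately (e.g. different cell lines)
#' should be scored in separate calls.
#'
#' @param expr An [expression_matrix()] in log-intensity mode (use
#'   [score_cells()] for counts).
#' @param defn An `IndexDefinition`.
#' @param alpha ssGSEA rank-weighting exponent.
#' @param meta Optional `SampleMetadata`; its label columns are carried into
#'   the result.
#' @return A data.frame of class `IndexResult`: `sample_id`,
#'   `raw_difference`, `index_value`, plus any metadata labels.
#' @export
compute_index <- function(expr, defn, alpha = 0.25, meta = NULL) {
  stopifnot(inherits(defn, "IndexDefinition"))
  pair <- defn$pair
  missing_pos <- setdiff(pair$positive$genes, gene_ids(expr))
  if (length(missing_pos) == length(pair$positive$genes)) {
    stop("no positive-component gene present; missing: ",
         paste(missing_pos, collapse = ", "))
  }
  sets <- list(pair$positive)
  has_neg <- !is.null(pair$negative) &&
    length(intersect(pair$negative$genes, gene_ids(expr))) > 0L
  if (!is.null(pair$negative) && !has_neg) {
    stop("no negative-component gene present; missing: ",
         paste(pair$negative$genes, collapse = ", "))
  }
  if (has_neg) sets <- c(sets, list(pair$negative))
  tab <- ssgsea_scores(expr, sets, alpha = alpha)
  es_pos <- tab$es[tab$gene_set == pair$positive$name]
  names(es_pos) <- tab$sample_id[tab$gene_set == pair$positive$name]
  raw <- es_pos
  if (has_neg) {
    es_neg <- tab$es[tab$gene_set == pair$negative$name]
    names(es_neg) <- tab$sample_id[tab$gene_set == pair$negative$name]
    raw <- es_pos - es_neg[names(es_pos)]
  }
  out <- data.frame(sample_id = names(raw),
                    raw_difference = unname(raw),
                    index_value = normalize_vector(unname(raw),
                                                   defn$normalization),
                    stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    idx <- match(out$sample_id, meta$sample_id)
    for (nm in setdiff(colnames(meta), "sample_id")) {
      out[[nm]] <- meta[[nm]][idx]
    }
  }
  attr(out, "index_name") <- defn$name
  class(out) <- c("IndexResult", "data.frame")
  out
}

#' Compare index values between groups
#'
#' Pairwise two-sided Wilcoxon rank-sum tests of the normalized index
#' between the levels of a grouping label, with figure-style significance
#' codes (`*` p < 0.05, `**` p < 0.01, `***` p < 0.001, `****` p < 0.0001).
#'
#' @param results An `IndexResult` from [compute_index()].
#' @param meta Optional `SampleMetadata` providing the grouping label when
#'   `results` does not already carry it.
#' @param by Name of the grouping label, e.g. `"treatment"`.
#' @return A data.frame of class `GroupComparison`: `group_a`, `group_b`,
#'   `n_a`, `n_b`, `statistic`, `p`, `significance_code`.
#' @export
compare_groups <- function(results, meta = NULL, by = "treatment") {
  labels <- results[[by]]
  if (is.null(labels)) {
    if (is.null(meta)) stop("label '", by, "' not found and no metadata given")
    labels <- meta[[by]][match(results$sample_id, meta$sample_id)]
  }
  if (anyNA(labels)) stop("missing '", by, "' label for some samples")
  levs <- unique(labels)
  if (length(levs) < 2L) stop("need >= 2 groups in '", by, "'")
  counts <- table(labels)
  if (any(counts < 2L)) {
    stop("groups with < 2 samples: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  }
  pairs <- utils::combn(levs, 2L, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    va <- results$index_value[labels == pr[1L]]
    vb <- results$index_value[labels == pr[2L]]
    tr <- wilcoxon_rank_sum(va, vb)
    data.frame(group_a = pr[1L], group_b = pr[2L],
               n_a = length(va), n_b = length(vb),
               statistic = tr$statistic, p = tr$p,
               significance_code = significance_code(tr$p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("GroupComparison", "data.frame")
  out
}

#' Component-gene expression table for index heatmaps
#'
#' The expression slice underlying an index: component genes in rows,
#' annotated positive/negative, row-standardized for display (mean 0, sd 1
#' per gene when the variance is positive). Component genes absent from the
#' matrix are omitted and listed in the `"missing_genes"` attribute.
#'
#' @param expr An [expression_matrix()].
#' @param defn An `IndexDefinition`.
#' @return A data.frame: `gene_id`, `component`, one column per sample.
#' @export
index_heatmap_table <- function(expr, defn) {
  stopifnot(inherits(defn, "IndexDefinition"))
  pair <- defn$pair
  comp <- data.frame(
    gene_id = c(pair$positive$genes,
                if (!is.null(pair$negative)) pair$negative$genes),
    component = c(rep("positive", length(pair$positive$genes)),
                  if (!is.null(pair$negative))
                    rep("negative", length(pair$negative$genes))),
    stringsAsFactors = FALSE
  )
  present <- comp$gene_id %in% gene_ids(expr)
  if (!any(present & comp$component == "positive")) {
    stop("no positive-component gene present")
  }
  kept <- comp[present, , drop = FALSE]
  vals <- expr$values[kept$gene_id, , drop = FALSE]
  std <- t(apply(vals, 1L, function(v) {
    if (stats::sd(v) == 0) v - mean(v) else (v - mean(v)) / stats::sd(v)
  }))
  colnames(std) <- sample_ids(expr)
  out <- cbind(kept, as.data.frame(std, check.names = FALSE))
  rownames(out) <- NULL
  attr(out, "missing_genes") <- comp$gene_id[!present]
  out
}
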
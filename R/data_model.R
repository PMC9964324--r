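#' Construct an expression matrix
#'
#' The canonical container consumed by every stage of the pipeline: a numeric
#' genes x samples matrix with unique axis labels and an explicit mode flag.
#' Bulk matrices are log2 intensities (`mode = "log_intensity"`); single-cell
#' matrices are raw counts (`mode = "counts"`), which must be non-negative.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Dimnames
#'   are taken from `gene_ids` / `sample_ids` when supplied, otherwise from
#'   the matrix itself.
#' @param mode Either `"log_intensity"` or `"counts"`.
#' @param gene_ids,sample_ids Optional character vectors overriding the
#'   matrix dimnames.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (the labelled matrix) and `mode`.
#' @export
expression_matrix <- function(values, mode = c("log_intensity", "counts"),
                              gene_ids = NULL, sample_ids = NULL) {
  mode <- match.arg(mode)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  if (!is.null(gene_ids)) rownames(values) <- gene_ids
  if (!is.null(sample_ids)) colnames(values) <- sample_ids
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("gene and sample identifiers are required")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (mode == "counts" && any(values < 0)) {
    stop("counts mode requires all values >= 0")
  }
  structure(list(values = values, mode = mode), class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (mode: %s)\n",
              nrow(x$values), ncol(x$values), x$mode))
  invisible(x)
}

#' Gene identifiers of an expression matrix
#' @param x An `ExpressionMatrix`.
#' @return Character vector of gene ids.
#' @export
gene_ids <- function(x) rownames(x$values)

#' Sample identifiers of an expression matrix
#' @param x An `ExpressionMatrix`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(x) colnames(x$values)

#' Construct a gene set
#'
#' @param name Set name.
#' @param genes Character vector of member gene ids; duplicates are removed
#'   with a warning. Identifiers are opaque, case-sensitive strings.
#' @return An object of class `GeneSet` with elements `name` and `genes`.
#' @export
gene_set <- function(name, genes) {
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("gene set '", name, "' is empty")
  if (anyDuplicated(genes)) {
    warning("gene set '", name, "' contains duplicate genes; deduplicated")
    genes <- unique(genes)
  }
  structure(list(name = as.character(name), genes = genes), class = "GeneSet")
}

#' Construct a directional gene-set pair
#'
#' A potential index such as the CPI is defined by a pair of gene sets: the
#' positive components (genes whose activity drives the process) and the
#' negative components (genes that suppress it). The two sets must be
#' disjoint.
#'
#' @param name Pair name, e.g. `"CPI"`.
#' @param positive,negative `GeneSet` objects (or character vectors, which
#'   are wrapped). `negative` may be `NULL` for one-sided custom indices.
#' @return An object of class `GeneSetPair`.
#' @export
gene_set_pair <- function(name, positive, negative = NULL) {
  if (!inherits(positive, "GeneSet")) {
    positive <- gene_set(paste0(name, "_POS"), positive)
  }
  if (!is.null(negative) && !inherits(negative, "GeneSet")) {
    negative <- gene_set(paste0(name, "_NEG"), negative)
  }
  if (!is.null(negative) &&
      length(intersect(positive$genes, negative$genes)) > 0L) {
    stop("positive and negative components overlap: ",
         paste(intersect(positive$genes, negative$genes), collapse = ", "))
  }
  structure(list(name = as.character(name), positive = positive,
                 negative = negative), class = "GeneSetPair")
}

#' Construct sample metadata
#'
#' @param sample_id Character vector of unique sample ids.
#' @param cell_line Optional cell-line labels (recycled if length 1).
#' @param treatment Optional treatment labels, conventionally `"control"` /
#'   `"curcumin"`.
#' @param ... Further per-sample label columns (e.g. `subcluster`).
#' @return A `data.frame` of class `SampleMetadata`.
#' @export
sample_metadata <- function(sample_id, cell_line = NULL, treatment = NULL, ...) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample ids in metadata")
  out <- data.frame(sample_id = sample_id, stringsAsFactors = FALSE)
  if (!is.null(cell_line)) out$cell_line <- as.character(cell_line)
  if (!is.null(treatment)) out$treatment <- as.character(treatment)
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- as.character(extra[[nm]])
  class(out) <- c("SampleMetadata", "data.frame")
  out
}

#' Construct survival records
#'
#' @param subject_id Character vector of subject ids.
#' @param time Non-negative follow-up times.
#' @param event Event indicator (1/TRUE = death observed, 0/FALSE = censored).
#' @param covariate Numeric covariate used for dichotomization, typically the
#'   expression of a candidate prognostic gene.
#' @return A `data.frame` of class `SurvivalRecords` with columns
#'   `subject_id`, `time`, `event`, `covariate`.
#' @export
survival_records <- function(subject_id, time, event, covariate = NA_real_) {
  time <- as.numeric(time)
  event <- as.integer(event)
  if (any(time < 0)) stop("survival times must be >= 0")
  if (!all(event %in% c(0L, 1L))) stop("event must be 0/1")
  out <- data.frame(subject_id = as.character(subject_id), time = time,
                    event = event, covariate = as.numeric(covariate),
                    stringsAsFactors = FALSE)
  class(out) <- c("SurvivalRecords", "data.frame")
  out
}

# Align metadata rows to an expression matrix's samples; errors on mismatch.
align_metadata <- function(expr, meta) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  idx <- match(sample_ids(expr), meta$sample_id)
  if (anyNA(idx)) {
    stop("metadata missing samples: ",
         paste(setdiff(sample_ids(expr), meta$sample_id), collapse = ", "))
  }
  meta[idx, , drop = FALSE]
}
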
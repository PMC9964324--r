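#' Read an expression matrix
#'
#' Reads either a dense TSV/CSV (gene ids in the first column, sample ids in
#' the header) or a MatrixMarket triplet file with two sidecar one-column
#' name files (genes, then samples/cells). Duplicate gene ids are collapsed
#' by keeping the row with the highest mean, the usual microarray convention.
#'
#' @param path Path to the dense table or `.mtx` file.
#' @param mode `"log_intensity"` (bulk) or `"counts"` (single-cell).
#' @param genes_path,samples_path Sidecar name files, required for MTX input.
#' @param genes_in_rows For MTX input, whether rows of the triplet are genes
#'   (the canonical orientation); set `FALSE` to transpose on load.
#' @param drop_missing If `TRUE`, genes with any missing value are dropped;
#'   by default missing values are an error.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, mode = c("log_intensity", "counts"),
                            genes_path = NULL, samples_path = NULL,
                            genes_in_rows = TRUE, drop_missing = FALSE) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    if (is.null(genes_path) || is.null(samples_path)) {
      stop("MTX input requires 'genes_path' and 'samples_path' sidecars")
    }
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(genes_path)
    samples <- readLines(samples_path)
    if (!genes_in_rows) m <- t(m)
    if (nrow(m) != length(genes)) {
      stop("MTX has ", nrow(m), " gene rows but sidecar lists ",
           length(genes), " genes")
    }
    if (ncol(m) != length(samples)) {
      stop("MTX has ", ncol(m), " sample columns but sidecar lists ",
           length(samples), " samples")
    }
    rownames(m) <- genes
    colnames(m) <- samples
  } else {
    tab <- data.table::fread(path, header = TRUE, sep = "auto",
                             data.table = FALSE)
    if (ncol(tab) < 2L) stop("malformed expression table: ", path)
    ids <- as.character(tab[[1L]])
    m <- as.matrix(tab[, -1L, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(!vapply(tab[-1L], is.numeric, logical(1)))[1L]
      stop("non-numeric expression values in column '",
           colnames(tab)[bad + 1L], "'")
    }
    rownames(m) <- ids
  }
  m <- collapse_duplicate_genes(m)
  if (anyNA(m)) {
    if (drop_missing) {
      keep <- !apply(is.na(m), 1L, any)
      message("dropping ", sum(!keep), " genes with missing values")
      m <- m[keep, , drop = FALSE]
    } else {
      bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
      stop("missing value at gene '", rownames(m)[bad[1L]], "', sample '",
           colnames(m)[bad[2L]], "' (use drop_missing = TRUE to drop)")
    }
  }
  expression_matrix(m, mode = mode)
}

collapse_duplicate_genes <- function(m) {
  if (!anyDuplicated(rownames(m))) return(m)
  means <- rowMeans(m, na.rm = TRUE)
  ord <- order(-means)
  keep <- ord[!duplicated(rownames(m)[ord])]
  message("collapsed ", nrow(m) - length(keep),
          " duplicate gene rows (kept highest-mean row)")
  m[sort(keep), , drop = FALSE]
}

#' Write an expression matrix as TSV
#'
#' @param expr An [expression_matrix()].
#' @param path Output path; dense TSV with gene ids in the first column.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  df <- data.frame(gene_id = gene_ids(expr), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_table(df, path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields `name`, `description`
#' (discarded), then member genes. Within-line duplicates are removed with a
#' warning.
#'
#' @param path Path to the GMT file.
#' @return A named list of [gene_set()] objects in file order.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("GMT parse error at line ", i, ": fewer than 3 fields")
    }
    sets[[i]] <- gene_set(fields[1L], fields[-c(1L, 2L)])
  }
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  sets
}

#' Load a directional gene-set pair from GMT
#'
#' Convenience wrapper: reads a two-set GMT file and pairs the set whose name
#' ends in `_POS` with the one ending in `_NEG` (or takes the sets in file
#' order when the suffixes are absent).
#'
#' @param path GMT path holding exactly one or two sets.
#' @param name Name for the pair; defaults to the common prefix.
#' @return A [gene_set_pair()].
#' @export
read_gene_set_pair <- function(path, name = NULL) {
  sets <- read_gmt(path)
  if (length(sets) == 1L) {
    nm <- if (is.null(name)) sets[[1L]]$name else name
    return(gene_set_pair(nm, sets[[1L]]))
  }
  if (length(sets) != 2L) {
    stop("expected 1 or 2 sets in ", path, ", found ", length(sets))
  }
  pos_i <- grep("_POS$", names(sets))
  neg_i <- grep("_NEG$", names(sets))
  if (length(pos_i) != 1L || length(neg_i) != 1L) {
    pos_i <- 1L; neg_i <- 2L
  }
  if (is.null(name)) name <- sub("_POS$", "", names(sets)[pos_i])
  gene_set_pair(name, sets[[pos_i]], sets[[neg_i]])
}

#' Write a tabular result as TSV
#'
#' All pipeline outputs go through this writer: tab-separated, header row,
#' stable column order, doubles at 6 significant digits so that write/read
#' round-trips are the identity at that precision.
#'
#' @param result A data.frame (any of the pipeline's tabular outputs).
#' @param path Output path.
#' @export
write_table <- function(result, path) {
  stopifnot(is.data.frame(result))
  out <- result
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- formatC(out[[j]], digits = 6L, format = "g")
    }
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Read a pipeline TSV back
#' @param path Path written by [write_table()].
#' @return A data.frame.
#' @export
read_table <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
}

#' Read sample metadata from TSV
#'
#' Requires a `sample_id` column; all other columns are kept as labels.
#' @param path TSV path.
#' @return A `SampleMetadata` data.frame.
#' @export
read_sample_metadata <- function(path) {
  tab <- read_table(path)
  if (!"sample_id" %in% colnames(tab)) stop("metadata needs a sample_id column")
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample ids in metadata")
  for (j in seq_along(tab)) tab[[j]] <- as.character(tab[[j]])
  class(tab) <- c("SampleMetadata", "data.frame")
  tab
}

#' Read survival records from TSV
#'
#' Requires columns `subject_id`, `time`, `event`; `covariate` is optional.
#' @param path TSV path.
#' @return A `SurvivalRecords` data.frame.
#' @export
read_survival_records <- function(path) {
  tab <- read_table(path)
  need <- c("subject_id", "time", "event")
  if (!all(need %in% colnames(tab))) {
    stop("survival table needs columns: ", paste(need, collapse = ", "))
  }
  survival_records(tab$subject_id, tab$time, tab$event,
                   if ("covariate" %in% colnames(tab)) tab$covariate else NA_real_)
}

#' Write a sparse counts matrix as MatrixMarket triplets with sidecars
#'
#' @param expr A counts-mode [expression_matrix()].
#' @param mtx_path,genes_path,samples_path Output paths.
#' @export
write_mtx <- function(expr, mtx_path, genes_path, samples_path) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  Matrix::writeMM(Matrix::Matrix(expr$values, sparse = TRUE), mtx_path)
  writeLines(gene_ids(expr), genes_path)
  writeLines(sample_ids(expr), samples_path)
  invisible(mtx_path)
}
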
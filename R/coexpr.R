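#' Unsigned soft-thresholded adjacency
#'
#' `a_ij = |cor(g_i, g_j)|^beta` with zero diagonal. Constant gene rows have
#' undefined correlations and must be removed first (see
#' [pick_soft_threshold()]).
#'
#' @param expr An [expression_matrix()] (genes x samples).
#' @param beta Positive soft-threshold power.
#' @return A genes x genes adjacency matrix in [0, 1].
#' @export
adjacency_matrix <- function(expr, beta) {
  stopifnot(beta > 0)
  a <- abs(stats::cor(t(expr$values)))^beta
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' \deqn{TOM_{ij} = \frac{\sum_u a_{iu} a_{uj} + a_{ij}}
#'                       {\min(k_i, k_j) + 1 - a_{ij}}}
#' with `TOM_ii = 1` and connectivity `k_i = sum_j a_ij`. Similarity of two
#' genes combines their direct adjacency with the overlap of their network
#' neighbourhoods.
#'
#' @param a Adjacency matrix from [adjacency_matrix()].
#' @return TOM similarity matrix in [0, 1].
#' @export
tom_similarity <- function(a) {
  stopifnot(is.matrix(a), nrow(a) == ncol(a))
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom
}

#' Pick the soft-threshold power by scale-free topology fit
#'
#' For each candidate power, the connectivity distribution is binned into
#' `n_bins` equal-count bins and log10(frequency) is regressed on log10(mean
#' connectivity); the scale-free fit index is the R-squared of that
#' regression, counted only when the slope is negative. The selected power
#' is the smallest candidate whose fit reaches `target_r2`, else the
#' candidate with the largest fit (flagged `target_met = FALSE`).
#'
#' @param expr An [expression_matrix()] with >= 4 samples. Constant gene
#'   rows are dropped with a warning.
#' @param candidates Integer vector of candidate powers.
#' @param target_r2 Fit threshold (default 0.85).
#' @param n_bins Number of connectivity bins (default 10).
#' @return A list of class `ScaleFreeFit`: `fit` data.frame
#'   (`beta`, `r_squared`, `slope`, `mean_connectivity`), `selected_beta`,
#'   `target_met`.
#' @export
pick_soft_threshold <- function(expr, candidates = c(1:10, 12, 14, 16, 18, 20, 21),
                                target_r2 = 0.85, n_bins = 10L) {
  stopifnot(inherits(expr, "ExpressionMatrix"), length(candidates) >= 1L)
  if (ncol(expr$values) < 4L) stop("need >= 4 samples")
  expr <- drop_constant_genes(expr)
  cors <- abs(stats::cor(t(expr$values)))
  diag(cors) <- 0
  rows <- lapply(candidates, function(beta) {
    k <- rowSums(cors^beta)
    sf <- scale_free_fit(k, n_bins)
    data.frame(beta = beta, r_squared = sf$r_squared, slope = sf$slope,
               mean_connectivity = mean(k))
  })
  fit <- do.call(rbind, rows)
  ok <- fit$r_squared >= target_r2
  if (any(ok)) {
    selected <- fit$beta[which(ok)[1L]]
    target_met <- TRUE
  } else {
    selected <- fit$beta[which.max(fit$r_squared)]
    target_met <- FALSE
  }
  structure(list(fit = fit, selected_beta = selected,
                 target_met = target_met, target_r2 = target_r2),
            class = "ScaleFreeFit")
}

# log-log regression of the binned connectivity density over equal-count
# bins (frequency divided by bin width, since equal-count bins hold equal
# frequency by construction); R^2 counted only when the slope is negative,
# as scale-free topology requires a decreasing density.
scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(k) < 2L * n_bins) return(list(r_squared = 0, slope = NA_real_))
  breaks <- unique(stats::quantile(k, seq(0, 1, length.out = n_bins + 1L),
                                   names = FALSE))
  if (length(breaks) < 4L) return(list(r_squared = 0, slope = NA_real_))
  bins <- cut(k, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  mean_k <- tapply(k, bins, mean)
  width <- diff(breaks)
  dens <- as.vector(table(bins)) / (length(k) * width)
  ok <- dens > 0 & mean_k > 0
  if (sum(ok) < 4L) return(list(r_squared = 0, slope = NA_real_))
  fitlm <- stats::lm(log10(dens[ok]) ~ log10(mean_k[ok]))
  slope <- unname(stats::coef(fitlm)[2L])
  r2 <- summary(fitlm)$r.squared
  if (is.na(slope) || slope >= 0 || is.na(r2)) {
    list(r_squared = 0, slope = slope)
  } else {
    list(r_squared = r2, slope = slope)
  }
}

drop_constant_genes <- function(expr) {
  sds <- apply(expr$values, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " constant genes")
    expr <- expression_matrix(expr$values[sds > 0, , drop = FALSE], expr$mode)
  }
  expr
}

#' Detection parameters for co-expression modules
#'
#' Defaults follow the analysis settings the pipeline reproduces: unsigned
#' network at power 21, minimum module size 30, eigengene-merge cut 0.25
#' (modules whose eigengenes correlate above 0.75 are merged).
#'
#' @param beta Soft-threshold power.
#' @param min_module_size Smallest retained module; smaller clusters go grey.
#' @param merge_cut_height Eigengene dissimilarity below which modules merge.
#' @param tree_cut_height Fraction of the dendrogram's maximum merge height
#'   at which the tree is statically cut into clusters.
#' @return A `ModuleDetectionParams` list.
#' @export
module_detection_params <- function(beta = 21L, min_module_size = 30L,
                                    merge_cut_height = 0.25,
                                    tree_cut_height = 0.99) {
  stopifnot(beta > 0, min_module_size >= 1L,
            merge_cut_height > 0, merge_cut_height < 1,
            tree_cut_height > 0, tree_cut_height < 1)
  structure(list(beta = beta, min_module_size = as.integer(min_module_size),
                 merge_cut_height = merge_cut_height,
                 tree_cut_height = tree_cut_height,
                 network_type = "unsigned"),
            class = "ModuleDetectionParams")
}

#' Detect co-expression modules
#'
#' Unsigned soft-thresholded adjacency, topological overlap dissimilarity
#' (1 - TOM), average-linkage hierarchical clustering, a static cut at
#' `tree_cut_height` times the maximum merge height, relabelling of clusters
#' below `min_module_size` as `"grey"`, then iterative merging of module
#' pairs whose eigengenes correlate at least `1 - merge_cut_height`.
#' Module eigengenes are the first principal component of the standardized
#' module submatrix (unit norm, sign aligned with mean module expression).
#'
#' @param expr An [expression_matrix()] with >= 4 samples.
#' @param params A [module_detection_params()].
#' @return A list of class `ModuleAssignment`: `modules` (named character
#'   vector gene -> label, `"grey"` = unassigned), `eigengenes` (samples x
#'   modules matrix), `sizes`, `params`.
#' @export
detect_modules <- function(expr, params = module_detection_params()) {
  stopifnot(inherits(expr, "ExpressionMatrix"),
            inherits(params, "ModuleDetectionParams"))
  if (ncol(expr$values) < 4L) stop("need >= 4 samples")
  if (nrow(expr$values) < params$min_module_size) {
    stop("fewer genes than min_module_size")
  }
  expr <- drop_constant_genes(expr)
  a <- adjacency_matrix(expr, params$beta)
  tom <- tom_similarity(a)
  diss <- 1 - tom
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  cut_h <- params$tree_cut_height * max(hc$height)
  cl <- stats::cutree(hc, h = cut_h)

  # clusters below the size floor are unassigned
  sizes <- table(cl)
  grey <- cl %in% as.integer(names(sizes)[sizes < params$min_module_size])
  labels <- ifelse(grey, "grey", paste0("m", cl))
  names(labels) <- gene_ids(expr)
  labels <- relabel_by_size(labels)

  # eigengene merging
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2L) break
    me <- module_eigengenes(expr, labels, mods)
    cors <- stats::cor(me)
    diag(cors) <- -Inf
    top <- which(cors == max(cors), arr.ind = TRUE)[1L, ]
    if (cors[top[1L], top[2L]] < 1 - params$merge_cut_height) break
    from <- colnames(me)[top[2L]]
    to <- colnames(me)[top[1L]]
    labels[labels == from] <- to
  }
  labels <- relabel_by_size(labels)
  mods <- setdiff(unique(labels), "grey")
  me <- if (length(mods)) module_eigengenes(expr, labels, mods) else
    matrix(numeric(0), nrow = ncol(expr$values), ncol = 0)
  structure(list(modules = labels, eigengenes = me,
                 sizes = table(labels), params = params),
            class = "ModuleAssignment")
}

# deterministic module names m1..mK by decreasing size (ties by old label)
relabel_by_size <- function(labels) {
  mods <- setdiff(unique(labels), "grey")
  if (length(mods) == 0L) return(labels)
  sz <- vapply(mods, function(m) sum(labels == m), integer(1))
  ord <- mods[order(-sz, mods, method = "radix")]
  map <- stats::setNames(paste0("m", seq_along(ord)), ord)
  out <- ifelse(labels == "grey", "grey", unname(map[labels]))
  names(out) <- names(labels)
  out
}

# first right-singular direction of the gene-standardized module submatrix;
# unit norm over samples, sign fixed against mean module expression
module_eigengenes <- function(expr, labels, mods) {
  me <- vapply(mods, function(m) {
    sub <- expr$values[names(labels)[labels == m], , drop = FALSE]
    subs <- t(scale(t(sub)))
    subs[is.na(subs)] <- 0
    v <- svd(subs, nu = 0, nv = 1)$v[, 1L]
    if (stats::cor(v, colMeans(sub)) < 0) v <- -v
    v
  }, numeric(ncol(expr$values)))
  rownames(me) <- sample_ids(expr)
  me
}

#' Correlate module eigengenes with sample traits
#'
#' Pearson correlation of each eigengene with each trait (binary traits
#' coded 0/1), p-values from the Student t on n - 2 degrees of freedom.
#' Constant traits are flagged and reported as r = 0, p = 1.
#'
#' @param assignment A `ModuleAssignment` from [detect_modules()].
#' @param meta `SampleMetadata` in the eigengenes' sample order.
#' @param traits Character vector of metadata columns to use. Two-level
#'   character columns are coded 0/1 (alphabetical); numeric columns are
#'   used as-is.
#' @return A data.frame of class `ModuleTraitCorrelation`: `module`,
#'   `trait`, `r`, `p`, `degenerate`.
#' @export
module_trait <- function(assignment, meta, traits) {
  stopifnot(inherits(assignment, "ModuleAssignment"))
  me <- assignment$eigengenes
  if (nrow(me) < 3L) stop("need >= 3 samples")
  idx <- match(rownames(me), meta$sample_id)
  if (anyNA(idx)) stop("metadata missing eigengene samples")
  rows <- list()
  for (tr in traits) {
    v <- meta[[tr]][idx]
    if (is.null(v)) stop("unknown trait: ", tr)
    if (!is.numeric(v)) {
      levs <- sort(unique(v))
      if (length(levs) > 2L) {
        stop("trait '", tr, "' has >2 levels; code it numerically")
      }
      v <- as.numeric(v == levs[length(levs)])
    }
    for (m in colnames(me)) {
      res <- pearson_test(me[, m], v)
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, trait = tr, r = res$statistic, p = res$p,
        degenerate = isTRUE(res$degenerate), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ModuleTraitCorrelation", "data.frame")
  out
}
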
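#' Configuration for the bulk expression simulator
#'
#' Emulates the assumed study design: three hepatocellular-carcinoma cell
#' lines, each with control and curcumin-treated groups of three replicates,
#' measured as log2 intensities.
#'
#' @param n_genes Number of genes.
#' @param cell_lines Cell-line names (default PLC, KMCH, Huh7).
#' @param reps_per_group Replicates per (cell line, treatment) group.
#' @param de_fraction Fraction of genes given a treatment effect.
#' @param de_log2fc_range Range (lo, hi) of |log2 fold change| for planted
#'   effects; sign random per gene.
#' @param planted_modules List of `list(size =, strength =)` co-expression
#'   blocks; `strength` is the within-module pairwise correlation.
#' @param index_shift Data frame with columns `cell_line`, `treatment`,
#'   `component` (`"positive"`/`"negative"`) and `shift` (units of
#'   `noise_sd`), or `NULL`. Requires `index_genes`.
#' @param index_genes A [gene_set_pair()] naming the component genes that
#'   receive `index_shift`; its genes are embedded in the matrix.
#' @param noise_sd Residual log2-scale standard deviation.
#' @param seed Integer seed fixing all randomness.
#' @return A `BulkSimConfig` list.
#' @export
bulk_sim_config <- function(n_genes = 2000L,
                            cell_lines = c("PLC", "KMCH", "Huh7"),
                            reps_per_group = 3L,
                            de_fraction = 0,
                            de_log2fc_range = c(2, 3),
                            planted_modules = list(),
                            index_shift = NULL,
                            index_genes = NULL,
                            noise_sd = 0.5,
                            seed = 1L) {
  stopifnot(n_genes >= 1L, reps_per_group >= 1L,
            de_fraction >= 0, de_fraction <= 1,
            length(de_log2fc_range) == 2L, noise_sd > 0)
  if (!is.null(index_shift)) {
    stopifnot(is.data.frame(index_shift),
              all(c("cell_line", "treatment", "component", "shift") %in%
                    colnames(index_shift)),
              all(is.finite(index_shift$shift)))
    if (is.null(index_genes)) stop("index_shift requires index_genes")
  }
  sizes <- vapply(planted_modules, function(m) as.integer(m$size), integer(1))
  if (sum(sizes) > n_genes) {
    stop("planted module sizes exceed n_genes")
  }
  structure(list(n_genes = as.integer(n_genes), cell_lines = cell_lines,
                 reps_per_group = as.integer(reps_per_group),
                 de_fraction = de_fraction,
                 de_log2fc_range = de_log2fc_range,
                 planted_modules = planted_modules,
                 index_shift = index_shift, index_genes = index_genes,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "BulkSimConfig")
}

#' Simulate a bulk log-intensity dataset
#'
#' Per gene, a Normal(7, 1) baseline mean; per sample, Normal(0, noise_sd)
#' noise. Planted signals on top: treatment effects on a random
#' `de_fraction` of genes (uniform |log2FC| in `de_log2fc_range`, random
#' sign, applied in every cell line's treated group), shared-latent-factor
#' co-expression blocks with pairwise correlation `strength`, and additive
#' shifts on index-component genes per (cell line, treatment).
#'
#' @param cfg A [bulk_sim_config()].
#' @return List with `expr` ([expression_matrix()]), `meta`
#'   (`SampleMetadata`) and `truth` (planted DE genes with signed effects,
#'   gene module labels, the index-shift table).
#' @export
simulate_bulk <- function(cfg) {
  stopifnot(inherits(cfg, "BulkSimConfig"))
  set.seed(cfg$seed)
  design <- expand.grid(rep = seq_len(cfg$reps_per_group),
                        treatment = c("control", "curcumin"),
                        cell_line = cfg$cell_lines,
                        stringsAsFactors = FALSE)
  n_s <- nrow(design)
  sample_names <- sprintf("%s_%s_%d", design$cell_line, design$treatment,
                          design$rep)
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  # embed the index-component genes under their own ids
  if (!is.null(cfg$index_genes)) {
    comp <- c(cfg$index_genes$positive$genes,
              if (!is.null(cfg$index_genes$negative))
                cfg$index_genes$negative$genes)
    if (length(comp) > cfg$n_genes) stop("more component genes than n_genes")
    genes[seq_along(comp)] <- comp
  }

  mu <- stats::rnorm(cfg$n_genes, mean = 7, sd = 1)
  x <- matrix(mu, nrow = cfg$n_genes, ncol = n_s)
  noise <- matrix(stats::rnorm(cfg$n_genes * n_s, 0, 1),
                  nrow = cfg$n_genes)

  # co-expression blocks: replace noise by a shared latent factor mixture
  module_label <- integer(cfg$n_genes)
  sizes <- vapply(cfg$planted_modules, function(m) as.integer(m$size),
                  integer(1))
  if (length(sizes) > 0L) {
    # module genes drawn from the tail so they never collide with component
    # genes embedded at the front
    avail <- rev(seq_len(cfg$n_genes))[seq_len(sum(sizes))]
    at <- 0L
    for (k in seq_along(sizes)) {
      idx <- avail[at + seq_len(sizes[k])]
      at <- at + sizes[k]
      s <- cfg$planted_modules[[k]]$strength
      stopifnot(s >= 0, s <= 1)
      f <- stats::rnorm(n_s)
      noise[idx, ] <- sqrt(s) * matrix(f, nrow = sizes[k], ncol = n_s,
                                       byrow = TRUE) +
        sqrt(1 - s) * noise[idx, ]
      module_label[idx] <- k
    }
  }
  x <- x + cfg$noise_sd * noise

  # treatment effects
  n_de <- round(cfg$de_fraction * cfg$n_genes)
  de_idx <- if (n_de > 0L) sample.int(cfg$n_genes, n_de) else integer(0)
  de_effect <- numeric(0)
  if (n_de > 0L) {
    de_effect <- stats::runif(n_de, cfg$de_log2fc_range[1L],
                              cfg$de_log2fc_range[2L]) *
      sample(c(-1, 1), n_de, replace = TRUE)
    treated <- design$treatment == "curcumin"
    x[de_idx, treated] <- x[de_idx, treated] + de_effect
  }

  # index-component shifts per (cell line, treatment), in noise_sd units
  if (!is.null(cfg$index_shift)) {
    for (i in seq_len(nrow(cfg$index_shift))) {
      row <- cfg$index_shift[i, ]
      gset <- if (row$component == "positive") cfg$index_genes$positive
              else cfg$index_genes$negative
      gi <- match(gset$genes, genes)
      si <- design$cell_line == row$cell_line &
        design$treatment == row$treatment
      x[gi, si] <- x[gi, si] + row$shift * cfg$noise_sd
    }
  }

  rownames(x) <- genes
  colnames(x) <- sample_names
  truth <- list(
    de_genes = genes[de_idx],
    de_log2fc = stats::setNames(de_effect, genes[de_idx]),
    module_label = stats::setNames(module_label, genes),
    index_shift = cfg$index_shift
  )
  list(expr = expression_matrix(x, "log_intensity"),
       meta = sample_metadata(sample_names, cell_line = design$cell_line,
                              treatment = design$treatment),
       truth = truth)
}

#' Configuration for the single-cell count simulator
#'
#' @param n_genes,n_cells Matrix dimensions.
#' @param n_subclusters Number of labelled subclusters (default 16, the
#'   malignant-cell subcluster count the pipeline targets).
#' @param nb_dispersion Negative-binomial dispersion shared across genes
#'   (variance = mu + dispersion * mu^2).
#' @param subcluster_shift Data frame with columns `subcluster` (integer),
#'   `component` (`"positive"`/`"negative"`) and `shift` (log2-fold units),
#'   or `NULL` for no planted contrast. Requires `index_genes`.
#' @param index_genes A [gene_set_pair()] whose component genes receive the
#'   shifts; embedded in the matrix.
#' @param libsize_meanlog,libsize_sdlog Log-normal per-cell library-size
#'   factor parameters.
#' @param seed Integer seed.
#' @return A `SingleCellSimConfig` list.
#' @export
single_cell_sim_config <- function(n_genes = 300L, n_cells = 800L,
                                   n_subclusters = 16L,
                                   nb_dispersion = 0.5,
                                   subcluster_shift = NULL,
                                   index_genes = NULL,
                                   libsize_meanlog = log(2000),
                                   libsize_sdlog = 0.3,
                                   seed = 1L) {
  stopifnot(n_subclusters >= 2L, nb_dispersion > 0, n_genes >= 1L,
            n_cells >= n_subclusters)
  if (!is.null(subcluster_shift)) {
    stopifnot(is.data.frame(subcluster_shift),
              all(c("subcluster", "component", "shift") %in%
                    colnames(subcluster_shift)))
    if (is.null(index_genes)) stop("subcluster_shift requires index_genes")
  }
  structure(list(n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
                 n_subclusters = as.integer(n_subclusters),
                 nb_dispersion = nb_dispersion,
                 subcluster_shift = subcluster_shift,
                 index_genes = index_genes,
                 libsize_meanlog = libsize_meanlog,
                 libsize_sdlog = libsize_sdlog, seed = as.integer(seed)),
            class = "SingleCellSimConfig")
}

#' Simulate a single-cell count dataset with labelled subclusters
#'
#' Counts are negative binomial with gene-specific relative abundances
#' (log-normal, log-scale SD 1) scaled by a log-normal per-cell library
#' size. Subclusters listed in `subcluster_shift` have the named index
#' component's expected counts multiplied by `2^shift`.
#'
#' @param cfg A [single_cell_sim_config()].
#' @return List with `expr` (counts-mode [expression_matrix()]), `meta`
#'   (`SampleMetadata` with a `subcluster` label) and `truth` (the shift
#'   table and per-cell subcluster assignment).
#' @export
simulate_single_cell <- function(cfg) {
  stopifnot(inherits(cfg, "SingleCellSimConfig"))
  set.seed(cfg$seed)
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  if (!is.null(cfg$index_genes)) {
    comp <- c(cfg$index_genes$positive$genes,
              if (!is.null(cfg$index_genes$negative))
                cfg$index_genes$negative$genes)
    if (length(comp) > cfg$n_genes) stop("more component genes than n_genes")
    genes[seq_along(comp)] <- comp
  }
  cells <- sprintf("C%05d", seq_len(cfg$n_cells))
  subcluster <- rep_len(seq_len(cfg$n_subclusters), cfg$n_cells)
  rel <- exp(stats::rnorm(cfg$n_genes, 0, 1))      # relative abundance
  rel <- rel / sum(rel)
  lib <- stats::rlnorm(cfg$n_cells, cfg$libsize_meanlog, cfg$libsize_sdlog)
  mu <- outer(rel, lib)                            # genes x cells
  if (!is.null(cfg$subcluster_shift)) {
    for (i in seq_len(nrow(cfg$subcluster_shift))) {
      row <- cfg$subcluster_shift[i, ]
      gset <- if (row$component == "positive") cfg$index_genes$positive
              else cfg$index_genes$negative
      gi <- match(gset$genes, genes)
      ci <- subcluster == row$subcluster
      mu[gi, ci] <- mu[gi, ci] * 2^row$shift
    }
  }
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / cfg$nb_dispersion),
                   nrow = cfg$n_genes)
  rownames(counts) <- genes
  colnames(counts) <- cells
  list(expr = expression_matrix(counts, "counts"),
       meta = sample_metadata(cells, subcluster = as.character(subcluster)),
       truth = list(subcluster = stats::setNames(subcluster, cells),
                    subcluster_shift = cfg$subcluster_shift))
}

#' Configuration for the survival simulator
#'
#' @param n_subjects Cohort size.
#' @param baseline_hazard Exponential baseline event hazard (> 0).
#' @param log_hazard_ratio_per_SD Log hazard ratio per standard deviation of
#'   the covariate.
#' @param censoring_rate Target fraction of subjects censored, in [0, 1).
#' @param seed Integer seed.
#' @return A `SurvivalSimConfig` list.
#' @export
survival_sim_config <- function(n_subjects = 200L, baseline_hazard = 0.1,
                                log_hazard_ratio_per_SD = 0,
                                censoring_rate = 0.2, seed = 1L) {
  stopifnot(n_subjects >= 2L, baseline_hazard > 0,
            censoring_rate >= 0, censoring_rate < 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 baseline_hazard = baseline_hazard,
                 log_hazard_ratio_per_SD = log_hazard_ratio_per_SD,
                 censoring_rate = censoring_rate, seed = as.integer(seed)),
            class = "SurvivalSimConfig")
}

#' Simulate an expression-dependent survival cohort
#'
#' Covariate ~ Normal(0, 1); event times exponential with hazard
#' `baseline_hazard * exp(log_hazard_ratio_per_SD * covariate)`; independent
#' exponential censoring with rate chosen so that the expected censored
#' fraction at the baseline hazard equals `censoring_rate`
#' (rate = baseline * c/(1-c); a rate of 0 observes every event).
#'
#' @param cfg A [survival_sim_config()].
#' @return A `SurvivalRecords` data.frame.
#' @export
simulate_survival <- function(cfg) {
  stopifnot(inherits(cfg, "SurvivalSimConfig"))
  set.seed(cfg$seed)
  z <- stats::rnorm(cfg$n_subjects)
  hazard <- cfg$baseline_hazard * exp(cfg$log_hazard_ratio_per_SD * z)
  t_event <- stats::rexp(cfg$n_subjects, rate = hazard)
  if (cfg$censoring_rate > 0) {
    cens_rate <- cfg$baseline_hazard * cfg$censoring_rate /
      (1 - cfg$censoring_rate)
    t_cens <- stats::rexp(cfg$n_subjects, rate = cens_rate)
  } else {
    t_cens <- rep(Inf, cfg$n_subjects)
  }
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  survival_records(sprintf("S%04d", seq_len(cfg$n_subjects)), time, event, z)
}
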
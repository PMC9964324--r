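#' Build and validate a pipeline configuration
#'
#' A single configuration drives the whole analysis: inputs (paths, or a
#' synthetic-data block), per-stage parameters, an output directory and a
#' seed. Unknown keys anywhere in the configuration are rejected before any
#' stage runs. Stage blocks set to `NULL` are skipped.
#'
#' @param config A named list, or a path to a YAML file holding one.
#'   Recognized blocks: `out_dir`, `seed`, `bulk` (either `expr` + `meta`
#'   paths or a `synthetic` list of [bulk_sim_config()] arguments),
#'   `diffexpr` (`lfc_threshold`, `alpha`), `modules` (`beta`,
#'   `min_module_size`, `merge_cut_height`, `tree_cut_height`, `traits`),
#'   `index` (`definition` = "cpi"/"cpi_fdx1" or a GMT path, `alpha`,
#'   `normalization`, `by`, `per_cell_line`), `survival` (`records` path or
#'   `synthetic` list, `quantile`), `single_cell` (`mtx`/`genes`/`cells` or
#'   dense `expr` path + `labels` path, or `synthetic` list; `definition`,
#'   `alpha`).
#' @return A validated `PipelineConfig` list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  known <- c("out_dir", "seed", "bulk", "diffexpr", "modules", "index",
             "survival", "single_cell")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  if (is.null(config$out_dir)) stop("config requires out_dir")
  config$seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  config$diffexpr <- merge_block(config$diffexpr, "diffexpr",
                                 list(lfc_threshold = 1, alpha = 0.05))
  config$modules <- merge_block(config$modules, "modules",
                                list(beta = 21, min_module_size = 30,
                                     merge_cut_height = 0.25,
                                     tree_cut_height = 0.99,
                                     traits = "treatment"))
  config$index <- merge_block(config$index, "index",
                              list(definition = "cpi", alpha = 0.25,
                                   normalization = "zscore",
                                   by = "treatment", per_cell_line = TRUE))
  if (!is.null(config$survival)) {
    config$survival <- merge_block(config$survival, "survival",
                                   list(records = NULL, synthetic = NULL,
                                        quantile = 0.5))
  }
  if (!is.null(config$single_cell)) {
    config$single_cell <- merge_block(
      config$single_cell, "single_cell",
      list(mtx = NULL, genes = NULL, cells = NULL, expr = NULL,
           labels = NULL, synthetic = NULL, definition = "cpi",
           alpha = 0.25))
  }
  if (!is.null(config$bulk)) {
    allowed <- c("expr", "meta", "synthetic", "mode")
    bad <- setdiff(names(config$bulk), allowed)
    if (length(bad)) stop("unknown bulk config keys: ",
                          paste(bad, collapse = ", "))
    if (is.null(config$bulk$synthetic)) {
      for (p in c("expr", "meta")) {
        if (is.null(config$bulk[[p]])) stop("bulk config requires ", p)
        if (!file.exists(config$bulk[[p]])) {
          stop("bulk input not found: ", config$bulk[[p]])
        }
      }
    }
  }
  structure(config, class = c("PipelineConfig", "list"))
}

merge_block <- function(given, name, defaults) {
  if (is.null(given)) given <- list()
  bad <- setdiff(names(given), names(defaults))
  if (length(bad)) stop("unknown ", name, " config keys: ",
                        paste(bad, collapse = ", "))
  utils::modifyList(defaults, given)
}

resolve_index_definition <- function(spec, normalization = "zscore") {
  if (inherits(spec, "IndexDefinition")) return(spec)
  if (spec == "cpi") return(cpi_definition("printed", normalization))
  if (spec == "cpi_fdx1") return(cpi_definition("fdx1", normalization))
  if (file.exists(spec)) {
    pair <- read_gene_set_pair(spec)
    return(index_definition(pair$name, pair, normalization))
  }
  stop("unknown index definition: ", spec)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — differential expression per
#' cell line, DEG intersection, co-expression modules with trait
#' correlations, potential indices with group comparisons, and the
#' independent survival and single-cell stages when configured — writing
#' every tabular output as TSV under `out_dir` plus a JSON run manifest
#' (config hash, seed, package version, per-stage row counts). Re-running
#' an identical configuration reproduces every TSV byte-identically.
#'
#' @param config A [pipeline_config()] (or list / YAML path accepted by it).
#' @return Invisibly, a list with the in-memory stage outputs and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "fpicpi",
    version = as.character(utils::packageVersion("fpicpi")),
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    stages = list()
  )
  outputs <- list()

  defn <- resolve_index_definition(cfg$index$definition,
                                   cfg$index$normalization)

  if (!is.null(cfg$bulk)) {
    if (!is.null(cfg$bulk$synthetic)) {
      args <- utils::modifyList(cfg$bulk$synthetic, list())
      if (is.null(args$seed)) args$seed <- cfg$seed
      if (!is.null(args$index_shift)) {
        args$index_shift <- as.data.frame(args$index_shift)
      }
      # embed the index component genes so the scoring stage can run
      if (is.null(args$index_genes)) args$index_genes <- defn$pair
      sim <- simulate_bulk(do.call(bulk_sim_config, args))
      expr <- sim$expr; meta <- sim$meta
      write_expression(expr, file.path(cfg$out_dir, "bulk_expression.tsv"))
      write_table(meta, file.path(cfg$out_dir, "bulk_metadata.tsv"))
      outputs$bulk_truth <- sim$truth
    } else {
      mode <- if (is.null(cfg$bulk$mode)) "log_intensity" else cfg$bulk$mode
      expr <- read_expression(cfg$bulk$expr, mode = mode)
      meta <- read_sample_metadata(cfg$bulk$meta)
    }
    outputs$expr <- expr; outputs$meta <- meta
    manifest$stages$bulk <- list(n_genes = nrow(expr$values),
                                 n_samples = ncol(expr$values))

    # differential expression per cell line + intersection
    lines <- unique(meta$cell_line)
    de <- lapply(lines, function(cl) {
      moderated_t_test(expr, meta, cell_line = cl,
                       lfc_threshold = cfg$diffexpr$lfc_threshold,
                       alpha = cfg$diffexpr$alpha)
    })
    names(de) <- lines
    for (cl in lines) {
      write_table(de[[cl]], file.path(cfg$out_dir,
                                      paste0("diffexpr_", cl, ".tsv")))
    }
    common <- if (length(lines) >= 2L) intersect_degs(de) else character(0)
    write_table(data.frame(gene_id = common),
                file.path(cfg$out_dir, "common_degs.tsv"))
    outputs$diffexpr <- de; outputs$common_degs <- common
    manifest$stages$diffexpr <- list(
      degs_per_line = lapply(de, function(r) sum(r$is_deg)),
      n_common = length(common))

    # co-expression modules
    params <- module_detection_params(
      beta = cfg$modules$beta,
      min_module_size = cfg$modules$min_module_size,
      merge_cut_height = cfg$modules$merge_cut_height,
      tree_cut_height = cfg$modules$tree_cut_height)
    assignment <- detect_modules(expr, params)
    write_table(data.frame(gene_id = names(assignment$modules),
                           module = unname(assignment$modules)),
                file.path(cfg$out_dir, "module_assignment.tsv"))
    if (ncol(assignment$eigengenes) > 0L) {
      write_table(data.frame(sample_id = rownames(assignment$eigengenes),
                             assignment$eigengenes, check.names = FALSE),
                  file.path(cfg$out_dir, "module_eigengenes.tsv"))
      traits <- intersect(cfg$modules$traits, colnames(meta))
      if (length(traits)) {
        mt <- module_trait(assignment, meta, traits)
        write_table(mt, file.path(cfg$out_dir, "module_trait.tsv"))
        outputs$module_trait <- mt
      }
    }
    outputs$modules <- assignment
    manifest$stages$modules <- list(
      n_modules = length(setdiff(unique(assignment$modules), "grey")),
      n_grey = sum(assignment$modules == "grey"))

    # potential indices per cell line (or jointly)
    score_one <- function(sub_expr, sub_meta, tag) {
      res <- compute_index(sub_expr, defn, alpha = cfg$index$alpha,
                           meta = sub_meta)
      write_table(res, file.path(cfg$out_dir,
                                 paste0("index_", tag, ".tsv")))
      cmp <- compare_groups(res, sub_meta, by = cfg$index$by)
      write_table(cmp, file.path(cfg$out_dir,
                                 paste0("index_comparison_", tag, ".tsv")))
      heat <- index_heatmap_table(sub_expr, defn)
      write_table(heat, file.path(cfg$out_dir,
                                  paste0("index_heatmap_", tag, ".tsv")))
      list(result = res, comparison = cmp)
    }
    if (isTRUE(cfg$index$per_cell_line) && "cell_line" %in% colnames(meta)) {
      idx <- lapply(lines, function(cl) {
        sel <- meta$cell_line == cl
        sub <- expression_matrix(expr$values[, meta$sample_id[sel],
                                             drop = FALSE], expr$mode)
        score_one(sub, meta[sel, , drop = FALSE], cl)
      })
      names(idx) <- lines
    } else {
      idx <- list(all = score_one(expr, meta, "all"))
    }
    outputs$index <- idx
    manifest$stages$index <- list(
      groups = names(idx),
      n_samples = vapply(idx, function(x) nrow(x$result), integer(1)))
  }

  if (!is.null(cfg$survival)) {
    if (!is.null(cfg$survival$synthetic)) {
      args <- cfg$survival$synthetic
      if (is.null(args$seed)) args$seed <- cfg$seed
      rec <- simulate_survival(do.call(survival_sim_config, args))
    } else {
      rec <- read_survival_records(cfg$survival$records)
    }
    rec <- dichotomize_by_expression(rec, cfg$survival$quantile)
    for (g in c("low", "high")) {
      write_table(km_fit(rec, g),
                  file.path(cfg$out_dir, paste0("km_", g, ".tsv")))
    }
    lr <- logrank_test(rec)
    write_table(data.frame(chi_sq = lr$chi_sq, df = lr$df, p = lr$p),
                file.path(cfg$out_dir, "logrank.tsv"))
    outputs$survival <- list(records = rec, logrank = lr)
    manifest$stages$survival <- list(n_subjects = nrow(rec),
                                     n_events = sum(rec$event))
  }

  if (!is.null(cfg$single_cell)) {
    sc_defn <- resolve_index_definition(cfg$single_cell$definition,
                                        cfg$index$normalization)
    if (!is.null(cfg$single_cell$synthetic)) {
      args <- cfg$single_cell$synthetic
      if (is.null(args$seed)) args$seed <- cfg$seed
      if (!is.null(args$subcluster_shift)) {
        args$subcluster_shift <- as.data.frame(args$subcluster_shift)
      }
      if (is.null(args$index_genes)) args$index_genes <- sc_defn$pair
      sim <- simulate_single_cell(do.call(single_cell_sim_config, args))
      sc_expr <- sim$expr; sc_meta <- sim$meta
      outputs$single_cell_truth <- sim$truth
    } else if (!is.null(cfg$single_cell$mtx)) {
      sc_expr <- read_expression(cfg$single_cell$mtx, mode = "counts",
                                 genes_path = cfg$single_cell$genes,
                                 samples_path = cfg$single_cell$cells)
      sc_meta <- read_sample_metadata(cfg$single_cell$labels)
    } else {
      sc_expr <- read_expression(cfg$single_cell$expr, mode = "counts")
      sc_meta <- read_sample_metadata(cfg$single_cell$labels)
    }
    cells <- score_cells(sc_expr, sc_defn, alpha = cfg$single_cell$alpha,
                         meta = sc_meta)
    write_table(cells, file.path(cfg$out_dir, "cell_index.tsv"))
    cmp <- compare_subclusters(cells)
    write_table(cmp$summary, file.path(cfg$out_dir,
                                       "subcluster_summary.tsv"))
    if (!is.null(cmp$pairwise)) {
      write_table(cmp$pairwise, file.path(cfg$out_dir,
                                          "subcluster_pairwise.tsv"))
    }
    outputs$cell_index <- cells; outputs$subclusters <- cmp
    manifest$stages$single_cell <- list(
      n_cells = nrow(cells),
      n_subclusters = nrow(cmp$summary),
      omnibus_p = cmp$omnibus$p)
  }

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  outputs$manifest <- manifest
  invisible(outputs)
}

# md5 of the canonical YAML rendering of the config
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  att <- cfg
  class(att) <- "list"
  yaml::write_yaml(att, tmp)
  unname(tools::md5sum(tmp))
}
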
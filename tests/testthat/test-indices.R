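test_that("built-in CPI definitions carry the component gene lists", {
  d <- cpi_definition()
  expect_setequal(d$pair$positive$genes,
                  c("PDX1", "LIAS", "LIPT1", "DLD", "DLAT", "PDHA1", "PDHB"))
  expect_setequal(d$pair$negative$genes, c("MTF1", "GLS", "CDKN2A"))
  d2 <- cpi_definition("fdx1")
  expect_true("FDX1" %in% d2$pair$positive$genes)
  expect_false("PDX1" %in% d2$pair$positive$genes)
  expect_error(gene_set_pair("X", c("A", "B"), c("B", "C")), "overlap")
})

test_that("symmetric component placement gives a zero index", {
  # ranks pos1 > neg1 > neg2 > pos2 make both integrated CDFs equal (alpha=0)
  x <- matrix(rep(c(4, 3, 2, 1), 3), 4,
              dimnames = list(c("P1", "N1", "N2", "P2"), paste0("s", 1:3)))
  defn <- index_definition("SYM",
                           gene_set_pair("SYM", c("P1", "P2"), c("N1", "N2")))
  res <- compute_index(expression_matrix(x, "log_intensity"), defn, alpha = 0)
  expect_equal(res$raw_difference, rep(0, 3))
  expect_equal(res$index_value, rep(0, 3))
})

test_that("planted positive-component shift raises the treated index", {
  cfg <- cpi_shift_config(seed = 80)
  sim <- simulate_bulk(cfg)
  res <- compute_index(sim$expr, cpi_definition(), meta = sim$meta)
  expect_gt(mean(res$index_value[res$treatment == "curcumin"]),
            mean(res$index_value[res$treatment == "control"]))
})

test_that("raw index is monotone in component-gene expression", {
  set.seed(81)
  defn <- cpi_definition()
  for (i in 1:20) {
    e <- random_expr(60, 2, seed = 200 + i)
    gids <- gene_ids(e)
    gids[1:7] <- defn$pair$positive$genes
    gids[8:10] <- defn$pair$negative$genes
    e <- expression_matrix(e$values, "log_intensity", gene_ids = gids)
    base <- compute_index(e, defn, alpha = 0)$raw_difference
    # bump one positive gene up in one sample
    x2 <- e$values
    g <- sample(1:7, 1)
    x2[g, 1] <- x2[g, 1] + stats::runif(1, 0.5, 5)
    up <- compute_index(expression_matrix(x2, "log_intensity"),
                        defn, alpha = 0)$raw_difference
    expect_gte(up[1] - base[1], -1e-12)
    # bump one negative gene up in one sample
    x3 <- e$values
    g <- sample(8:10, 1)
    x3[g, 2] <- x3[g, 2] + stats::runif(1, 0.5, 5)
    dn <- compute_index(expression_matrix(x3, "log_intensity"),
                        defn, alpha = 0)$raw_difference
    expect_lte(dn[2] - base[2], 1e-12)
  }
})

test_that("sample permutation permutes the index identically", {
  sim <- simulate_bulk(bulk_sim_config(n_genes = 200, seed = 82))
  defn <- index_definition("S", gene_set_pair(
    "S", gene_ids(sim$expr)[1:5], gene_ids(sim$expr)[6:10]))
  res <- compute_index(sim$expr, defn)
  perm <- sample(ncol(sim$expr$values))
  e2 <- expression_matrix(sim$expr$values[, perm], "log_intensity")
  res2 <- compute_index(e2, defn)
  expect_equal(res2$index_value[match(res$sample_id, res2$sample_id)],
               res$index_value)
})

test_that("missing positive components are a named error", {
  e <- random_expr(20, 3, seed = 83)
  expect_error(compute_index(e, cpi_definition()), "PDX1")
})

test_that("group comparison fixtures and guards", {
  res <- data.frame(sample_id = paste0("s", 1:6), raw_difference = 1:6,
                    index_value = c(1, 2, 3, 4, 5, 6),
                    treatment = rep(c("control", "curcumin"), each = 3))
  cmp <- compare_groups(res, by = "treatment")
  expect_equal(cmp$p, 0.1)
  expect_identical(cmp$significance_code, "ns")
  res$index_value <- rep(c(1, 2, 3), 2)
  expect_equal(compare_groups(res, by = "treatment")$p, 1)
  res$treatment <- c("a", "a", "a", "a", "a", "b")
  expect_error(compare_groups(res, by = "treatment"), "< 2 samples")
})

test_that("heatmap table slices, annotates and standardizes components", {
  cfg <- cpi_shift_config(seed = 84, n_genes = 300)
  sim <- simulate_bulk(cfg)
  defn <- cpi_definition()
  tab <- index_heatmap_table(sim$expr, defn)
  expect_lte(nrow(tab), 10L)
  expect_setequal(unique(tab$component), c("positive", "negative"))
  vals <- as.matrix(tab[, -(1:2)])
  expect_equal(unname(rowMeans(vals)), rep(0, nrow(tab)), tolerance = 1e-12)
  # absent components are listed in the sidecar attribute
  sub <- expression_matrix(
    sim$expr$values[setdiff(gene_ids(sim$expr), "PDHB"), ], "log_intensity")
  tab2 <- index_heatmap_table(sub, defn)
  expect_identical(attr(tab2, "missing_genes"), "PDHB")
})
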
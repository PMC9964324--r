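make_two_group <- function(x) {
  n <- ncol(x)
  meta <- sample_metadata(colnames(x), cell_line = "PLC",
                          treatment = rep(c("control", "curcumin"),
                                          each = n / 2))
  list(expr = expression_matrix(x, "log_intensity"), meta = meta)
}

test_that("flat genes are never called and limits behave", {
  set.seed(70)
  x <- matrix(stats::rnorm(50 * 6, 7, 0.5), 50,
              dimnames = list(sprintf("G%02d", 1:50), paste0("s", 1:6)))
  x[1, ] <- 5  # identical in both groups
  d <- make_two_group(x)
  de <- moderated_t_test(d$expr, d$meta)
  expect_equal(de$log2fc[1], 0)
  expect_false(de$is_deg[1])
  # d0 = Inf limit: every t uses the common prior variance
  de_inf <- moderated_t_test(d$expr, d$meta, d0 = Inf)
  s0 <- attr(de_inf, "s0_sq")
  expect_equal(de_inf$t_mod,
               de_inf$log2fc / sqrt(s0 * (1 / 3 + 1 / 3)))
  # d0 = 0 recovers the ordinary pooled two-sample t
  de0 <- suppressMessages(moderated_t_test(d$expr, d$meta, d0 = 0))
  tt <- apply(x[2:50, ], 1L, function(v) {
    unname(stats::t.test(v[4:6], v[1:3], var.equal = TRUE)$statistic)
  })
  expect_equal(de0$t_mod[2:50], unname(tt), tolerance = 1e-10)
})

test_that("moderated t agrees with an independent empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(71)
  n_g <- 400
  # heterogeneous gene variances so the prior df is finite
  x <- matrix(stats::rnorm(n_g * 6, 7, rep(exp(stats::rnorm(n_g, 0, 0.5)), 6)),
              n_g, dimnames = list(sprintf("G%03d", 1:n_g), paste0("s", 1:6)))
  d <- make_two_group(x)
  de <- moderated_t_test(d$expr, d$meta)
  design <- stats::model.matrix(~ rep(0:1, each = 3))
  fit <- limma::eBayes(limma::lmFit(x, design))
  expect_true(is.finite(attr(de, "d0")))
  expect_equal(attr(de, "d0"), fit$df.prior, tolerance = 1e-8)
  expect_equal(de$t_mod, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(de$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("DE result invariants hold on simulated data", {
  sim <- simulate_bulk(bulk_sim_config(n_genes = 500, de_fraction = 0.1,
                                       seed = 72))
  de <- moderated_t_test(sim$expr, sim$meta, cell_line = "KMCH")
  expect_identical(de$is_deg, abs(de$log2fc) > 1 & de$p_adj < 0.05)
  expect_identical(de$direction == "up", de$is_deg & de$log2fc > 0)
  expect_identical(de$direction == "down", de$is_deg & de$log2fc < 0)
  expect_true(all(de$p_adj >= de$p))
  ord <- order(de$p)
  expect_true(all(diff(de$p_adj[ord]) >= 0))
})

test_that("group size and mode requirements are enforced", {
  e <- random_expr(20, 4, seed = 73)
  meta <- sample_metadata(sample_ids(e), cell_line = "PLC",
                          treatment = c("control", rep("curcumin", 3)))
  expect_error(moderated_t_test(e, meta), ">= 2 samples")
  counts <- expression_matrix(matrix(1:8, 2,
                                     dimnames = list(c("A", "B"),
                                                     paste0("s", 1:4))) + 0,
                              "counts")
  expect_error(
    moderated_t_test(counts, sample_metadata(paste0("s", 1:4),
                                             treatment = rep(c("control",
                                                               "curcumin"),
                                                             2))),
    "log-intensity")
})

test_that("DEG intersection is membership-based and sorted", {
  mk <- function(genes, deg) {
    r <- data.frame(gene_id = genes, log2fc = 0, t_mod = 0, p = 1, p_adj = 1,
                    is_deg = genes %in% deg, direction = "none")
    class(r) <- c("DEResult", "data.frame")
    r
  }
  genes <- c("A", "B", "C", "D")
  expect_identical(intersect_degs(list(mk(genes, c("A", "B")),
                                       mk(genes, c("B", "C")))), "B")
  expect_identical(intersect_degs(list(mk(genes, "A"), mk(genes, "C"))),
                   character(0))
  expect_error(intersect_degs(list(mk(genes, "A"))), ">= 2")
})

test_that("common planted DE genes are recovered across three cell lines", {
  sim <- simulate_bulk(bulk_sim_config(n_genes = 800, de_fraction = 0.05,
                                       de_log2fc_range = c(2, 2), seed = 74))
  de <- lapply(unique(sim$meta$cell_line), function(cl) {
    moderated_t_test(sim$expr, sim$meta, cell_line = cl)
  })
  common <- intersect_degs(de)
  sens <- mean(sim$truth$de_genes %in% common)
  expect_gte(sens, 0.9)
})
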
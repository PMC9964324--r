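test_that("TOM matches the closed form and the triple-loop oracle", {
  # two genes, no third vertex: TOM_12 = a / (a + 1 - a) = a
  for (a12 in c(0.2, 0.5, 0.9)) {
    a <- matrix(c(0, a12, a12, 0), 2)
    expect_equal(tom_similarity(a)[1, 2], a12)
  }
  set.seed(90)
  for (i in 1:5) {
    r <- matrix(stats::runif(20 * 20), 20)
    a <- (r + t(r)) / 2
    diag(a) <- 0
    expect_equal(tom_similarity(a), brute_tom(a), tolerance = 1e-12)
  }
})

test_that("adjacency and TOM live in the unit interval", {
  e <- random_expr(30, 8, seed = 91)
  a <- adjacency_matrix(e, 6)
  expect_true(all(a >= 0 & a <= 1))
  tom <- tom_similarity(a)
  expect_true(all(tom >= -1e-12 & tom <= 1 + 1e-12))
  expect_equal(unname(diag(tom)), rep(1, 30))
})

test_that("scale-free data meets the fit target at its generating power", {
  set.seed(7)
  n_g <- 300; n_s <- 2000; beta <- 6
  u <- (1 - stats::runif(n_g))^(-1 / 1)          # Pareto-tailed loadings
  l <- pmin(u / max(u), 1)^(1 / beta)
  f <- stats::rnorm(n_s)
  x <- l %o% f + sqrt(1 - l^2) * matrix(stats::rnorm(n_g * n_s), n_g)
  rownames(x) <- sprintf("G%04d", seq_len(n_g))
  colnames(x) <- sprintf("s%04d", seq_len(n_s))
  sf <- pick_soft_threshold(expression_matrix(x, "log_intensity"),
                            candidates = beta, target_r2 = 0.85)
  expect_gte(sf$fit$r_squared, 0.9)
  expect_true(sf$target_met)
  expect_equal(sf$selected_beta, beta)
})

test_that("independent noise falls back to argmax with a flag", {
  xn <- matrix(stats::rnorm(100 * 20), 100,
               dimnames = list(sprintf("G%03d", 1:100),
                               sprintf("s%02d", 1:20)))
  xn[1, ] <- 3  # constant gene must be dropped, not crash the fit
  expect_warning(
    sf <- pick_soft_threshold(expression_matrix(xn, "log_intensity"),
                              candidates = 1:6),
    "constant")
  expect_false(sf$target_met)
  expect_equal(sf$selected_beta, sf$fit$beta[which.max(sf$fit$r_squared)])
  # single candidate is always selected
  sf1 <- suppressWarnings(
    pick_soft_threshold(expression_matrix(xn, "log_intensity"),
                        candidates = 21))
  expect_equal(sf1$selected_beta, 21)
})

test_that("planted modules are recovered and labels partition the genes", {
  skip_if_not_installed("mclust")
  cfg <- bulk_sim_config(
    n_genes = 450, seed = 11,
    planted_modules = list(list(size = 60, strength = 0.85),
                           list(size = 50, strength = 0.85),
                           list(size = 40, strength = 0.85)))
  sim <- simulate_bulk(cfg)
  asg <- detect_modules(sim$expr, module_detection_params())
  expect_equal(sum(asg$sizes), 450)
  expect_true(all(asg$sizes[setdiff(names(asg$sizes), "grey")] >= 30))
  keep <- asg$modules != "grey"
  truth <- sim$truth$module_label[names(asg$modules)]
  ari <- mclust::adjustedRandIndex(asg$modules[keep], truth[keep])
  expect_gte(ari, 0.8)
})

test_that("modules driven by one latent factor merge", {
  set.seed(92)
  n_s <- 18
  f <- stats::rnorm(n_s)
  block <- function(n) t(replicate(n, sqrt(0.85) * f +
                                     sqrt(0.15) * stats::rnorm(n_s)))
  x <- rbind(block(40), block(40), matrix(stats::rnorm(200 * n_s), 200))
  rownames(x) <- sprintf("G%03d", seq_len(nrow(x)))
  colnames(x) <- sprintf("s%02d", seq_len(n_s))
  asg <- detect_modules(expression_matrix(x, "log_intensity"),
                        module_detection_params())
  mods <- setdiff(unique(asg$modules), "grey")
  expect_length(mods, 1L)
  expect_equal(unname(asg$sizes[mods]), 80L, ignore_attr = TRUE)
})

test_that("eigengenes maximize explained variance (Rayleigh property)", {
  cfg <- bulk_sim_config(n_genes = 200, seed = 93,
                         planted_modules = list(list(size = 50,
                                                     strength = 0.8)))
  sim <- simulate_bulk(cfg)
  asg <- detect_modules(sim$expr, module_detection_params())
  m <- setdiff(unique(asg$modules), "grey")[1L]
  sub <- sim$expr$values[names(asg$modules)[asg$modules == m], ]
  subs <- t(scale(t(sub)))
  v <- asg$eigengenes[, m]
  expect_equal(sum(v^2), 1)
  var_eigen <- sum((subs %*% v)^2)
  set.seed(94)
  for (i in 1:20) {
    probe <- stats::rnorm(ncol(subs))
    probe <- probe / sqrt(sum(probe^2))
    expect_gte(var_eigen + 1e-8, sum((subs %*% probe)^2))
  }
})

test_that("module-trait correlation identifies the responsive module", {
  set.seed(95)
  n_s <- 18
  treatment <- rep(c("control", "curcumin"), each = n_s / 2)
  tvec <- as.numeric(treatment == "curcumin")
  resp <- t(replicate(40, 2 * tvec + 0.5 * stats::rnorm(n_s)))
  other_f <- stats::rnorm(n_s)
  other <- t(replicate(40, other_f + 0.5 * stats::rnorm(n_s)))
  x <- rbind(resp, other, matrix(stats::rnorm(120 * n_s), 120)) + 7
  rownames(x) <- sprintf("G%03d", seq_len(nrow(x)))
  colnames(x) <- sprintf("s%02d", seq_len(n_s))
  e <- expression_matrix(x, "log_intensity")
  meta <- sample_metadata(colnames(x), treatment = treatment)
  asg <- detect_modules(e, module_detection_params())
  mt <- module_trait(asg, meta, "treatment")
  resp_modules <- unique(asg$modules[1:40])
  best <- mt$module[which.max(abs(mt$r))]
  expect_true(best %in% resp_modules)
  # eigengene equal to the trait gives |r| = 1
  direct <- pearson_test(tvec, tvec)
  expect_equal(direct$statistic, 1)
  # constant trait is degenerate, not an error
  meta$flat <- "x"
  mt2 <- module_trait(asg, meta, "flat")
  expect_true(all(mt2$degenerate))
  expect_true(all(mt2$p == 1))
})
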
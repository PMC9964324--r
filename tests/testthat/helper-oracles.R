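# Independent brute-force oracles used to verify the package's engines.
# These deliberately use explicit position loops, never the vectorized code
# paths they check.

# ssGSEA enrichment score by explicit position loop
brute_ssgsea <- function(x, set_genes, alpha) {
  ids <- names(x)
  ord <- order(-x, ids, method = "radix")
  ids <- ids[ord]
  n <- length(ids)
  r_abs <- n:1
  in_set <- logical(n)
  for (j in seq_len(n)) in_set[j] <- ids[j] %in% set_genes
  denom_in <- 0
  for (j in seq_len(n)) if (in_set[j]) denom_in <- denom_in + r_abs[j]^alpha
  n_out <- n - sum(in_set)
  es <- 0
  for (i in seq_len(n)) {
    p_in <- 0
    n_o <- 0
    for (j in seq_len(i)) {
      if (in_set[j]) p_in <- p_in + r_abs[j]^alpha else n_o <- n_o + 1
    }
    es <- es + p_in / denom_in - (if (n_out > 0) n_o / n_out else 0)
  }
  es
}

# Benjamini-Hochberg by the definition: q_(i) = min_{j >= i} p_(j) * m / j
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, p[ord[j]] * m / j)
    q[ord[i]] <- min(best, 1)
  }
  q
}

# topological overlap by triple loop
brute_tom <- function(a) {
  n <- nrow(a)
  k <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) k[i] <- k[i] + a[i, j]
  tom <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { tom[i, j] <- 1; next }
      l <- 0
      for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  tom
}

# exact two-sided rank-sum p by full enumeration of group assignments
enum_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(na)])
  idx_sets <- utils::combn(n, na)
  ws <- apply(idx_sets, 2L, function(ix) sum(ranks[ix]))
  p_low <- mean(ws <= w_obs)
  p_high <- mean(ws >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

# small labelled matrix with reproducible values
random_expr <- function(n_genes, n_samples, seed, mode = "log_intensity") {
  set.seed(seed)
  x <- matrix(stats::rnorm(n_genes * n_samples, 7, 1), n_genes)
  rownames(x) <- sprintf("G%03d", seq_len(n_genes))
  colnames(x) <- sprintf("s%02d", seq_len(n_samples))
  expression_matrix(x, mode)
}

# planted +2 SD positive-component shift in every cell line's treated group
cpi_shift_config <- function(seed, n_genes = 1000L, shift = 2) {
  defn <- cpi_definition()
  shift_tab <- data.frame(
    cell_line = rep(c("PLC", "KMCH", "Huh7"), each = 1L),
    treatment = "curcumin", component = "positive", shift = shift,
    stringsAsFactors = FALSE)
  bulk_sim_config(n_genes = n_genes, index_shift = shift_tab,
                  index_genes = defn$pair, seed = seed)
}
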
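# Shared in-code fixtures for the test suite. Everything is generated at
# test time; seeds are fixed per call site.

# small NB count matrix with optional group-B fold change on a gene subset
make_counts <- function(n_genes = 100, n_per_group = 5, mu_log = log(100),
                        dispersion = 0.1, lfc_genes = integer(0),
                        log2fc = 0, seed = 1) {
  set.seed(seed)
  mu <- exp(stats::rnorm(n_genes, mu_log, 1))
  mu_b <- mu
  mu_b[lfc_genes] <- mu[lfc_genes] * 2^log2fc
  cnt <- cbind(
    matrix(stats::rnbinom(n_genes * n_per_group, mu = rep(mu, n_per_group),
                          size = 1 / dispersion), nrow = n_genes),
    matrix(stats::rnbinom(n_genes * n_per_group, mu = rep(mu_b, n_per_group),
                          size = 1 / dispersion), nrow = n_genes))
  dimnames(cnt) <- list(sprintf("g%03d", seq_len(n_genes)),
                        sprintf("s%02d", seq_len(2 * n_per_group)))
  cnt
}

group_ids <- function(cnt, which = c("a", "b")) {
  which <- match.arg(which)
  n <- ncol(cnt) / 2
  if (which == "a") colnames(cnt)[seq_len(n)]
  else colnames(cnt)[n + seq_len(n)]
}

# samples x genes expression with correlated blocks and noise background
make_block_expr <- function(n_samples = 20, block_sizes = c(50, 50),
                            n_background = 0, block_cor_sd = 0.3,
                            seed = 1) {
  set.seed(seed)
  blocks <- lapply(seq_along(block_sizes), function(b) {
    f <- stats::rnorm(n_samples)
    sapply(seq_len(block_sizes[b]), function(i)
      f + stats::rnorm(n_samples, sd = block_cor_sd))
  })
  x <- do.call(cbind, blocks)
  if (n_background > 0)
    x <- cbind(x, matrix(stats::rnorm(n_samples * n_background),
                         n_samples))
  colnames(x) <- sprintf("gene%04d", seq_len(ncol(x)))
  rownames(x) <- sprintf("s%02d", seq_len(n_samples))
  x
}

# brute-force O(n^3) topological overlap used as the oracle
tom_oracle <- function(a) {
  n <- nrow(a)
  k <- colSums(a) - diag(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- 0
    for (u in seq_len(n)) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
    tom[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# step-up BH coded independently of stats::p.adjust
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  adj
}
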
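test_that("signed-hybrid adjacency zeroes negative correlation and powers positives", {
  # vectors with exact sample correlations +/-0.5 built from an
  # orthogonal design
  z1 <- c(1, 1, -1, -1)
  z2 <- c(1, -1, 1, -1)
  expr <- cbind(g1 = z1, g2 = 0.5 * z1 + sqrt(0.75) * z2,
                g3 = -0.5 * z1 - sqrt(0.75) * z2, g4 = z1)
  a <- adjacency_signed_hybrid(expr, beta = 8)
  expect_equal(a["g1", "g2"], 0.5^8)       # 0.00390625
  expect_equal(a["g1", "g3"], 0)           # negative correlation
  expect_equal(a["g1", "g4"], 1)           # perfect correlation
  expect_equal(diag(a), c(g1 = 1, g2 = 1, g3 = 1, g4 = 1))
  expect_true(isSymmetric(a))

  expr_const <- cbind(expr, g5 = rep(2, 4))
  expect_error(adjacency_signed_hybrid(expr_const, 8), "g5")
})

test_that("topological overlap matches the O(n^3) oracle and its bounds", {
  set.seed(20)
  for (n in c(4, 10, 50)) {
    a <- matrix(runif(n * n), n)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    tom <- tom_similarity(a)
    expect_lt(max(abs(tom - tom_oracle(a))), 1e-10)
    expect_true(all(tom >= -1e-12 & tom <= 1 + 1e-12))
    expect_true(isSymmetric(tom))
  }
  # two fully linked nodes sharing an identical (binary) neighborhood
  # overlap completely
  a <- diag(4)
  a[1, 2] <- a[2, 1] <- 1
  a[1, 3] <- a[3, 1] <- a[2, 3] <- a[3, 2] <- 1
  tom <- tom_similarity(a)
  expect_equal(tom[1, 2], 1)
  # disconnected pair with no shared neighbor has zero overlap
  b <- diag(4)
  expect_equal(tom_similarity(b)[1, 2], 0)
  bad <- matrix(runif(9), 3); bad[1, 2] <- 2
  expect_error(tom_similarity((bad + t(bad)) / 2), "\\[0, 1\\]")
  expect_error(tom_similarity(matrix(runif(9), 3)), "symmetric")
})

test_that("module detection separates planted blocks and greys small ones", {
  expr <- make_block_expr(n_samples = 30, block_sizes = c(50, 50),
                          seed = 2)
  a <- adjacency_signed_hybrid(expr, beta = 6)
  mods <- detect_modules(1 - tom_similarity(a), min_module_size = 30,
                         cut_height = 0.99)
  non_grey <- unique(mods[mods != "grey"])
  expect_equal(length(non_grey), 2)
  b1 <- colnames(expr)[1:50]
  expect_equal(length(unique(mods[b1])), 1)  # block 1 stays together

  # a 20-gene block cannot reach the minimum module size
  expr_small <- make_block_expr(n_samples = 30, block_sizes = 20,
                                n_background = 40, seed = 3)
  mods_small <- detect_modules(
    1 - tom_similarity(adjacency_signed_hybrid(expr_small, 6)),
    min_module_size = 30)
  expect_true(all(mods_small[colnames(expr_small)[1:20]] == "grey"))

  # permuting gene order leaves the partition invariant up to labels
  perm <- sample(ncol(expr))
  mods_p <- detect_modules(
    1 - tom_similarity(adjacency_signed_hybrid(expr[, perm], 6)),
    min_module_size = 30)
  split_a <- split(names(mods), mods)
  split_b <- split(names(mods_p), mods_p)
  expect_setequal(vapply(split_a, function(g) paste(sort(g), collapse = ","),
                         ""),
                  vapply(split_b, function(g) paste(sort(g), collapse = ","),
                         ""))
})

test_that("eigengenes are unit-norm, sign-oriented, dominant principal components", {
  # identical genes: eigengene is the standardized common profile
  set.seed(30)
  f <- rnorm(15)
  expr_same <- matrix(rep(f, 5), 15, dimnames = list(NULL, paste0("g", 1:5)))
  mods <- stats::setNames(rep("blue", 5), paste0("g", 1:5))
  eig <- module_eigengenes(expr_same, mods)
  expect_equal(eig$var_explained[["MEblue"]], 1)
  me <- eig$eigengenes[, "MEblue"]
  expect_equal(sum(me^2), 1)
  expect_equal(abs(stats::cor(me, f)), 1)
  expect_gte(stats::cor(me, f), 0)  # oriented with the module average

  # 3-gene toy block vs an independent power-iteration eigensolver
  expr3 <- make_block_expr(n_samples = 12, block_sizes = 3, seed = 31)
  mods3 <- stats::setNames(rep("red", 3), colnames(expr3))
  me3 <- module_eigengenes(expr3, mods3)$eigengenes[, "MEred"]
  z <- scale(expr3)
  m <- z %*% t(z)
  v <- rep(1, nrow(m))
  for (i in 1:500) { v <- m %*% v; v <- v / sqrt(sum(v^2)) }
  expect_lt(min(sum((me3 - v)^2), sum((me3 + v)^2)), 1e-8)

  # eigengene beats random unit summaries on variance explained
  expr_b <- make_block_expr(n_samples = 20, block_sizes = 40, seed = 32)
  mods_b <- stats::setNames(rep("cyan", 40), colnames(expr_b))
  eg <- module_eigengenes(expr_b, mods_b)
  zb <- scale(expr_b)
  ve_me <- sum(stats::cor(eg$eigengenes[, 1], zb)^2)
  set.seed(33)
  for (r in 1:100) {
    u <- rnorm(20); u <- u / sqrt(sum(u^2))
    expect_lte(sum(stats::cor(u, zb)^2), ve_me + 1e-8)
  }
})

test_that("modules merge exactly when eigengene correlation exceeds 0.80", {
  set.seed(40)
  n <- 24
  f1 <- rnorm(n)
  f2 <- 0.95 * scale(f1)[, 1] + sqrt(1 - 0.95^2) * rnorm(n)  # cor ~ 0.95
  f3 <- rnorm(n)                                             # unrelated
  mk <- function(f, sz, pre) {
    x <- sapply(seq_len(sz), function(i) f + rnorm(n, sd = 0.1))
    colnames(x) <- paste0(pre, seq_len(sz))
    x
  }
  expr <- cbind(mk(f1, 35, "a"), mk(f2, 31, "b"), mk(f3, 33, "c"))
  mods <- stats::setNames(c(rep("blue", 35), rep("red", 31),
                            rep("green", 33)), colnames(expr))
  merged <- merge_modules(expr, mods, cut_height = 0.20)
  # the two highly correlated modules collapse, the unrelated one stays
  expect_equal(length(unique(merged$modules)), 2)
  expect_equal(length(unique(merged$modules[1:66])), 1)
  me <- merged$eigengenes$eigengenes
  cors <- stats::cor(me)
  expect_true(all(cors[upper.tri(cors)] <= 0.80))
})

test_that("module-trait correlation matches the t-test and a permutation oracle", {
  set.seed(50)
  n <- 20
  me <- cbind(ME1 = rnorm(n))
  traits <- data.frame(exact = me[, 1], const = rep(1, n))
  expect_warning(mt <- module_trait_correlation(me, traits), "constant")
  row <- mt[mt$trait == "exact", ]
  expect_equal(row$cor, 1)
  expect_lt(row$p, 1e-20)
  expect_true(is.na(mt$cor[mt$trait == "const"]))

  # r ~ 0.7: analytic p agrees with a permutation null
  tr <- 0.7 * scale(me[, 1])[, 1] + sqrt(1 - 0.49) * rnorm(n)
  mt2 <- module_trait_correlation(me, data.frame(tr = tr))
  r_obs <- abs(mt2$cor[1])
  perm <- replicate(1e5, abs(stats::cor(me[, 1], sample(tr))))
  p_perm <- (1 + sum(perm >= r_obs)) / (1e5 + 1)
  expect_lt(abs(mt2$p[1] - p_perm), 3 * sqrt(p_perm * (1 - p_perm) / 1e5) +
              2e-4)
})

test_that("kME, gene significance and intramodular connectivity behave", {
  expr <- make_block_expr(n_samples = 20, block_sizes = c(40, 40),
                          seed = 60)
  mods <- stats::setNames(c(rep("blue", 40), rep("brown", 40)),
                          colnames(expr))
  eig <- module_eigengenes(expr, mods)$eigengenes
  trait <- rnorm(20)
  gstat <- gene_statistics(expr, eig, trait)
  # a gene equal to its eigengene has kME 1
  expr2 <- cbind(expr, me_copy = eig[, "MEblue"])
  mods2 <- c(mods, me_copy = "blue")
  g2 <- gene_statistics(expr2, eig, trait)
  expect_equal(unname(g2$kme["me_copy", "MEblue"]), 1)
  # cross-module kME on independent blocks is near zero
  expect_lt(mean(abs(gstat$kme[1:40, "MEbrown"])), 0.25)
  expect_true(all(gstat$primary_module[1:40] == "blue"))

  a <- adjacency_signed_hybrid(expr, 6)
  kw <- intramodular_connectivity(a, mods)
  idx <- which(mods == "blue")
  for (g in names(mods)[c(1, 17)])
    expect_equal(kw[[g]], sum(a[g, setdiff(names(idx), g)]))
  # complete module of identical genes: kWithin = size - 1
  same <- matrix(rep(rnorm(10), 5), 10,
                 dimnames = list(NULL, paste0("s", 1:5)))
  a_same <- adjacency_signed_hybrid(same, 6)
  kw_same <- intramodular_connectivity(
    a_same, stats::setNames(rep("red", 5), paste0("s", 1:5)))
  expect_equal(unname(kw_same), rep(4, 5))
  # grey genes get missing connectivity
  kw_grey <- intramodular_connectivity(
    a_same, stats::setNames(c(rep("red", 4), "grey"), paste0("s", 1:5)))
  expect_true(is.na(kw_grey[["s5"]]))
})

test_that("scale-free fit index is 1 on an exact power law and the scan recommends", {
  # degrees at the centers 1..10 of the 10 equal-width bins with
  # frequency exactly proportional to 1/k: a perfect log-log line
  k <- rep(1:10, times = 2520 / (1:10))
  fit <- scale_free_fit(k, n_bins = 10)
  expect_lt(abs(fit$fit_index - 1), 1e-6)
  expect_equal(fit$slope, -1, tolerance = 1e-8)
  expect_warning(scale_free_fit(c(1, 1, 1, 2, 2, 2), n_bins = 10),
                 "distinct")

  expr <- make_block_expr(n_samples = 20, block_sizes = c(60, 60),
                          n_background = 80, seed = 70)
  scan <- soft_threshold_scan(expr, powers = c(1, 4, 8), default_power = 8)
  expect_equal(nrow(scan), 3)
  expect_true(attr(scan, "power") %in% c(1, 4, 8))
  expect_true(all(diff(scan$mean_k) < 0))  # connectivity falls with power
})
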
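test_that("size factors: identical columns give 1, doubled column gives ratio 2", {
  cnt <- matrix(rep(c(10, 20, 30), 3), 3, 3,
                dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  expect_equal(unname(estimate_size_factors(cnt)), rep(1, 3))

  cnt2 <- cnt
  cnt2[, 2] <- 2 * cnt2[, 1]
  sf <- estimate_size_factors(cnt2)
  expect_equal(unname(sf["s2"] / sf["s1"]), 2)
  expect_equal(exp(mean(log(sf))), 1)

  zero <- matrix(c(0, 5, 5, 0), 2, 2,
                 dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_warning(sf0 <- estimate_size_factors(zero), "total-count")
  expect_equal(exp(mean(log(sf0))), 1)
})

test_that("NB Wald fold-change converges to the planted doubling", {
  set.seed(4)
  n_genes <- 200
  mu <- exp(stats::rnorm(n_genes, log(200), 0.5))
  a <- matrix(rep(mu, 6), n_genes)  # noise-free means, 2x in group B
  cnt <- cbind(a, 2 * a)
  cnt <- round(cnt)
  dimnames(cnt) <- list(sprintf("g%03d", 1:n_genes), sprintf("s%02d", 1:12))
  sf <- stats::setNames(rep(1, 12), colnames(cnt))
  de <- nb_wald_test(cnt, sf, colnames(cnt)[1:6], colnames(cnt)[7:12])
  expect_true(all(abs(de$log2fc - 1) < 0.1))  # pseudocount bias < 0.1 at mu >= 50
})

test_that("degenerate genes are reported untested and antisymmetry holds", {
  cnt <- make_counts(n_genes = 50, n_per_group = 4, seed = 9)
  cnt["g001", ] <- 0
  sf <- estimate_size_factors(cnt)
  ga <- group_ids(cnt, "a"); gb <- group_ids(cnt, "b")
  de <- nb_wald_test(cnt, sf, ga, gb)
  z <- de[de$gene == "g001", ]
  expect_equal(z$log2fc, 0)
  expect_equal(z$pvalue, 1)
  expect_false(z$tested)
  expect_true(is.na(z$padj))

  flipped <- nb_wald_test(cnt, sf, gb, ga)
  expect_equal(flipped$log2fc, -de$log2fc)
  expect_error(nb_wald_test(cnt, sf, ga[1], gb), "at least 2")
})

test_that("BH adjustment equals the hand-worked example and brute-force step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(10)
  for (n in c(1, 7, 100, 1000)) {
    p <- runif(n)^2
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  p_na <- c(0.01, NA, 0.5)
  expect_true(is.na(bh_adjust(p_na)[2]))
})

test_that("the four design contrasts run, label groups correctly, and error on missing ones", {
  # a clean planted diet shift: the module carries log2FC -2 in PM
  # samples with little shared-factor noise, so the two FM-vs-PM
  # contrasts (diet, enteritis) see it and the strain-matched ones do not
  cfg <- sim_config(n_fish_per_group = 6, n_genes = 300,
                    module_sizes = 50, module_trait_cor = 0,
                    module_log2fc = -2, module_factor_sd = 0.3,
                    library_size_mean = 3e6, seed = 31)
  study <- simulate_study(cfg)
  res <- run_design_contrasts(study$counts, study$design, "liver",
                              fpkm = study$fpkm)
  expect_setequal(names(res$results),
                  c("selection", "diet", "strain", "enteritis"))
  expect_equal(res$summary$n_significant,
               res$summary$n_up + res$summary$n_down)
  # the planted factor is diet-driven: diet and enteritis contrasts carry
  # the signal, the strain-matched contrasts are mostly null
  expect_gt(res$summary$n_significant[res$summary$contrast == "diet"],
            res$summary$n_significant[res$summary$contrast == "strain"])

  broken <- study$design[!(study$design$strain == "selected" &
                             study$design$diet == "PM"), ]
  expect_error(run_design_contrasts(
    study$counts[, broken$sample_id], broken, "liver"), "selected PM")
})

test_that("power guard: a planted doubling is detected in over 80% of genes", {
  cfg <- sim_config(n_fish_per_group = 10, n_genes = 2000,
                    module_sizes = 100, module_trait_cor = 0,
                    module_log2fc = 1, module_factor_sd = 0,
                    nb_dispersion = 0.1, library_size_mean = 5e6,
                    seed = 2001)
  des <- simulate_design(cfg)
  sim <- simulate_counts(des, cfg)
  liver <- des[des$tissue == "liver" & des$strain == "selected", ]
  cnt <- sim$counts[, liver$sample_id]
  de <- nb_wald_test(cnt, estimate_size_factors(cnt),
                     liver$sample_id[liver$diet == "FM"],
                     liver$sample_id[liver$diet == "PM"])
  shifted <- sim$gene_info$gene[sim$gene_info$planted_module != "background"]
  expect_gt(mean(de$pvalue[de$gene %in% shifted] < 0.05), 0.8)
})

test_that("NB Wald direction and magnitude agree with an established NB engine", {
  cnt <- make_counts(n_genes = 150, n_per_group = 5, lfc_genes = 1:30,
                     log2fc = 1.5, seed = 12)
  sf <- estimate_size_factors(cnt)
  de <- nb_wald_test(cnt, sf, group_ids(cnt, "a"), group_ids(cnt, "b"))

  suppressMessages({
    coldata <- data.frame(group = factor(rep(c("A", "B"), each = 5)))
    dds <- DESeq2::DESeqDataSetFromMatrix(cnt, coldata, ~group)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    ref <- DESeq2::results(dds, contrast = c("group", "B", "A"))
  })
  expect_gt(stats::cor(de$log2fc, ref$log2FoldChange, use = "complete.obs"),
            0.95)
  both_sig <- !is.na(ref$padj) & ref$padj < 0.01 & !is.na(de$padj) &
    de$padj < 0.01
  expect_true(all(sign(de$log2fc[both_sig]) ==
                    sign(ref$log2FoldChange[both_sig])))
})

test_that("venn regions count exclusive memberships with percentages of the union", {
  out <- venn_overlap(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
  expect_equal(out$count[out$region == "A"], 1)
  expect_equal(out$count[out$region == "B"], 1)
  expect_equal(out$count[out$region == "A&B"], 2)
  expect_equal(out$pct[out$region == "A&B"], 50.0)

  dis <- venn_overlap(list(A = "x", B = "y", C = "z"))
  expect_true(all(dis$count[grepl("&", dis$region)] == 0))
  same <- venn_overlap(list(A = letters[1:4], B = letters[1:4]))
  expect_equal(same$count[same$region == "A&B"], 4)
  expect_equal(sum(same$count[same$region != "A&B"]), 0)
  expect_error(venn_overlap(list(A = "x")), "at least 2")
})
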
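test_that("hub selection ranks by connectivity, breaks ties by id, filters descriptions", {
  set.seed(1)
  genes <- sprintf("g%02d", 1:40)
  kw <- stats::setNames(c(40:3, 5, 5), genes)  # tie on the last two
  mods <- stats::setNames(rep("salmon", 40), genes)
  ann <- data.frame(gene = genes, description = "well characterized kinase",
                    stringsAsFactors = FALSE)
  ann$description[ann$gene == "g01"] <- "hypothetical protein"
  out <- select_hub_genes(kw, mods, ann, "salmon", top_n = 30)
  expect_false("g01" %in% out$salmon)  # top gene filtered out, not replaced
  expect_equal(length(out$salmon), 29)
  # independent sort oracle
  oracle <- genes[order(-kw, genes)][1:30]
  expect_equal(out$salmon, setdiff(oracle, "g01"))

  small <- stats::setNames(rep("purple", 10), genes[1:10])
  expect_warning(out_small <- select_hub_genes(kw[1:10], small, ann,
                                               "purple", top_n = 30),
                 "only 10")
  expect_equal(length(out_small$purple), 9)  # all ranked, one filtered
})

test_that("|kME + Cor| scoring reproduces the published anchor and cancels on opposite signs", {
  genes <- c("prg4_like", "cancel", paste0("g", 1:10))
  kme <- matrix(c(0.820, 0.5, runif(10, 0.6, 0.9)), ncol = 1,
                dimnames = list(genes, "MEsalmon"))
  gs <- stats::setNames(c(0.862, -0.5, runif(10, -0.2, 0.2)), genes)
  mods <- stats::setNames(rep("salmon", 12), genes)
  ann <- data.frame(gene = genes, description = "characterized")
  out <- select_kme_cor(kme, gs, mods, ann, "salmon", top_n = 30)$salmon
  expect_equal(out$score[out$gene == "prg4_like"], 1.682)
  expect_equal(out$score[out$gene == "cancel"], 0)
  # ranking equals a brute-force enumeration
  oracle <- order(-abs(kme[, 1] + gs[genes]), genes)
  expect_equal(out$gene, genes[oracle])
})

test_that("top-DEG selection takes ceil(1%) by |FC| and drops non-significant modules", {
  n_sig <- 1341
  set.seed(2)
  genes <- sprintf("deg%04d", 1:n_sig)
  de <- data.frame(gene = genes,
                   log2fc = stats::rnorm(n_sig, 0, 2),
                   padj = stats::runif(n_sig, 0, 0.05),
                   significant = TRUE, stringsAsFactors = FALSE)
  pm <- stats::setNames(rep("turquoise", n_sig), genes)
  ann <- data.frame(gene = genes, description = "characterized")
  out <- select_top_degs(de, pm, "turquoise", ann, frac = 0.01)
  expect_equal(length(out), 14)  # ceil(0.01 * 1341)
  oracle <- de$gene[order(-abs(de$log2fc), de$padj, de$gene)][1:14]
  expect_setequal(out, oracle)

  # a top gene whose primary module is not diet-significant is removed
  pm[oracle[1]] <- "grey60"
  out2 <- select_top_degs(de, pm, "turquoise", ann, frac = 0.01)
  expect_false(oracle[1] %in% out2)
  expect_equal(length(out2), 13)

  expect_equal(select_top_degs(de[0, ], pm, "turquoise", ann), character(0))
})

test_that("assembly unions selectors with tags and errors on module conflicts", {
  hub <- list(purple = c("a", "b"))
  kc <- list(purple = data.frame(gene = c("b", "c"), kme = c(0.9, 0.8),
                                 cor = c(-0.7, -0.6), score = c(1.6, 1.4)))
  mods <- stats::setNames(rep("purple", 4), c("a", "b", "c", "d"))
  tab <- assemble_candidates(hub, kc, deg_genes = "d", modules = mods)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$tags[tab$gene == "b"], "hub,kme_cor")
  expect_equal(tab$tags[tab$gene == "d"], "deg")
  expect_true(all(nchar(tab$tags) > 0))
  expect_lte(nrow(tab), 2 + 2 + 1)

  mods_bad <- mods; mods_bad["d"] <- "salmon"
  hub_bad <- list(purple = "d", salmon = "d")
  expect_error(assemble_candidates(hub_bad, list(), character(0),
                                   modules = mods_bad),
               "conflicting")
})

test_that("the packaged candidate table round-trips through assembly and summary", {
  fix <- trout_candidate_fixture()
  expect_equal(nrow(fix), 63)
  inputs <- candidate_selector_inputs(fix)
  de <- data.frame(gene = fix$gene, log2fc = fix$fc,
                   significant = !is.na(fix$fc), stringsAsFactors = FALSE)
  tab <- assemble_candidates(inputs$hub_lists, inputs$kme_cor_lists,
                             inputs$deg_genes, modules = inputs$modules,
                             de = de, go_genes = inputs$go_genes)
  expect_equal(nrow(tab), 63)
  # per-module membership is reproduced exactly
  expect_equal(sort(tab$gene[tab$module == "salmon"]),
               sort(fix$gene[fix$module == "salmon"]))
  expect_equal(sort(tab$gene[tab$module == "purple"]),
               sort(fix$gene[fix$module == "purple"]))
  expect_equal(sort(tab$gene[tab$module == "turquoise"]),
               sort(fix$gene[fix$module == "turquoise"]))
  # tag sets agree gene by gene
  norm_tags <- function(x) vapply(strsplit(x, ","), function(t)
    paste(sort(t), collapse = ","), "")
  expect_equal(norm_tags(tab$tags[match(fix$gene, tab$gene)]),
               norm_tags(fix$tags))

  s <- summarize_candidates(fix)
  expect_equal(s$total, 63)
  expect_equal(s$per_module[["salmon"]], 18)
  expect_equal(s$per_module[["purple"]], 19)
  expect_equal(s$per_module[["turquoise"]], 26)
  expect_equal(s$n_missing_fc, 2)
  expect_equal(s$n_deg_only, 3)
  # the fold-change-less records are the interleukin receptor and the
  # CTD phosphatase; the same transporter symbol recurs in two modules
  expect_setequal(fix$symbol[is.na(fix$fc)], c("IL17REL", "CTDSP2"))
  expect_setequal(fix$symbol[fix$tags == "deg"],
                  c("PPP1R3B", "bty", "CES1"))
  expect_equal(s$duplicated_symbols, "slc25a36a")

  empty <- summarize_candidates(fix[0, ])
  expect_equal(empty$total, 0L)
  expect_equal(empty$n_deg_only, 0L)
})
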
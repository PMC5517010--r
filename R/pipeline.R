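#' Validate expression inputs against sample metadata
#'
#' Consistency checks before analysis: every matrix column must have a
#' metadata row (fatal), gene ids must be unique (fatal), traits must be
#' present and numeric (fatal when missing), and annotation covering
#' extra genes is reported as a warning only. Problems are reported,
#' never silently fixed.
#'
#' @param counts Gene x sample matrix.
#' @param samples Sample table with \code{sample_id}.
#' @param annotation Optional annotation data.frame with \code{gene}.
#' @param required_traits Trait columns that must exist in
#'   \code{samples}.
#' @param strict Stop on fatal problems (default); otherwise return the
#'   report with an attribute \code{"fatal"}.
#' @return Data.frame report: \code{check}, \code{level}
#'   ("ok"/"warning"/"fatal"), \code{detail}.
#' @export
validate_inputs <- function(counts, samples, annotation = NULL,
                            required_traits = c("weight_g",
                                                "liver_weight_g", "hsi"),
                            strict = TRUE) {
  rep_row <- function(check, level, detail)
    data.frame(check = check, level = level, detail = detail,
               stringsAsFactors = FALSE)
  rows <- list()
  missing_meta <- setdiff(colnames(counts), samples$sample_id)
  rows[[length(rows) + 1]] <- if (length(missing_meta))
    rep_row("samples_in_metadata", "fatal",
            paste("matrix samples missing from metadata:",
                  paste(utils::head(missing_meta, 5), collapse = ", ")))
  else rep_row("samples_in_metadata", "ok", "")
  dup <- rownames(counts)[duplicated(rownames(counts))]
  rows[[length(rows) + 1]] <- if (length(dup))
    rep_row("unique_gene_ids", "fatal",
            paste("duplicate gene ids:",
                  paste(utils::head(unique(dup), 5), collapse = ", ")))
  else rep_row("unique_gene_ids", "ok", "")
  miss_tr <- setdiff(required_traits, names(samples))
  rows[[length(rows) + 1]] <- if (length(miss_tr))
    rep_row("traits_present", "fatal",
            paste("missing traits:", paste(miss_tr, collapse = ", ")))
  else rep_row("traits_present", "ok", "")
  if (!is.null(annotation)) {
    extra <- setdiff(annotation$gene, rownames(counts))
    rows[[length(rows) + 1]] <- if (length(extra))
      rep_row("annotation_extra_genes", "warning",
              paste(length(extra), "annotated genes absent from matrix"))
    else rep_row("annotation_extra_genes", "ok", "")
  }
  report <- do.call(rbind, rows)
  fatal <- report$level == "fatal"
  attr(report, "fatal") <- any(fatal)
  for (d in report$detail[report$level == "warning"]) warning(d)
  if (strict && any(fatal))
    stop("input validation failed: ",
         paste(report$detail[fatal], collapse = "; "))
  report
}

#' Run the full integrative analysis end to end
#'
#' Executes the whole pipeline on a synthetic study: simulation,
#' FPKM computation, the four strain-by-diet differential-expression
#' contrasts per tissue with Venn overlaps, the signed-hybrid
#' co-expression network on the network tissue/strain subset
#' (expression-filtered, log2(FPKM + 1)-transformed) with module-trait
#' correlation, the hub / |kME + Cor| / top-DEG candidate integration
#' over the diet-significant modules, GO enrichment of those modules,
#' KEGG-style pathway perturbation over the cross-tissue DEG union, and
#' the histopathology comparison. Deterministic for a fixed
#' configuration seed; optionally writes all result tables and a
#' manifest as TSV/JSON.
#'
#' @param cfg A \code{\link{sim_config}} describing the synthetic study.
#' @param out_dir Optional output directory for TSV artifacts.
#' @param network_tissue Tissue used for the network (default "liver",
#'   the metabolically dominant tissue).
#' @param network_strain Strain used for the network (default
#'   "selected": the tolerant line, so diet signal is free of the
#'   enteritis confounder).
#' @param beta,min_module_size,merge_cut_height,cut_height Network
#'   parameters, see \code{\link{build_network}}.
#' @param de_alpha Adjusted-p threshold for DEGs.
#' @param fpkm_threshold Expression floor for DEG calls and filters.
#' @param module_p Module-trait significance threshold for selecting
#'   diet modules.
#' @param top_n Hub and kME list length.
#' @param deg_frac Fraction of significant DEGs kept as top DEGs.
#' @param ... Passed to \code{\link{simulate_study}}.
#' @return Object of class \code{"nutrinet_run"}: a list with
#'   \code{study}, \code{de} (per tissue), \code{venn} (per tissue),
#'   \code{network}, \code{sig_modules}, \code{candidates},
#'   \code{candidate_summary}, \code{enrichment}, \code{kegg},
#'   \code{histology}, \code{manifest}.
#' @export
run_pipeline <- function(cfg = sim_config(), out_dir = NULL,
                         network_tissue = "liver",
                         network_strain = "selected",
                         beta = 8, min_module_size = 30,
                         merge_cut_height = 0.20, cut_height = 0.99,
                         de_alpha = 0.05, fpkm_threshold = 1,
                         module_p = 0.003, top_n = 30, deg_frac = 0.01,
                         ...) {
  study <- simulate_study(cfg, ...)
  validate_inputs(study$counts, study$design, study$annotation)

  de <- list()
  venn <- list()
  for (tis in unique(study$design$tissue)) {
    de[[tis]] <- run_design_contrasts(study$counts, study$design, tis,
                                      fpkm = study$fpkm, alpha = de_alpha,
                                      fpkm_threshold = fpkm_threshold)
    sets <- lapply(de[[tis]]$results, function(d) d$gene[d$significant])
    venn[[tis]] <- venn_overlap(sets)
  }

  net_samples <- study$design[study$design$tissue == network_tissue &
                                study$design$strain == network_strain, ]
  fpkm_net <- study$fpkm[, net_samples$sample_id, drop = FALSE]
  fpkm_net <- filter_network_genes(fpkm_net)
  expr <- t(log_transform(fpkm_net))
  traits <- data.frame(diet = as.numeric(net_samples$diet == "PM"),
                       weight = net_samples$weight_g,
                       liver_weight = net_samples$liver_weight_g,
                       hsi = net_samples$hsi,
                       row.names = net_samples$sample_id)
  outliers <- sample_outlier_report(expr)
  net <- build_network(expr, traits, beta = beta,
                       min_module_size = min_module_size,
                       merge_cut_height = merge_cut_height,
                       cut_height = cut_height)
  sig_mods <- significant_modules(net, trait = "diet", p_cut = module_p)

  diet_de <- de[[network_tissue]]$results$diet
  hub <- select_hub_genes(net$k_within, net$modules, study$annotation,
                          sig_mods, top_n = top_n)
  kc <- select_kme_cor(net$kme, net$gs, net$modules, study$annotation,
                       sig_mods, top_n = top_n)
  degs <- select_top_degs(diet_de, net$primary_module, sig_mods,
                          study$annotation, frac = deg_frac)

  term_map <- annotation_long(study$annotation)
  reference <- study$annotation$gene
  enrichment <- lapply(stats::setNames(sig_mods, sig_mods), function(m)
    fisher_enrichment(names(net$modules)[net$modules == m], reference,
                      term_map, sided = "two"))
  go_genes <- unique(unlist(lapply(sig_mods, function(m) {
    enr <- enrichment[[m]]
    over <- enr$term[enr$significant & enr$direction == "over"]
    if (length(over) == 0) return(character(0))
    mod_genes <- names(net$modules)[net$modules == m]
    tm <- term_map[term_map$term %in% over & term_map$gene %in% mod_genes, ]
    tm$gene
  })))

  candidates <- assemble_candidates(hub, kc, degs, modules = net$modules,
                                    de = diet_de, kme = net$kme,
                                    gs = net$gs, go_genes = go_genes,
                                    annotation = study$annotation)
  cand_summary <- summarize_candidates(candidates)

  deg_union <- unique(unlist(lapply(de, function(tis_de)
    unlist(lapply(tis_de$results, function(d) d$gene[d$significant])))))
  kegg <- kegg_perturbation(deg_union, study$annotation)

  hist_scores <- cumulative_score(study$histology)
  kw <- kruskal_wallis(hist_scores$per_fish$total,
                       hist_scores$per_fish$group)
  dunn <- dunn_posthoc(hist_scores$per_fish$total,
                       hist_scores$per_fish$group)

  manifest <- list(package_version = as.character(
    utils::packageVersion("nutrinet")),
    r_version = R.version.string,
    seed = cfg$seed,
    parameters = list(beta = beta, min_module_size = min_module_size,
                      merge_cut_height = merge_cut_height,
                      cut_height = cut_height, de_alpha = de_alpha,
                      fpkm_threshold = fpkm_threshold,
                      module_p = module_p, top_n = top_n,
                      deg_frac = deg_frac,
                      network_tissue = network_tissue,
                      network_strain = network_strain),
    config = unclass(cfg))

  run <- list(study = study, de = de, venn = venn, outliers = outliers,
              network = net, sig_modules = sig_mods,
              candidates = candidates, candidate_summary = cand_summary,
              enrichment = enrichment, kegg = kegg,
              histology = list(scores = hist_scores, kruskal = kw,
                               dunn = dunn),
              manifest = manifest)
  class(run) <- "nutrinet_run"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    for (tis in names(de)) {
      for (cn in names(de[[tis]]$results))
        wt(de[[tis]]$results[[cn]], paste0("de_", tis, "_", cn, ".tsv"))
      wt(de[[tis]]$summary, paste0("de_", tis, "_summary.tsv"))
      wt(venn[[tis]], paste0("venn_", tis, ".tsv"))
    }
    wt(data.frame(gene = names(net$modules), module = net$modules,
                  k_within = net$k_within[names(net$modules)],
                  gs_diet = net$gs[names(net$modules)]),
       "modules.tsv")
    if (!is.null(net$eigengenes))
      utils::write.table(net$eigengenes, file.path(out_dir,
                                                   "eigengenes.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA)
    if (!is.null(net$module_trait)) wt(net$module_trait,
                                       "module_trait.tsv")
    wt(candidates, "candidates.tsv")
    if (requireNamespace("jsonlite", quietly = TRUE))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
  }
  run
}

#' @export
print.nutrinet_run <- function(x, ...) {
  cat("Integrative nutrigenomic analysis run (seed ",
      x$manifest$seed, ")\n", sep = "")
  for (tis in names(x$de)) {
    cat("\nDE, ", tis, " (p-adj < ",
        x$manifest$parameters$de_alpha, ", mean FPKM >= ",
        x$manifest$parameters$fpkm_threshold, "):\n", sep = "")
    print(x$de[[tis]]$summary, row.names = FALSE)
  }
  cat("\nNetwork: ", length(setdiff(unique(x$network$modules), "grey")),
      " modules; diet-significant: ",
      if (length(x$sig_modules)) paste(x$sig_modules, collapse = ", ")
      else "none", "\n", sep = "")
  cat("Candidates: ", x$candidate_summary$total, " genes (",
      paste(names(x$candidate_summary$per_module),
            x$candidate_summary$per_module, sep = ": ",
            collapse = ", "), ")\n", sep = "")
  cat("Histology Kruskal-Wallis: H = ",
      round(x$histology$kruskal$H, 3), ", p = ",
      signif(x$histology$kruskal$p, 3), "\n", sep = "")
  invisible(x)
}
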
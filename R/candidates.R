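#' Annotation-based keyword filter
#'
#' Removes genes whose description matches (case-insensitively) any of
#' the filter keywords — by default unknown, uncharacterized,
#' hypothetical, structural or unnamed proteins, the classes excluded
#' from candidate lists because they cannot be interpreted or acted on.
#'
#' @param genes Character vector of gene ids.
#' @param annotation Data.frame with \code{gene} and \code{description}.
#' @param keywords Character vector of (regex-escaped) keywords.
#' @return The subset of \code{genes} passing the filter. Genes with no
#'   annotation row are kept.
#' @export
filter_annotated <- function(genes, annotation,
                             keywords = c("unknown", "uncharacterized",
                                          "hypothetical", "structural",
                                          "unnamed")) {
  if (length(genes) == 0) return(genes)
  desc <- annotation$description[match(genes, annotation$gene)]
  desc[is.na(desc)] <- ""
  pat <- paste(keywords, collapse = "|")
  genes[!grepl(pat, desc, ignore.case = TRUE)]
}

#' Top hub genes per module
#'
#' Ranks the genes of each significant module by intramodular
#' connectivity (descending, ties broken by gene id), takes the top
#' \code{top_n} and then applies the annotation keyword filter.
#'
#' @param k_within Named per-gene intramodular connectivity.
#' @param modules Named gene -> color vector.
#' @param annotation Annotation data.frame (gene, description).
#' @param sig_modules Module colors to report.
#' @param top_n Hub list length before filtering.
#' @return Named list (per module) of hub gene ids, connectivity-ordered.
#' @export
select_hub_genes <- function(k_within, modules, annotation, sig_modules,
                             top_n = 30) {
  out <- list()
  for (m in sig_modules) {
    genes <- names(modules)[modules == m]
    if (length(genes) == 0) { out[[m]] <- character(0); next }
    if (length(genes) < top_n)
      warning("module ", m, " has only ", length(genes), " genes (top_n = ",
              top_n, ")")
    kw <- k_within[genes]
    ord <- genes[order(-kw, genes)]
    top <- utils::head(ord, top_n)
    out[[m]] <- filter_annotated(top, annotation)
  }
  out
}

#' Top |kME + Cor| genes per module
#'
#' Within each significant module, takes the \code{top_n} genes with the
#' highest module membership (kME), scores each as |kME + Cor| where Cor
#' is the gene's correlation with the diet trait, ranks by the combined
#' score and applies the annotation filter. Because kME and Cor share
#' their sign inside a diet-driven module, the sum rewards genes that are
#' both tightly connected and strongly diet-associated.
#'
#' @param kme Genes x modules kME matrix (columns \code{ME<color>}).
#' @param gs Named gene-significance vector (correlation with diet).
#' @param modules Named gene -> color vector.
#' @param annotation Annotation data.frame.
#' @param sig_modules Module colors to report.
#' @param top_n Number of highest-kME genes entering the scoring.
#' @return Named list of data.frames (gene, kme, cor, score), score-ranked
#'   and filtered.
#' @export
select_kme_cor <- function(kme, gs, modules, annotation, sig_modules,
                           top_n = 30) {
  out <- list()
  for (m in sig_modules) {
    genes <- names(modules)[modules == m]
    col <- paste0("ME", m)
    if (length(genes) == 0 || !col %in% colnames(kme)) {
      out[[m]] <- data.frame(gene = character(0), kme = numeric(0),
                             cor = numeric(0), score = numeric(0))
      next
    }
    k <- kme[genes, col]
    cor_d <- gs[genes]
    miss <- is.na(cor_d) | is.na(k)
    if (any(miss)) {
      warning(sum(miss), " gene(s) in module ", m,
              " lack kME or diet correlation; skipped")
      genes <- genes[!miss]; k <- k[!miss]; cor_d <- cor_d[!miss]
    }
    ord <- order(-k, genes)
    keep <- utils::head(ord, top_n)
    df <- data.frame(gene = genes[keep], kme = k[keep], cor = cor_d[keep],
                     score = abs(k[keep] + cor_d[keep]),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$score, df$gene), , drop = FALSE]
    df <- df[df$gene %in% filter_annotated(df$gene, annotation), ,
             drop = FALSE]
    rownames(df) <- NULL
    out[[m]] <- df
  }
  out
}

#' Top differentially expressed genes by fold-change magnitude
#'
#' From the significant DEGs of the diet contrast, takes
#' \code{ceiling(frac * N)} genes with the largest |log2FC| (adjusted p
#' as tie-breaker), applies the annotation filter, and removes genes
#' whose primary module membership is not one of the significant
#' modules. With \code{ordering = "padj_then_fc"} the candidate pool is
#' instead the \code{ceiling(frac * N)} most significant genes by
#' adjusted p, reported in fold-change-magnitude order (the alternative
#' reading of "sorted by significance, top 1\% by fold-change").
#'
#' @param de DE data.frame of the diet contrast (with \code{significant},
#'   \code{log2fc}, \code{padj}).
#' @param primary_module Named gene -> color vector of primary module
#'   membership (highest kME).
#' @param sig_modules Significant module colors.
#' @param annotation Annotation data.frame.
#' @param frac Fraction of significant DEGs selected.
#' @param ordering Selection rule ("abs_fc" or "padj_then_fc").
#' @return Character vector of candidate DEG ids.
#' @export
select_top_degs <- function(de, primary_module, sig_modules, annotation,
                            frac = 0.01,
                            ordering = c("abs_fc", "padj_then_fc")) {
  ordering <- match.arg(ordering)
  sig <- de[de$significant, , drop = FALSE]
  if (nrow(sig) == 0) return(character(0))
  n_take <- ceiling(frac * nrow(sig))
  if (ordering == "abs_fc") {
    sig <- sig[order(-abs(sig$log2fc), sig$padj, sig$gene), , drop = FALSE]
  } else {
    sig <- sig[order(sig$padj, -abs(sig$log2fc), sig$gene), , drop = FALSE]
    sig <- utils::head(sig, n_take)
    sig <- sig[order(-abs(sig$log2fc), sig$gene), , drop = FALSE]
  }
  top <- utils::head(sig$gene, n_take)
  top <- filter_annotated(top, annotation)
  pm <- primary_module[top]
  top[!is.na(pm) & pm %in% sig_modules]
}

#' Assemble the candidate-gene table
#'
#' Unions the hub, |kME + Cor| and top-DEG selections (keyed by gene id
#' within module), recording for each candidate every selector that
#' contributed as tags from \{hub, kme_cor, deg, go\}. Fold-changes come
#' from the final DE table and are absent (NA) for genes that did not
#' survive it (e.g. expression-filtered); kME and diet correlation come
#' from the network statistics; the go tag marks genes mapping to a
#' module-level over-represented term.
#'
#' @param hub_lists Output of \code{\link{select_hub_genes}}.
#' @param kme_cor_lists Output of \code{\link{select_kme_cor}}.
#' @param deg_genes Output of \code{\link{select_top_degs}}.
#' @param modules Named gene -> color vector (module of record for each
#'   candidate; DEG candidates use their primary membership).
#' @param de Optional DE data.frame providing \code{log2fc} (only rows
#'   present in it yield a fold-change).
#' @param kme Optional kME matrix; \code{gs} optional diet-correlation
#'   vector (used to fill mm / cor columns when a selector did not).
#' @param gs Optional gene-significance vector.
#' @param go_genes Optional character vector of genes carrying a
#'   module-level enriched term (receive the \code{go} tag).
#' @param annotation Optional annotation (adds symbol / description).
#' @return Data.frame of candidate records: \code{module}, \code{gene},
#'   \code{symbol}, \code{description}, \code{fc}, \code{mm}, \code{cor},
#'   \code{tags} (comma-separated).
#' @export
assemble_candidates <- function(hub_lists, kme_cor_lists, deg_genes,
                                modules, de = NULL, kme = NULL, gs = NULL,
                                go_genes = character(0),
                                annotation = NULL) {
  recs <- list()
  add <- function(gene, module, tag) {
    key <- gene
    prev <- recs[[key]]
    if (!is.null(prev)) {
      if (prev$module != module)
        stop("gene ", gene, " assigned to conflicting modules: ",
             prev$module, " vs ", module)
      prev$tags <- union(prev$tags, tag)
      recs[[key]] <<- prev
    } else {
      recs[[key]] <<- list(gene = gene, module = module, tags = tag)
    }
  }
  for (m in names(hub_lists))
    for (g in hub_lists[[m]]) add(g, m, "hub")
  for (m in names(kme_cor_lists))
    for (g in kme_cor_lists[[m]]$gene) add(g, m, "kme_cor")
  for (g in deg_genes) add(g, unname(modules[g]), "deg")
  if (length(recs) == 0)
    return(data.frame(module = character(0), gene = character(0),
                      symbol = character(0), description = character(0),
                      fc = numeric(0), mm = numeric(0), cor = numeric(0),
                      tags = character(0), stringsAsFactors = FALSE))
  tab <- do.call(rbind, lapply(recs, function(r) {
    tags <- r$tags
    if (r$gene %in% go_genes) tags <- union(tags, "go")
    data.frame(module = r$module, gene = r$gene,
               tags = paste(intersect(c("hub", "kme_cor", "deg", "go"),
                                      tags), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  tab$fc <- if (!is.null(de)) {
    lfc <- de$log2fc[match(tab$gene, de$gene)]
    sig <- de$significant[match(tab$gene, de$gene)]
    ifelse(!is.na(sig) & sig, lfc, NA_real_)
  } else NA_real_
  tab$mm <- if (!is.null(kme)) {
    vapply(seq_len(nrow(tab)), function(i) {
      col <- paste0("ME", tab$module[i])
      if (col %in% colnames(kme)) kme[tab$gene[i], col] else NA_real_
    }, numeric(1))
  } else NA_real_
  tab$cor <- if (!is.null(gs)) unname(gs[tab$gene]) else NA_real_
  if (!is.null(annotation)) {
    idx <- match(tab$gene, annotation$gene)
    tab$symbol <- annotation$symbol[idx]
    tab$description <- annotation$description[idx]
  } else {
    tab$symbol <- NA_character_
    tab$description <- NA_character_
  }
  tab <- tab[order(tab$module, -abs(ifelse(is.na(tab$mm), 0, tab$mm)),
                   tab$gene), ]
  rownames(tab) <- NULL
  tab[, c("module", "gene", "symbol", "description", "fc", "mm", "cor",
          "tags")]
}

#' Summary counts of a candidate table
#'
#' @param tab Candidate data.frame as from
#'   \code{\link{assemble_candidates}} (needs \code{module}, \code{fc},
#'   \code{tags}; \code{symbol} optional for the duplicate report).
#' @return List: \code{total}, \code{per_module} (named counts),
#'   \code{n_missing_fc}, \code{n_deg_only} (records whose only tag is
#'   deg), \code{duplicated_symbols} (symbols appearing in more than one
#'   module).
#' @export
summarize_candidates <- function(tab) {
  if (nrow(tab) == 0)
    return(list(total = 0L, per_module = integer(0), n_missing_fc = 0L,
                n_deg_only = 0L, duplicated_symbols = character(0)))
  per_module <- table(tab$module)
  dup <- character(0)
  if ("symbol" %in% names(tab) && !all(is.na(tab$symbol))) {
    sm <- unique(tab[!is.na(tab$symbol), c("symbol", "module")])
    cnt <- table(sm$symbol)
    dup <- names(cnt)[cnt > 1]
  }
  list(total = nrow(tab),
       per_module = stats::setNames(as.integer(per_module),
                                    names(per_module)),
       n_missing_fc = sum(is.na(tab$fc)),
       n_deg_only = sum(tab$tags == "deg"),
       duplicated_symbols = dup)
}

#' Published rainbow-trout candidate-gene list
#'
#' Loads the packaged candidate-gene table from the rainbow trout
#' plant-diet tolerance study that this package's integration logic
#' models: 63 liver transcripts from the three diet-correlated modules
#' (salmon, purple, turquoise), each with its diet-contrast fold-change
#' (absent for two purple-module genes), module membership (MM), diet
#' correlation (Cor) and the selector tags that discovered it.
#'
#' @return Data.frame with columns \code{module}, \code{symbol},
#'   \code{gene}, \code{description}, \code{fc}, \code{mm}, \code{cor},
#'   \code{tags}.
#' @export
trout_candidate_fixture <- function() {
  path <- system.file("extdata", "trout_candidate_genes.tsv",
                      package = "nutrinet", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
}

#' Split a candidate table back into selector inputs
#'
#' Decomposes a candidate table (e.g. the packaged fixture) into the
#' per-module hub lists, |kME + Cor| lists, DEG list and go-tagged genes
#' that \code{\link{assemble_candidates}} consumes — used to verify that
#' assembly reproduces a known integration end to end.
#'
#' @param tab Candidate data.frame with \code{module}, \code{gene},
#'   \code{mm}, \code{cor}, \code{tags}.
#' @return List with \code{hub_lists}, \code{kme_cor_lists},
#'   \code{deg_genes}, \code{go_genes}, \code{modules} (gene -> module).
#' @export
candidate_selector_inputs <- function(tab) {
  has <- function(tag) grepl(paste0("(^|,)", tag, "(,|$)"), tab$tags)
  mods <- unique(tab$module)
  hub_lists <- lapply(stats::setNames(mods, mods), function(m)
    tab$gene[tab$module == m & has("hub")])
  kme_cor_lists <- lapply(stats::setNames(mods, mods), function(m) {
    sel <- tab$module == m & has("kme_cor")
    data.frame(gene = tab$gene[sel], kme = tab$mm[sel],
               cor = tab$cor[sel],
               score = abs(tab$mm[sel] + tab$cor[sel]),
               stringsAsFactors = FALSE)
  })
  list(hub_lists = hub_lists,
       kme_cor_lists = kme_cor_lists,
       deg_genes = tab$gene[has("deg")],
       go_genes = tab$gene[has("go")],
       modules = stats::setNames(tab$module, tab$gene))
}
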
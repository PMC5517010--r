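#' Parse semicolon-separated annotation columns into long form
#'
#' Expands an annotation data.frame (as from
#' \code{\link{simulate_annotation}}) into one row per gene-term
#' assignment across the three GO categories.
#'
#' @param annotation Data.frame with \code{gene}, \code{go_bp},
#'   \code{go_mf}, \code{go_cc}.
#' @return Data.frame: \code{gene}, \code{category} (BP/MF/CC),
#'   \code{term}.
#' @export
annotation_long <- function(annotation) {
  cats <- c(go_bp = "BP", go_mf = "MF", go_cc = "CC")
  out <- lapply(names(cats), function(col) {
    terms <- strsplit(annotation[[col]], ";", fixed = TRUE)
    n <- lengths(terms)
    data.frame(gene = rep(annotation$gene, n),
               category = cats[[col]],
               term = unlist(terms), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[nzchar(out$term), , drop = FALSE]
}

#' Fisher's exact term enrichment
#'
#' For every term annotated in the reference, builds the 2x2 table
#' (membership in the test set vs the rest of the reference, against
#' carrying the term vs not) and computes the exact hypergeometric
#' p-value — two-sided by the sum of tables at most as probable as the
#' observed one, or one-sided (upper tail) for over-representation.
#' P-values are Benjamini-Hochberg adjusted across the terms of the run;
#' direction is read off the odds ratio.
#'
#' @param test_genes Character vector, a subset of
#'   \code{reference_genes}.
#' @param reference_genes Character vector, the transcriptome-wide
#'   reference.
#' @param term_map Long data.frame (gene, category, term) as from
#'   \code{\link{annotation_long}}.
#' @param sided "two" (default) or "over".
#' @param fdr_cut FDR flag threshold.
#' @return Data.frame: \code{term}, \code{category}, \code{direction}
#'   ("over"/"under"), \code{test_in}, \code{test_out}, \code{ref_in},
#'   \code{ref_out}, \code{p}, \code{fdr}, \code{significant}; ordered by
#'   p.
#' @export
fisher_enrichment <- function(test_genes, reference_genes, term_map,
                              sided = c("two", "over"), fdr_cut = 0.05) {
  sided <- match.arg(sided)
  test_genes <- unique(test_genes)
  reference_genes <- unique(reference_genes)
  if (!all(test_genes %in% reference_genes))
    stop("test set must be a subset of the reference set")
  term_map <- term_map[term_map$gene %in% reference_genes, , drop = FALSE]
  keys <- unique(term_map[, c("term", "category")])
  n_test <- length(test_genes)
  n_rest <- length(reference_genes) - n_test
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    carriers <- unique(term_map$gene[term_map$term == keys$term[i] &
                                       term_map$category == keys$category[i]])
    a <- sum(test_genes %in% carriers)
    b <- n_test - a
    cc <- length(carriers) - a
    d <- n_rest - cc
    m <- matrix(c(a, b, cc, d), nrow = 2)
    p <- stats::fisher.test(m, alternative =
                              if (sided == "two") "two.sided" else "greater")$p.value
    p <- min(1, p)  # guard against tiny floating-point overshoot
    over <- a / max(1, n_test) > (a + cc) / (n_test + n_rest)
    data.frame(term = keys$term[i], category = keys$category[i],
               direction = if (over) "over" else "under",
               test_in = a, test_out = b, ref_in = cc, ref_out = d,
               p = p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$fdr <- bh_adjust(tab$p)
  tab$significant <- tab$fdr < fdr_cut
  tab <- tab[order(tab$p, tab$term), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' KEGG-style pathway perturbation counts
#'
#' For a union of differentially expressed genes (across tissues), counts
#' per pathway the number of member sequences in the union and the number
#' of distinct enzyme codes those sequences carry, and reports two ranked
#' tables: pathways with at least \code{min_sequences} member sequences,
#' and pathways with at least \code{min_enzymes} distinct enzymes. Genes
#' with a pathway but no EC number count toward sequences only.
#'
#' @param genes Character vector of (unique) DEG ids combined across
#'   tissues.
#' @param annotation Data.frame with \code{gene}, \code{pathways}
#'   (semicolon-separated) and \code{ec} (semicolon-separated, possibly
#'   empty).
#' @param min_sequences Sequence-count cutoff for the first report.
#' @param min_enzymes Enzyme-count cutoff for the second report.
#' @return List with \code{by_sequences} and \code{by_enzymes}
#'   data.frames (\code{pathway}, \code{n_sequences}, \code{n_enzymes}),
#'   each sorted by its ranking column.
#' @export
kegg_perturbation <- function(genes, annotation, min_sequences = 20,
                              min_enzymes = 10) {
  ann <- annotation[annotation$gene %in% unique(genes), , drop = FALSE]
  pw <- strsplit(ann$pathways, ";", fixed = TRUE)
  n <- lengths(pw)
  long <- data.frame(gene = rep(ann$gene, n),
                     ec = rep(ann$ec, n),
                     pathway = unlist(pw), stringsAsFactors = FALSE)
  long <- long[nzchar(long$pathway), , drop = FALSE]
  if (nrow(long) == 0)
    return(list(by_sequences = data.frame(pathway = character(0),
                                          n_sequences = integer(0),
                                          n_enzymes = integer(0)),
                by_enzymes = data.frame(pathway = character(0),
                                        n_sequences = integer(0),
                                        n_enzymes = integer(0))))
  stats_ <- do.call(rbind, lapply(split(long, long$pathway), function(d) {
    ecs <- unlist(strsplit(d$ec, ";", fixed = TRUE))
    data.frame(pathway = d$pathway[1],
               n_sequences = length(unique(d$gene)),
               n_enzymes = length(unique(ecs[nzchar(ecs)])),
               stringsAsFactors = FALSE)
  }))
  rownames(stats_) <- NULL
  by_seq <- stats_[stats_$n_sequences >= min_sequences, , drop = FALSE]
  by_seq <- by_seq[order(-by_seq$n_sequences, by_seq$pathway), ]
  by_enz <- stats_[stats_$n_enzymes >= min_enzymes, , drop = FALSE]
  by_enz <- by_enz[order(-by_enz$n_enzymes, by_enz$pathway), ]
  rownames(by_seq) <- rownames(by_enz) <- NULL
  list(by_sequences = by_seq, by_enzymes = by_enz)
}
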
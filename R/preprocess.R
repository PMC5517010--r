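#' Compute FPKM from raw counts
#'
#' FPKM_ij = counts_ij * 1e9 / (length_i * library_size_j): fragments per
#' kilobase of transcript per million mapped reads.
#'
#' @param counts Non-negative gene x sample count matrix.
#' @param gene_lengths Named vector of transcript lengths (bp), covering
#'   the rownames of \code{counts}.
#' @param library_sizes Named vector of mapped reads per sample, covering
#'   the colnames of \code{counts}.
#' @return Numeric matrix of FPKM values, same dimnames as \code{counts}.
#' @export
compute_fpkm <- function(counts, gene_lengths, library_sizes) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  gl <- gene_lengths[rownames(counts)]
  ls <- library_sizes[colnames(counts)]
  if (anyNA(gl)) stop("gene_lengths missing for: ",
                      paste(utils::head(rownames(counts)[is.na(gl)], 5),
                            collapse = ", "))
  if (anyNA(ls)) stop("library_sizes missing for: ",
                      paste(utils::head(colnames(counts)[is.na(ls)], 5),
                            collapse = ", "))
  if (any(gl <= 0)) stop("non-positive gene length for: ",
                         paste(utils::head(names(gl)[gl <= 0], 5),
                               collapse = ", "))
  if (any(ls <= 0)) stop("non-positive library size for: ",
                         paste(utils::head(names(ls)[ls <= 0], 5),
                               collapse = ", "))
  counts * 1e9 / outer(as.numeric(gl), as.numeric(ls))
}

#' Apply the post-hoc FPKM filter to a differential-expression table
#'
#' Removes genes whose mean FPKM across the given samples is below the
#' threshold. The filter is applied after testing, so multiple-testing
#' adjustment is unchanged; it only prunes the reported table (and the
#' significance calls that require expression above the floor).
#'
#' @param de A DE result data.frame with a \code{gene} column (as from
#'   \code{\link{nb_wald_test}}).
#' @param fpkm FPKM matrix.
#' @param samples Optional sample ids over which the mean is taken
#'   (default: all columns of \code{fpkm}; the pipeline passes the
#'   contrast's own samples).
#' @param threshold Minimum mean FPKM to keep a gene (genes with mean
#'   strictly below it are removed; a mean exactly at the threshold is
#'   kept).
#' @return The filtered DE data.frame, with a \code{mean_fpkm} column.
#' @export
filter_fpkm_de <- function(de, fpkm, samples = colnames(fpkm),
                           threshold = 1) {
  common <- intersect(de$gene, rownames(fpkm))
  if (length(common) == 0)
    stop("no shared gene ids between DE table and FPKM matrix")
  de <- de[de$gene %in% common, , drop = FALSE]
  m <- rowMeans(fpkm[de$gene, samples, drop = FALSE])
  de$mean_fpkm <- as.numeric(m)
  de[de$mean_fpkm >= threshold, , drop = FALSE]
}

#' Filter genes for network construction
#'
#' A gene is removed when at least \code{ceiling(frac * n_samples)}
#' samples have FPKM below \code{threshold} (default: below 1 in >= 90\%
#' of samples, i.e. 18 of 20).
#'
#' @param fpkm FPKM matrix (genes x samples).
#' @param frac Fraction of samples that must be below threshold to drop
#'   the gene.
#' @param threshold FPKM floor.
#' @return The row-subset FPKM matrix of retained genes.
#' @export
filter_network_genes <- function(fpkm, frac = 0.9, threshold = 1) {
  if (ncol(fpkm) < 2) stop("need at least 2 samples")
  n_low <- rowSums(fpkm < threshold)
  keep <- n_low < ceiling(frac * ncol(fpkm))
  fpkm[keep, , drop = FALSE]
}

#' Variance-stabilizing log transform
#'
#' Elementwise log2(x + 1); preserves shape and dimnames.
#'
#' @param x Non-negative numeric matrix or vector.
#' @return log2(x + 1).
#' @export
log_transform <- function(x) {
  if (any(x < 0)) stop("log_transform requires non-negative values")
  log2(x + 1)
}
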
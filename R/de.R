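#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median across genes of
#' the ratio of each sample's count to the gene-wise geometric mean
#' (computed over genes expressed in every sample), then rescaled so the
#' factors have geometric mean 1. When no gene is expressed in all
#' samples, falls back to total-count ratios with a warning.
#'
#' @param counts Non-negative gene x sample count matrix.
#' @return Named numeric vector of positive size factors.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    warning("no gene expressed in all samples; using total-count ratios")
    sf <- colSums(counts)
  } else {
    sub <- counts[all_pos, , drop = FALSE]
    log_geo <- rowMeans(log(sub))
    sf <- apply(sub, 2, function(col) exp(stats::median(log(col) - log_geo)))
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(as.numeric(sf), colnames(counts))
}

#' Negative-binomial Wald test between two sample groups
#'
#' A simplified NB two-group test: counts are divided by size factors,
#' group means are computed, the dispersion is estimated per gene by
#' method of moments on the normalized counts pooled within groups
#' (floored at \code{alpha_floor}; optionally moderated toward the
#' genewise mean dispersion with \code{prior_df} prior degrees of
#' freedom), and a Wald statistic is formed for the log2 fold-change
#' log2((muB + c) / (muA + c)) with pseudocount c = 0.5 and a
#' delta-method standard error under Var(K) = mu + alpha * mu^2.
#' P-values are two-sided from a t reference on nA + nB - 2 degrees of
#' freedom, which accounts for the estimated dispersion (a normal
#' reference is available but anticonservative at the study's group
#' sizes);
#' Benjamini-Hochberg adjustment is applied over the tested genes. It
#' deliberately omits outlier replacement and independent filtering, so
#' it is not expected to be numerically identical to full
#' shrinkage-based NB engines.
#'
#' Genes with all-zero counts across both groups are reported untested:
#' log2FC 0, p 1, adjusted p NA.
#'
#' @param counts Gene x sample count matrix.
#' @param size_factors Named per-sample size factors (see
#'   \code{\link{estimate_size_factors}}).
#' @param group_a,group_b Character vectors of sample ids (baseline and
#'   delta group; the fold-change is B vs A). Each must have >= 2 samples.
#' @param pseudocount Fold-change pseudocount c.
#' @param alpha_floor Lower bound on the dispersion estimate.
#' @param prior_df Prior degrees of freedom pulling each gene's
#'   dispersion toward the genewise mean (0 disables moderation).
#' @param reference Null reference for the Wald statistic: \code{"t"}
#'   (default, nA + nB - 2 df) or \code{"normal"}.
#' @return Data.frame: \code{gene}, \code{base_mean} (mean normalized
#'   count over both groups), \code{log2fc}, \code{lfc_se}, \code{stat},
#'   \code{pvalue}, \code{padj}, \code{tested}.
#' @export
nb_wald_test <- function(counts, size_factors, group_a, group_b,
                         pseudocount = 0.5, alpha_floor = 1e-8,
                         prior_df = 0, reference = c("t", "normal")) {
  reference <- match.arg(reference)
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 samples for a dispersion estimate")
  if (!all(c(group_a, group_b) %in% colnames(counts)))
    stop("group sample ids missing from count matrix")
  sa <- size_factors[group_a]; sb <- size_factors[group_b]
  na <- length(group_a); nb <- length(group_b)
  norm_a <- sweep(counts[, group_a, drop = FALSE], 2, sa, "/")
  norm_b <- sweep(counts[, group_b, drop = FALSE], 2, sb, "/")

  mu_a <- rowMeans(norm_a)
  mu_b <- rowMeans(norm_b)
  v_a <- apply(norm_a, 1, stats::var)
  v_b <- apply(norm_b, 1, stats::var)

  # method-of-moments dispersion pooled across the two groups; the
  # E[1/s] term removes the Poisson part on the normalized scale
  inv_sa <- mean(1 / sa); inv_sb <- mean(1 / sb)
  num <- (na - 1) * (v_a - mu_a * inv_sa) + (nb - 1) * (v_b - mu_b * inv_sb)
  den <- (na - 1) * mu_a^2 + (nb - 1) * mu_b^2
  alpha <- pmax(alpha_floor, ifelse(den > 0, num / den, alpha_floor))
  if (prior_df > 0 && sum(den > 0) > 1) {
    # moderate the noisy per-gene MoM estimate toward the genewise mean;
    # stabilizes the Wald SE at small group sizes
    alpha_prior <- mean(alpha[den > 0])
    df_gene <- na + nb - 2
    alpha <- (prior_df * alpha_prior + df_gene * alpha) /
      (prior_df + df_gene)
  }

  c0 <- pseudocount
  log2fc <- log2((mu_b + c0) / (mu_a + c0))

  var_mu_a <- (mu_a * sum(1 / sa) + alpha * mu_a^2 * na) / na^2
  var_mu_b <- (mu_b * sum(1 / sb) + alpha * mu_b^2 * nb) / nb^2
  se <- sqrt(var_mu_a / (mu_a + c0)^2 + var_mu_b / (mu_b + c0)^2) / log(2)

  tested <- (mu_a + mu_b) > 0 & se > 0
  stat <- ifelse(tested, log2fc / se, 0)
  p <- if (reference == "t")
    ifelse(tested, 2 * stats::pt(-abs(stat), df = na + nb - 2), 1)
  else ifelse(tested, 2 * stats::pnorm(-abs(stat)), 1)
  padj <- rep(NA_real_, length(p))
  padj[tested] <- bh_adjust(p[tested])
  data.frame(gene = rownames(counts),
             base_mean = (na * mu_a + nb * mu_b) / (na + nb),
             log2fc = ifelse(tested, log2fc, 0),
             lfc_se = ifelse(tested, se, NA_real_),
             stat = stat, pvalue = p, padj = padj, tested = tested,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment with monotonicity enforcement;
#' missing values are propagated untouched.
#'
#' @param p Numeric vector of p-values in [0, 1] (NAs allowed).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' The four strain-by-diet contrasts
#'
#' Returns the contrast table of the 2x2 design: each contrast names its
#' baseline and delta group as (strain, diet) pairs. "selection" compares
#' the strains on the plant diet, "diet" the diets within the selected
#' strain, "strain" the strains on the fishmeal diet, and "enteritis" the
#' diets within the non-selected strain (where enteritis develops).
#'
#' @return Data.frame with columns \code{contrast},
#'   \code{baseline_strain}, \code{baseline_diet}, \code{delta_strain},
#'   \code{delta_diet}.
#' @export
design_contrasts <- function() {
  data.frame(
    contrast = c("selection", "diet", "strain", "enteritis"),
    baseline_strain = c("non_selected", "selected", "non_selected",
                        "non_selected"),
    baseline_diet = c("PM", "FM", "FM", "FM"),
    delta_strain = c("selected", "selected", "selected", "non_selected"),
    delta_diet = c("PM", "PM", "FM", "PM"),
    stringsAsFactors = FALSE)
}

#' Run all four design contrasts for one tissue
#'
#' Estimates size factors on the tissue's samples, runs the NB Wald test
#' for each of the four contrasts, optionally applies the post-hoc mean
#' FPKM >= threshold rule over each contrast's samples, and flags
#' significance at adjusted p below \code{alpha}.
#'
#' @param counts Gene x sample count matrix (all samples).
#' @param samples Sample table with \code{sample_id}, \code{strain},
#'   \code{diet}, \code{tissue}.
#' @param tissue Tissue to analyse ("liver" or "muscle").
#' @param fpkm Optional FPKM matrix for the expression floor.
#' @param alpha Adjusted-p significance threshold.
#' @param fpkm_threshold Mean-FPKM floor for calling significance.
#' @return A list with \code{results} (named list of DE data.frames, one
#'   per contrast, each with \code{significant}) and \code{summary}
#'   (data.frame of n significant / up / down per contrast).
#' @export
run_design_contrasts <- function(counts, samples, tissue, fpkm = NULL,
                                 alpha = 0.05, fpkm_threshold = 1) {
  sm <- samples[samples$tissue == tissue, , drop = FALSE]
  if (nrow(sm) == 0) stop("no samples for tissue ", tissue)
  counts <- counts[, sm$sample_id, drop = FALSE]
  sf <- estimate_size_factors(counts)
  cons <- design_contrasts()
  results <- list()
  for (i in seq_len(nrow(cons))) {
    ga <- sm$sample_id[sm$strain == cons$baseline_strain[i] &
                         sm$diet == cons$baseline_diet[i]]
    gb <- sm$sample_id[sm$strain == cons$delta_strain[i] &
                         sm$diet == cons$delta_diet[i]]
    if (length(ga) == 0 || length(gb) == 0)
      stop("missing group for contrast '", cons$contrast[i], "' (",
           if (length(ga) == 0) paste(cons$baseline_strain[i],
                                      cons$baseline_diet[i])
           else paste(cons$delta_strain[i], cons$delta_diet[i]), ")")
    de <- nb_wald_test(counts, sf, ga, gb)
    if (!is.null(fpkm)) {
      m <- rowMeans(fpkm[de$gene, c(ga, gb), drop = FALSE])
      de$mean_fpkm <- as.numeric(m)
    } else {
      de$mean_fpkm <- NA_real_
    }
    de$significant <- !is.na(de$padj) & de$padj < alpha &
      (is.null(fpkm) | de$mean_fpkm >= fpkm_threshold)
    results[[cons$contrast[i]]] <- de
  }
  summary <- do.call(rbind, lapply(names(results), function(nm) {
    de <- results[[nm]]
    data.frame(contrast = nm,
               n_significant = sum(de$significant),
               n_up = sum(de$significant & de$log2fc > 0),
               n_down = sum(de$significant & de$log2fc < 0),
               stringsAsFactors = FALSE)
  }))
  list(results = results, summary = summary)
}

#' Venn-region counts for DEG sets
#'
#' For k named sets, counts the elements falling in every exclusive Venn
#' region (members of exactly that combination of sets) and reports each
#' region's percentage of the union to one decimal.
#'
#' @param sets Named list (>= 2) of character vectors.
#' @return Data.frame: \code{region} (set names joined by "&"),
#'   \code{count}, \code{pct} of the union.
#' @export
venn_overlap <- function(sets) {
  if (length(sets) < 2) stop("need at least 2 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sets)))
  key <- apply(member, 1, function(r) paste(names(sets)[r], collapse = "&"))
  combos <- unlist(lapply(seq_along(sets), function(k)
    utils::combn(names(sets), k, paste, collapse = "&", simplify = FALSE)))
  counts <- vapply(combos, function(cb) sum(key == cb), integer(1))
  data.frame(region = combos, count = counts,
             pct = round(100 * counts / max(1, length(universe)), 1),
             row.names = NULL, stringsAsFactors = FALSE)
}
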
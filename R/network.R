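#' Canonical module color sequence
#'
#' Color labels assigned to modules in decreasing size order, following
#' the convention of weighted co-expression analysis where modules are
#' referred to by color and the largest module is "turquoise". Genes
#' outside any module are "grey".
#'
#' @return Character vector of color names.
#' @export
module_colors <- function() {
  c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
    "pink", "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown",
    "steelblue", "paleturquoise", "violet", "darkolivegreen",
    "darkmagenta", "sienna3", "yellowgreen", "skyblue3", "plum1",
    "orangered4", "mediumpurple3", "lightsteelblue1")
}

#' Soft-threshold scan for scale-free topology
#'
#' For each candidate power, builds the signed-hybrid adjacency, computes
#' whole-network connectivities, bins them into (up to) 10 equal-count
#' bins and regresses log10 of the bin frequency on log10 of the bin mean
#' connectivity. The scale-free fit index is R^2 signed by the negative
#' of the slope (a proper scale-free degree distribution has a negative
#' slope). The recommended power is the smallest one reaching
#' \code{rsq_cut}; when none does, the configured default is kept.
#'
#' @param expr Samples x genes matrix of log-transformed expression.
#' @param powers Candidate integer powers.
#' @param rsq_cut Fit-index threshold for recommending a power.
#' @param default_power Power returned when no candidate reaches the cut
#'   (the study value beta = 8).
#' @param n_bins Number of connectivity bins.
#' @return Data.frame (power, fit_index, slope, mean_k, median_k, max_k)
#'   with the chosen power in attribute \code{"power"}.
#' @export
soft_threshold_scan <- function(expr, powers = 1:20, rsq_cut = 0.8,
                                default_power = 8, n_bins = 10) {
  v <- apply(expr, 2, stats::var)
  if (any(v == 0)) expr <- expr[, v > 0, drop = FALSE]
  cc <- stats::cor(expr)
  cc <- pmax(cc, 0)
  diag(cc) <- 0
  rows <- lapply(powers, function(b) {
    k <- colSums(cc^b)
    fit <- scale_free_fit(k, n_bins = n_bins)
    data.frame(power = b, fit_index = fit$fit_index, slope = fit$slope,
               mean_k = mean(k), median_k = stats::median(k), max_k = max(k))
  })
  tab <- do.call(rbind, rows)
  ok <- which(tab$fit_index >= rsq_cut)
  attr(tab, "power") <- if (length(ok)) tab$power[min(ok)] else default_power
  tab
}

#' Scale-free topology fit index of a connectivity vector
#'
#' Bins connectivities into equal-width bins (frequencies within
#' equal-width bins estimate the degree distribution p(k), which is what
#' a power law constrains; equal-count bins would make the frequencies
#' flat by construction), then regresses log10(frequency) on
#' log10(mean connectivity) per bin. Returns R^2 signed by -slope.
#'
#' @param k Connectivity vector.
#' @param n_bins Requested number of bins (reduced with a warning when k
#'   has too few distinct values).
#' @return List with \code{fit_index} and \code{slope}.
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  n_distinct <- length(unique(k))
  if (n_distinct < 2) return(list(fit_index = NA_real_, slope = NA_real_))
  if (n_distinct < n_bins) {
    warning("fewer than ", n_bins, " distinct connectivities; using ",
            n_distinct, " bins")
    n_bins <- n_distinct
  }
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  p_dk <- tapply(k, bin, length) / length(k)
  keep <- !is.na(dk) & dk > 0 & p_dk > 0
  if (sum(keep) < 2) return(list(fit_index = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(p_dk[keep]) ~ log10(dk[keep]))
  r2 <- summary(fit)$r.squared
  slope <- unname(stats::coef(fit)[2])
  list(fit_index = r2 * sign(-slope), slope = slope)
}

#' Signed-hybrid adjacency
#'
#' a_ij = max(cor(x_i, x_j), 0)^beta with unit diagonal: positive
#' co-expression is raised to the soft-threshold power, negative
#' correlations contribute nothing.
#'
#' @param expr Samples x genes matrix.
#' @param beta Soft-threshold power (>= 1).
#' @return Symmetric genes x genes adjacency matrix in [0, 1].
#' @export
adjacency_signed_hybrid <- function(expr, beta = 8) {
  if (beta < 1) stop("beta must be >= 1")
  v <- apply(expr, 2, stats::var)
  if (any(v == 0))
    stop("zero-variance genes: ",
         paste(utils::head(colnames(expr)[v == 0], 5), collapse = ", "))
  a <- pmax(stats::cor(expr), 0)^beta
  diag(a) <- 1
  a
}

#' Topological overlap similarity
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij), where
#' the sum runs over u distinct from i and j and connectivity k excludes
#' the diagonal; TOM_ii = 1. Two genes overlap topologically when they
#' are connected to each other and share neighbors.
#'
#' @param adjacency Symmetric adjacency matrix in [0, 1] with unit
#'   diagonal.
#' @return TOM similarity matrix; the clustering dissimilarity is
#'   \code{1 - tom_similarity(a)}.
#' @export
tom_similarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (!isSymmetric(unname(a), tol = 1e-10)) stop("adjacency must be symmetric")
  if (any(a < 0) || any(a > 1 + 1e-12)) stop("adjacency must lie in [0, 1]")
  k <- colSums(a) - diag(a)
  # (A %*% A)[i,j] counts u over everything incl. u = i and u = j, each of
  # which contributes a_ij (diag is 1); remove both, then add back a_ij
  shared <- a %*% a - 2 * a
  num <- shared + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect co-expression modules by hierarchical clustering
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity with
#' a static cut at \code{cut_height}, followed (optionally) by recursive
#' branch splitting: any cluster large enough to contain two modules is
#' re-clustered and split in two whenever both branches reach
#' \code{min_module_size}, recursively. A flat cut alone cannot both
#' assemble modules and keep adjacent ones apart when their mutual
#' dissimilarity falls below the cut (e.g. modules sharing a common
#' driver such as diet); the recursive split separates such branches,
#' and any over-splitting of a genuinely homogeneous module is undone by
#' the eigengene-merging stage, whose merged eigengenes correlate far
#' above the merge threshold. Clusters smaller than
#' \code{min_module_size} are set to grey (unassigned). Module color
#' labels are assigned in decreasing size order over the canonical color
#' sequence.
#'
#' @param diss Dissimilarity matrix (typically 1 - TOM) in [0, 1].
#' @param min_module_size Smallest retained cluster.
#' @param cut_height Static tree-cut height.
#' @param split_branches Recursively split large branches (default TRUE;
#'   FALSE gives the plain static cut).
#' @return Named character vector gene -> color ("grey" = unassigned),
#'   with the \code{hclust} tree in attribute \code{"dendro"}.
#' @export
detect_modules <- function(diss, min_module_size = 30, cut_height = 0.99,
                           split_branches = TRUE) {
  d <- as.matrix(diss)
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  cl <- stats::cutree(tree, h = cut_height)
  clusters <- split(rownames(d), cl)
  clusters <- clusters[lengths(clusters) >= min_module_size]
  if (split_branches && length(clusters))
    clusters <- unlist(lapply(clusters, split_branch, d = d,
                              min_size = min_module_size),
                       recursive = FALSE, use.names = FALSE)
  colors <- rep("grey", nrow(d))
  names(colors) <- rownames(d)
  if (length(clusters) == 0) {
    warning("no cluster reaches min_module_size; all genes grey")
  } else {
    sizes <- lengths(clusters)
    first <- vapply(clusters, function(g) sort(g)[1], character(1))
    ord <- order(-sizes, first)
    palette <- module_colors()
    keep <- utils::head(ord, length(palette))  # beyond the palette stays grey
    for (i in seq_along(keep))
      colors[clusters[[keep[i]]]] <- palette[i]
  }
  attr(colors, "dendro") <- tree
  colors
}

# depth-first binary splitting of one cluster: re-cluster its genes and
# cut the top merge; halves of module size recurse independently, while
# sub-module-size twigs are set aside, the body is split further, and
# each twig gene is reattached to its nearest resulting piece (least
# mean dissimilarity), so loosely attached genes are kept
split_branch <- function(genes, d, min_size) {
  if (length(genes) < 2 * min_size) return(list(genes))
  sub <- stats::hclust(stats::as.dist(d[genes, genes]), method = "average")
  halves <- stats::cutree(sub, k = 2)
  pieces <- list(genes[halves == 1], genes[halves == 2])
  sizes <- lengths(pieces)
  if (any(sizes == 0)) return(list(genes))
  if (all(sizes >= min_size))
    return(unlist(lapply(pieces, split_branch, d = d, min_size = min_size),
                  recursive = FALSE))
  twig <- pieces[[which.min(sizes)]]
  out <- split_branch(pieces[[which.max(sizes)]], d, min_size)
  if (length(out) == 1) return(list(genes))  # nothing split off: keep whole
  for (g in twig) {
    near <- which.min(vapply(out, function(p) mean(d[g, p]), numeric(1)))
    out[[near]] <- c(out[[near]], g)
  }
  out
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' standardized (per-gene z-scored) expression block, scaled to unit
#' Euclidean norm and sign-oriented so that it correlates non-negatively
#' with the module's average expression profile. Constant genes are
#' dropped with a warning.
#'
#' @param expr Samples x genes matrix.
#' @param modules Named gene -> color vector (grey ignored).
#' @return List with \code{eigengenes} (samples x modules matrix, columns
#'   named \code{ME<color>}) and \code{var_explained} (named fraction of
#'   module variance captured by each eigengene).
#' @export
module_eigengenes <- function(expr, modules) {
  mods <- setdiff(unique(modules), "grey")
  if (length(mods) == 0) stop("no non-grey modules")
  me <- matrix(NA_real_, nrow = nrow(expr), ncol = length(mods),
               dimnames = list(rownames(expr), paste0("ME", mods)))
  ve <- stats::setNames(numeric(length(mods)), paste0("ME", mods))
  for (j in seq_along(mods)) {
    genes <- names(modules)[modules == mods[j]]
    block <- expr[, genes, drop = FALSE]
    v <- apply(block, 2, stats::var)
    if (any(v == 0)) {
      warning("dropping ", sum(v == 0), " constant gene(s) in module ",
              mods[j])
      block <- block[, v > 0, drop = FALSE]
    }
    if (ncol(block) < 2) stop("module ", mods[j], " has < 2 usable genes")
    z <- scale(block)
    sv <- svd(z, nu = 1, nv = 0)
    u <- sv$u[, 1]
    if (stats::cor(u, rowMeans(z)) < 0) u <- -u
    me[, j] <- u
    ve[j] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = me, var_explained = ve)
}

#' Merge modules with similar eigengenes
#'
#' Iteratively clusters module eigengenes by the dissimilarity
#' 1 - cor(ME_a, ME_b), merges every cluster falling below
#' \code{cut_height} (default 0.20, i.e. eigengene correlation above
#' 0.80), recomputes eigengenes and repeats until no pair of retained
#' eigengenes is closer than the cut. Merged modules keep the color of
#' their largest member; colors are then re-ranked by size.
#'
#' @param expr Samples x genes matrix.
#' @param modules Named gene -> color vector.
#' @param cut_height Eigengene-dissimilarity merge threshold.
#' @param relabel Re-assign colors by size rank after merging (default
#'   TRUE).
#' @param max_iter Safety bound on merge rounds.
#' @return List with \code{modules} (merged gene -> color vector) and
#'   \code{eigengenes} (recomputed, as in \code{\link{module_eigengenes}}).
#' @export
merge_modules <- function(expr, modules, cut_height = 0.20,
                          relabel = TRUE, max_iter = 25) {
  modules <- drop_attrs(modules)
  for (iter in seq_len(max_iter)) {
    mods <- setdiff(unique(modules), "grey")
    if (length(mods) < 2) break
    me <- module_eigengenes(expr, modules)$eigengenes
    diss <- 1 - stats::cor(me)
    tree <- stats::hclust(stats::as.dist(diss), method = "average")
    grp <- stats::cutree(tree, h = cut_height)
    if (max(table(grp)) == 1) break
    for (g in unique(grp)) {
      members <- sub("^ME", "", colnames(me)[grp == g])
      if (length(members) < 2) next
      sizes <- vapply(members, function(m) sum(modules == m), integer(1))
      keep <- members[which.max(sizes)]
      modules[modules %in% members] <- keep
    }
  }
  if (relabel) {
    mods <- setdiff(unique(modules), "grey")
    if (length(mods) > 0) {
      sizes <- vapply(mods, function(m) sum(modules == m), integer(1))
      ord <- mods[order(-sizes, mods)]
      palette <- module_colors()[seq_along(ord)]
      new <- modules
      for (i in seq_along(ord)) new[modules == ord[i]] <- palette[i]
      modules <- new
    }
  }
  eig <- if (length(setdiff(unique(modules), "grey")) > 0)
    module_eigengenes(expr, modules) else list(eigengenes = NULL,
                                               var_explained = NULL)
  list(modules = modules, eigengenes = eig)
}

drop_attrs <- function(x) {
  y <- as.vector(x)
  names(y) <- names(x)
  y
}

#' Module-trait correlations
#'
#' Pearson correlation of each module eigengene with each numeric trait,
#' with the p-value from the t distribution on n - 2 degrees of freedom.
#' Constant traits give missing statistics with a warning.
#'
#' @param eigengenes Samples x modules eigengene matrix.
#' @param traits Samples x traits numeric data.frame or matrix (binary
#'   traits such as diet coded 0/1).
#' @return Data.frame: \code{module}, \code{trait}, \code{cor}, \code{p}.
#' @export
module_trait_correlation <- function(eigengenes, traits) {
  traits <- as.data.frame(traits)
  n <- nrow(eigengenes)
  if (n < 3) stop("need at least 3 samples")
  out <- expand.grid(module = colnames(eigengenes), trait = names(traits),
                     stringsAsFactors = FALSE)
  out$cor <- NA_real_
  out$p <- NA_real_
  for (i in seq_len(nrow(out))) {
    tv <- traits[[out$trait[i]]]
    if (stats::sd(tv) == 0) {
      warning("trait '", out$trait[i], "' is constant; correlation undefined")
      next
    }
    r <- stats::cor(eigengenes[, out$module[i]], tv)
    tstat <- r * sqrt((n - 2) / max(1e-300, 1 - r^2))
    out$cor[i] <- r
    out$p[i] <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  out
}

#' Per-gene module membership (kME) and gene significance (GS)
#'
#' kME is the correlation of each gene's expression with each module
#' eigengene; GS is the correlation with a sample trait. A gene's primary
#' module membership is the module where its |kME| is largest.
#'
#' @param expr Samples x genes matrix.
#' @param eigengenes Samples x modules eigengene matrix.
#' @param trait Numeric trait vector over samples (e.g. diet 0/1).
#' @return List with \code{kme} (genes x modules), \code{gs} (named
#'   vector), \code{primary_module} (named color vector, "ME" prefix
#'   stripped).
#' @export
gene_statistics <- function(expr, eigengenes, trait) {
  stopifnot(nrow(expr) == nrow(eigengenes), nrow(expr) == length(trait))
  v <- apply(expr, 2, stats::var)
  kme <- matrix(NA_real_, ncol(expr), ncol(eigengenes),
                dimnames = list(colnames(expr), colnames(eigengenes)))
  gs <- stats::setNames(rep(NA_real_, ncol(expr)), colnames(expr))
  ok <- v > 0
  if (any(ok)) {
    kme[ok, ] <- stats::cor(expr[, ok, drop = FALSE], eigengenes)
    gs[ok] <- as.numeric(stats::cor(expr[, ok, drop = FALSE], trait))
  }
  primary <- apply(kme, 1, function(r) {
    if (all(is.na(r))) NA_character_
    else sub("^ME", "", colnames(kme)[which.max(abs(r))])
  })
  list(kme = kme, gs = gs, primary_module = primary)
}

#' Intramodular connectivity
#'
#' kWithin_i = sum of adjacencies from gene i to the other genes of its
#' module; grey (unassigned) genes get NA.
#'
#' @param adjacency Genes x genes adjacency matrix.
#' @param modules Named gene -> color vector.
#' @return Named numeric vector of kWithin.
#' @export
intramodular_connectivity <- function(adjacency, modules) {
  genes <- rownames(adjacency)
  kw <- stats::setNames(rep(NA_real_, length(genes)), genes)
  for (m in setdiff(unique(modules), "grey")) {
    idx <- which(modules[genes] == m)
    if (length(idx) == 1) { kw[idx] <- 0; next }
    block <- adjacency[idx, idx, drop = FALSE]
    kw[idx] <- colSums(block) - diag(block)
  }
  kw
}

#' Report-only outlier screen of samples
#'
#' Clusters samples by their expression distance and flags samples whose
#' merge height exceeds \code{z_cut} standard deviations above the mean
#' leaf height. Nothing is removed; the report is for inspection.
#'
#' @param expr Samples x genes matrix.
#' @param z_cut Robust z threshold for flagging.
#' @return Data.frame sample, height, flagged.
#' @export
sample_outlier_report <- function(expr, z_cut = 3) {
  d <- stats::dist(expr)
  tree <- stats::hclust(d, method = "average")
  h <- vapply(seq_len(nrow(expr)), function(i) {
    row <- which(tree$merge == -i, arr.ind = TRUE)[1]
    tree$height[row]
  }, numeric(1))
  z <- (h - mean(h)) / max(1e-12, stats::sd(h))
  data.frame(sample = rownames(expr), height = h, flagged = z > z_cut,
             stringsAsFactors = FALSE)
}

#' Build the full signed-hybrid co-expression network
#'
#' End-to-end network stage: signed-hybrid adjacency at the given power,
#' topological overlap, average-linkage module detection with a static
#' cut and minimum module size, eigengene computation, module merging at
#' the eigengene-dissimilarity threshold, module-trait correlation, kME /
#' gene-significance statistics and intramodular connectivity.
#'
#' @param expr Samples x genes matrix of filtered, log-transformed
#'   expression.
#' @param traits Samples x traits numeric data.frame (diet coded 0/1).
#' @param beta Soft-threshold power.
#' @param min_module_size Minimum module size.
#' @param merge_cut_height Eigengene merge threshold (0.20 merges
#'   eigengenes correlated above 0.80).
#' @param cut_height Static tree-cut height on the TOM dissimilarity.
#' @param trait_for_gs Name of the trait used for gene significance
#'   (default "diet").
#' @param kme_assign Module-membership threshold for the final
#'   assignment stage: unassigned (grey) genes whose largest eigengene
#'   correlation reaches this value join that module. At 20 samples,
#'   kME = 0.6 corresponds to p of about 0.005, so chance assignments
#'   are rare; set to 1 to disable.
#' @return Object of class \code{"coexpression_network"}: a list with
#'   \code{modules}, \code{eigengenes}, \code{var_explained},
#'   \code{module_trait}, \code{kme}, \code{gs}, \code{primary_module},
#'   \code{k_within}, \code{dendro}, and the parameters used.
#' @export
build_network <- function(expr, traits, beta = 8, min_module_size = 30,
                          merge_cut_height = 0.20, cut_height = 0.99,
                          trait_for_gs = "diet", kme_assign = 0.6) {
  v <- apply(expr, 2, stats::var)
  if (any(v == 0)) expr <- expr[, v > 0, drop = FALSE]
  adj <- adjacency_signed_hybrid(expr, beta = beta)
  tom <- tom_similarity(adj)
  modules <- detect_modules(1 - tom, min_module_size = min_module_size,
                            cut_height = cut_height)
  dendro <- attr(modules, "dendro")
  merged <- merge_modules(expr, modules, cut_height = merge_cut_height)
  me <- merged$eigengenes$eigengenes
  if (!is.null(me) && kme_assign < 1) {
    # assignment stage: grey genes strongly correlated with an eigengene
    # join that module (the tree cut misses loosely attached members)
    grey <- names(merged$modules)[merged$modules == "grey"]
    if (length(grey)) {
      km <- stats::cor(expr[, grey, drop = FALSE], me)
      best <- max.col(km, ties.method = "first")
      take <- km[cbind(seq_along(grey), best)] >= kme_assign
      merged$modules[grey[take]] <- sub("^ME", "", colnames(me)[best[take]])
      if (any(take)) {
        merged$eigengenes <- module_eigengenes(expr, merged$modules)
        me <- merged$eigengenes$eigengenes
      }
    }
  }
  mt <- if (!is.null(me)) module_trait_correlation(me, traits) else NULL
  gstat <- if (!is.null(me))
    gene_statistics(expr, me, traits[[trait_for_gs]])
  else list(kme = NULL, gs = NULL, primary_module = NULL)
  kw <- intramodular_connectivity(adj, merged$modules)
  out <- list(modules = merged$modules, eigengenes = me,
              var_explained = merged$eigengenes$var_explained,
              module_trait = mt, kme = gstat$kme, gs = gstat$gs,
              primary_module = gstat$primary_module, k_within = kw,
              dendro = dendro,
              params = list(beta = beta, min_module_size = min_module_size,
                            merge_cut_height = merge_cut_height,
                            cut_height = cut_height,
                            trait_for_gs = trait_for_gs,
                            kme_assign = kme_assign))
  class(out) <- "coexpression_network"
  out
}

#' @export
print.coexpression_network <- function(x, ...) {
  sizes <- sort(table(x$modules[x$modules != "grey"]), decreasing = TRUE)
  cat("Signed-hybrid co-expression network\n")
  cat("  genes:   ", length(x$modules), " (",
      sum(x$modules == "grey"), " unassigned)\n", sep = "")
  cat("  beta:    ", x$params$beta, "\n", sep = "")
  cat("  modules: ", length(sizes), "\n", sep = "")
  if (length(sizes)) {
    shown <- utils::head(sizes, 8)
    cat(paste0("    ", names(shown), ": ", shown, collapse = "\n"), "\n")
    if (length(sizes) > 8) cat("    ...\n")
  }
  invisible(x)
}

#' @export
summary.coexpression_network <- function(object, ...) {
  mt <- object$module_trait
  cat("Module-trait correlations (Pearson r, p on n-2 df):\n")
  if (!is.null(mt)) print(mt, digits = 3)
  invisible(mt)
}

#' Significant diet-correlated modules
#'
#' Modules whose eigengene correlates with the given trait at p at or
#' below the threshold (the study used p <= 0.003 against diet).
#'
#' @param net A \code{coexpression_network}.
#' @param trait Trait name.
#' @param p_cut Significance threshold.
#' @return Character vector of module colors.
#' @export
significant_modules <- function(net, trait = "diet", p_cut = 0.003) {
  mt <- net$module_trait
  if (is.null(mt)) return(character(0))
  sel <- mt$trait == trait & !is.na(mt$p) & mt$p <= p_cut
  sub("^ME", "", mt$module[sel])
}
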
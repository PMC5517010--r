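#' Simulation configuration for a synthetic strain-by-diet feeding trial
#'
#' Bundles every parameter of the synthetic study generator: a 2 (strain) x
#' 2 (diet) factorial with two tissues per fish, negative-binomial counts
#' with planted co-expression modules, continuous body traits, gene
#' annotation and histopathology scores. The defaults reproduce the study
#' conditions the package emulates: 10 fish per treatment group (80 RNA
#' libraries over two tissues), 5000 genes with three planted modules of
#' 100 genes whose latent factors correlate with the plant-meal diet at
#' |r| = 0.8 (one positively, two negatively, mirroring the sign pattern of
#' the published salmon/purple/turquoise modules), NB dispersion 0.1, and
#' an inverse hepatosomatic-index / plant-diet correlation of -0.5.
#'
#' @param n_fish_per_group Fish per strain-by-diet group (>= 2).
#' @param n_genes Total number of simulated genes.
#' @param module_sizes Integer vector of planted module sizes; their sum
#'   must not exceed \code{n_genes}. Remaining genes are independent
#'   background.
#' @param module_trait_cor Per-module correlation (in \code{[-1, 1]})
#'   between the module's latent factor and the plant-meal diet indicator.
#' @param module_log2fc Per-module additive log2 fold-change applied to
#'   plant-meal samples on top of the factor. A diet-correlated factor
#'   already shifts its genes between diets (about
#'   \code{2 * loading * module_trait_cor} log2 units), so the default is
#'   0; nonzero values plant additional shifts.
#' @param module_factor_sd Standard deviation, in log2 expression units, of
#'   the latent module factor's contribution (gene loadings are drawn
#'   uniformly from 0.5--1 and scaled by this value).
#' @param nb_dispersion Negative-binomial dispersion alpha (> 0), so that
#'   Var(K) = mu + alpha * mu^2.
#' @param library_size_mean Mean mapped-read count per library. The
#'   default (1e6) is a desk-scale stand-in for the tens of millions of
#'   reads of a production sequencing run.
#' @param gene_length_range Two-element numeric vector, the range (bp) of
#'   simulated transcript lengths.
#' @param hsi_diet_cor Target Pearson correlation between the
#'   hepatosomatic index and the plant-meal diet indicator (negative by
#'   default: plant-fed fish carry relatively smaller livers).
#' @param frac_uncharacterized Fraction of genes annotated as
#'   "uncharacterized"/"hypothetical" (no informative description).
#' @param n_histology_per_group Fish scored histologically per group.
#' @param seed Integer seed; identical configurations give identical
#'   outputs.
#'
#' @return An object of class \code{"sim_config"} (a validated list).
#' @export
sim_config <- function(n_fish_per_group = 10,
                       n_genes = 5000,
                       module_sizes = c(100, 100, 100),
                       module_trait_cor = c(0.8, -0.8, -0.8),
                       module_log2fc = c(0, 0, 0),
                       module_factor_sd = 1,
                       nb_dispersion = 0.1,
                       library_size_mean = 1e6,
                       gene_length_range = c(500, 5000),
                       hsi_diet_cor = -0.5,
                       frac_uncharacterized = 0.2,
                       n_histology_per_group = 6,
                       seed = 1L) {
  if (!is.numeric(n_fish_per_group) || n_fish_per_group < 2)
    stop("n_fish_per_group must be >= 2")
  if (n_genes < 1) stop("n_genes must be positive")
  k <- length(module_sizes)
  if (length(module_trait_cor) != k || length(module_log2fc) != k)
    stop("module_sizes, module_trait_cor and module_log2fc must have equal length")
  if (sum(module_sizes) > n_genes)
    stop("sum of module_sizes (", sum(module_sizes),
         ") exceeds n_genes (", n_genes, ")")
  if (any(abs(module_trait_cor) > 1))
    stop("module_trait_cor values must lie in [-1, 1]")
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (library_size_mean <= 0) stop("library_size_mean must be > 0")
  if (length(gene_length_range) != 2 || any(gene_length_range <= 0))
    stop("gene_length_range must be two positive lengths")
  cfg <- list(
    n_fish_per_group = as.integer(n_fish_per_group),
    n_genes = as.integer(n_genes),
    module_sizes = as.integer(module_sizes),
    module_trait_cor = as.numeric(module_trait_cor),
    module_log2fc = as.numeric(module_log2fc),
    module_factor_sd = module_factor_sd,
    nb_dispersion = nb_dispersion,
    library_size_mean = library_size_mean,
    gene_length_range = as.numeric(gene_length_range),
    hsi_diet_cor = hsi_diet_cor,
    frac_uncharacterized = frac_uncharacterized,
    n_histology_per_group = as.integer(n_histology_per_group),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic feeding-trial configuration\n")
  cat("  fish per group:   ", x$n_fish_per_group,
      " (", 4 * x$n_fish_per_group, " fish, ",
      8 * x$n_fish_per_group, " RNA libraries)\n", sep = "")
  cat("  genes:            ", x$n_genes, "\n", sep = "")
  cat("  planted modules:  ", paste(x$module_sizes, collapse = ", "),
      " genes; diet cor ", paste(x$module_trait_cor, collapse = ", "),
      "\n", sep = "")
  cat("  NB dispersion:    ", x$nb_dispersion, "\n", sep = "")
  cat("  seed:             ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Simulate the sample table of the feeding trial
#'
#' Generates the full factorial design: two strains (a line selected for
#' growth on an all-plant diet, and a non-selected control line) crossed
#' with two diets (fishmeal FM vs plant meal PM), \code{n_fish_per_group}
#' fish per group, and two tissue samples (liver, muscle) per fish. Body
#' traits are drawn per fish: weight is lognormal, the hepatosomatic index
#' (HSI, liver weight / body weight) is drawn so that its correlation with
#' the PM-diet indicator targets \code{cfg$hsi_diet_cor}, and liver weight
#' is \code{weight * hsi}.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return A data.frame with one row per sample (fish x tissue) and
#'   columns \code{sample_id}, \code{fish_id}, \code{strain}
#'   (\code{"selected"}/\code{"non_selected"}), \code{diet}
#'   (\code{"FM"}/\code{"PM"}), \code{tissue}
#'   (\code{"liver"}/\code{"muscle"}), \code{weight_g},
#'   \code{liver_weight_g} and \code{hsi}.
#' @export
simulate_design <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_fish_per_group
  groups <- expand.grid(strain = c("non_selected", "selected"),
                        diet = c("FM", "PM"),
                        stringsAsFactors = FALSE)
  fish <- groups[rep(seq_len(nrow(groups)), each = n), ]
  fish$fish_id <- sprintf("fish_%s_%s_%02d", substr(fish$strain, 1, 3),
                          fish$diet, rep(seq_len(n), times = nrow(groups)))
  nf <- nrow(fish)

  # weight: selected line grows faster, mild lognormal spread
  mu_w <- ifelse(fish$strain == "selected", log(450), log(380))
  fish$weight_g <- round(stats::rlnorm(nf, meanlog = mu_w, sdlog = 0.15), 1)

  # HSI built from a standardized PM indicator so the sample correlation
  # targets cfg$hsi_diet_cor in expectation
  pm <- as.numeric(fish$diet == "PM")
  z_pm <- (pm - mean(pm)) / stats::sd(pm)
  rho <- cfg$hsi_diet_cor
  latent <- rho * z_pm + sqrt(max(0, 1 - rho^2)) * stats::rnorm(nf)
  fish$hsi <- pmax(0.004, 0.013 + 0.0025 * latent)
  fish$liver_weight_g <- round(fish$weight_g * fish$hsi, 2)
  fish$hsi <- round(fish$hsi, 5)

  des <- fish[rep(seq_len(nf), each = 2), ]
  des$tissue <- rep(c("liver", "muscle"), times = nf)
  des$sample_id <- paste(des$fish_id, des$tissue, sep = "_")
  rownames(des) <- NULL
  des[, c("sample_id", "fish_id", "strain", "diet", "tissue",
          "weight_g", "liver_weight_g", "hsi")]
}

#' Simulate negative-binomial counts with planted co-expression modules
#'
#' Draws a gene x sample count matrix. Expected expression on the log2
#' scale is the sum of a gene baseline, a planted per-module latent factor
#' (one Gaussian factor per module and sample, correlated with the
#' sample's PM-diet indicator at the module's \code{module_trait_cor};
#' gene loadings uniform on 0.5--1), the module's diet log2 fold-change for
#' PM samples, and a library-size offset. Counts are negative binomial
#' with dispersion \code{cfg$nb_dispersion}. Background genes are
#' independent.
#'
#' @param design Sample table from \code{\link{simulate_design}}.
#' @param cfg A \code{\link{sim_config}}.
#' @return A list with \code{counts} (integer matrix, genes x samples),
#'   \code{gene_lengths} (named, bp), \code{library_sizes} (named, mapped
#'   reads per sample) and \code{gene_info} (data.frame with the planted
#'   module of each gene; \code{"background"} otherwise).
#' @export
simulate_counts <- function(design, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  ng <- cfg$n_genes
  ns <- nrow(design)
  genes <- sprintf("g%05d", seq_len(ng))
  k <- length(cfg$module_sizes)
  planted <- rep("background", ng)
  idx <- 0L
  for (m in seq_len(k)) {
    planted[idx + seq_len(cfg$module_sizes[m])] <- paste0("planted_", m)
    idx <- idx + cfg$module_sizes[m]
  }

  # baselines on the log2-FPKM scale: module genes are solidly expressed,
  # background spans the realistic range incl. genes below the FPKM-1 floor
  base <- stats::rnorm(ng, mean = 1.5, sd = 2.5)
  base[planted != "background"] <- stats::rnorm(sum(planted != "background"),
                                                mean = 3.5, sd = 1)

  lengths <- round(stats::runif(ng, cfg$gene_length_range[1],
                                cfg$gene_length_range[2]))
  names(lengths) <- genes
  libsize <- round(stats::rlnorm(ns, meanlog = log(cfg$library_size_mean),
                                 sdlog = 0.1))
  names(libsize) <- design$sample_id

  pm <- as.numeric(design$diet == "PM")
  z_pm <- (pm - mean(pm)) / stats::sd(pm)

  # module factors are planted with their correlation structure holding
  # exactly in-sample: an orthonormal basis (diet direction + one
  # residual direction per module) gives cor(f_m, diet) = rho_m and
  # cor(f_m, f_m') = rho_m * rho_m' exactly, so planted modules are
  # exactly as diet-driven, and as mutually distinct, as configured
  basis <- qr.Q(qr(cbind(1, z_pm, matrix(stats::rnorm(ns * k), ns, k))))
  u_diet <- basis[, 2] * sign(sum(basis[, 2] * z_pm))
  log2fpkm <- matrix(base, nrow = ng, ncol = ns)
  for (m in seq_len(k)) {
    rows <- which(planted == paste0("planted_", m))
    rho <- cfg$module_trait_cor[m]
    f <- rho * u_diet + sqrt(max(0, 1 - rho^2)) * basis[, m + 2]
    f <- f / stats::sd(f)
    load <- stats::runif(length(rows), 0.5, 1) * cfg$module_factor_sd
    log2fpkm[rows, ] <- log2fpkm[rows, ] + outer(load, f) +
      outer(rep(cfg$module_log2fc[m], length(rows)), pm)
  }

  mu <- 2^log2fpkm * outer(lengths, libsize) / 1e9
  counts <- matrix(stats::rnbinom(ng * ns, mu = mu,
                                  size = 1 / cfg$nb_dispersion),
                   nrow = ng, ncol = ns,
                   dimnames = list(genes, design$sample_id))
  list(counts = counts,
       gene_lengths = lengths,
       library_sizes = libsize,
       gene_info = data.frame(gene = genes, planted_module = planted,
                              stringsAsFactors = FALSE))
}

#' Simulate a gene annotation map
#'
#' Assigns each gene a symbol, a free-text description (a configurable
#' fraction flagged uncharacterized/hypothetical), 0--5 GO terms per
#' category (BP/MF/CC), an optional EC number and optional pathway
#' memberships. Term and pathway frequencies are configurable so that
#' enrichment signal can be planted: genes of a chosen planted module can
#' carry a chosen GO term at elevated frequency, and a chosen pathway can
#' be loaded with a large member set.
#'
#' @param genes Character vector of gene ids (e.g. from
#'   \code{\link{simulate_counts}}).
#' @param cfg A \code{\link{sim_config}}.
#' @param gene_info Optional data.frame from \code{\link{simulate_counts}}
#'   mapping genes to planted modules (required for planted enrichment).
#' @param planted_go Optional list \code{list(term=, category=, module=,
#'   prob_in=, prob_out=)}: GO term carried with probability
#'   \code{prob_in} by genes of planted module \code{module} and
#'   \code{prob_out} elsewhere.
#' @param planted_pathway Optional list \code{list(pathway=, n_members=,
#'   ec_frac=)}: a pathway assigned to the first \code{n_members} genes,
#'   a fraction of which carry distinct EC numbers.
#' @return A data.frame with one row per gene: \code{gene}, \code{symbol},
#'   \code{description}, \code{go_bp}, \code{go_mf}, \code{go_cc}
#'   (semicolon-separated term lists, possibly empty), \code{ec} and
#'   \code{pathways}.
#' @export
simulate_annotation <- function(genes, cfg, gene_info = NULL,
                                planted_go = NULL, planted_pathway = NULL) {
  stopifnot(inherits(cfg, "sim_config"), length(genes) > 0)
  set.seed(cfg$seed + 2L)
  ng <- length(genes)

  words <- c("kinase", "phosphatase", "transporter", "receptor", "ligase",
             "helicase", "dehydrogenase", "oxidase", "reductase", "carrier",
             "binding protein", "channel", "factor", "synthase", "protease")
  descr <- paste(sample(c("putative", "probable", ""), ng, replace = TRUE),
                 sample(words, ng, replace = TRUE),
                 sample(LETTERS, ng, replace = TRUE))
  descr <- trimws(descr)
  n_unchar <- round(cfg$frac_uncharacterized * ng)
  if (n_unchar > 0) {
    unchar <- sample(ng, n_unchar)
    descr[unchar] <- sample(c("uncharacterized protein",
                              "hypothetical protein",
                              "unknown protein"),
                            n_unchar, replace = TRUE)
  }

  draw_terms <- function(pool) {
    vapply(seq_len(ng), function(i) {
      nt <- sample(0:5, 1)
      if (nt == 0) "" else paste(sample(pool, nt), collapse = ";")
    }, character(1))
  }
  bp_pool <- sprintf("GO:%07d", 8100 + 1:40)
  mf_pool <- sprintf("GO:%07d", 3600 + 1:30)
  cc_pool <- sprintf("GO:%07d", 5500 + 1:20)
  ann <- data.frame(gene = genes,
                    symbol = toupper(sub("^g", "SYM", genes)),
                    description = descr,
                    go_bp = draw_terms(bp_pool),
                    go_mf = draw_terms(mf_pool),
                    go_cc = draw_terms(cc_pool),
                    stringsAsFactors = FALSE)

  if (!is.null(planted_go)) {
    if (is.null(gene_info)) stop("planted_go requires gene_info")
    in_mod <- gene_info$planted_module == planted_go$module
    carry <- stats::runif(ng) < ifelse(in_mod, planted_go$prob_in,
                                       planted_go$prob_out)
    col <- paste0("go_", tolower(planted_go$category))
    ann[[col]] <- ifelse(carry,
                         ifelse(nzchar(ann[[col]]),
                                paste(ann[[col]], planted_go$term, sep = ";"),
                                planted_go$term),
                         ann[[col]])
  }

  has_ec <- stats::runif(ng) < 0.3
  ann$ec <- ifelse(has_ec,
                   sprintf("ec:%d.%d.%d.%d", sample(1:6, ng, TRUE),
                           sample(1:9, ng, TRUE), sample(1:9, ng, TRUE),
                           sample(1:99, ng, TRUE)),
                   "")
  pw_pool <- sprintf("map%05d", sample(c(10, 20, 30, 40, 230, 240, 500,
                                         620, 730, 980), 10))
  in_pw <- stats::runif(ng) < 0.15
  ann$pathways <- ifelse(in_pw, sample(pw_pool, ng, replace = TRUE), "")

  if (!is.null(planted_pathway)) {
    members <- seq_len(min(planted_pathway$n_members, ng))
    ann$pathways[members] <- ifelse(nzchar(ann$pathways[members]),
                                    paste(ann$pathways[members],
                                          planted_pathway$pathway, sep = ";"),
                                    planted_pathway$pathway)
    need_ec <- members[stats::runif(length(members)) <
                         planted_pathway$ec_frac & !nzchar(ann$ec[members])]
    if (length(need_ec))
      ann$ec[need_ec] <- sprintf("ec:2.7.1.%d", seq_along(need_ec))
  }
  ann
}

#' Simulate histopathology scores for the distal intestine
#'
#' Scores seven variables per fish on a continuous 1--5 scale (mucosal
#' fold fusion MF, lamina propria LP, sub-epithelial mucosa SM,
#' supranuclear vacuolization SNV, goblet cells GC, eosinophilic
#' granulocytes EG, total inflammatory cells TIC). Group means are
#' configurable; the default ordering puts the non-selected plant-fed
#' group highest (enteritis), then non-selected FM, selected FM, and
#' selected PM lowest, matching the phenotype the selected line was bred
#' for. Values falling outside [1, 5] are clipped with a warning.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param group_means Named numeric vector of mean scores per group
#'   (names \code{"non_selected_PM"}, \code{"non_selected_FM"},
#'   \code{"selected_FM"}, \code{"selected_PM"}).
#' @param score_sd Within-group standard deviation of each score.
#' @return Data.frame: \code{fish_id}, \code{strain}, \code{diet},
#'   \code{group}, and columns \code{MF}, \code{LP}, \code{SM},
#'   \code{SNV}, \code{GC}, \code{EG}, \code{TIC}.
#' @export
simulate_histology <- function(cfg,
                               group_means = c(non_selected_PM = 3.2,
                                               non_selected_FM = 2.2,
                                               selected_FM = 2.0,
                                               selected_PM = 1.8),
                               score_sd = 0.5) {
  stopifnot(inherits(cfg, "sim_config"))
  need <- c("non_selected_PM", "non_selected_FM", "selected_FM",
            "selected_PM")
  if (!all(need %in% names(group_means)))
    stop("group_means must name all four treatment groups")
  set.seed(cfg$seed + 3L)
  n <- cfg$n_histology_per_group
  vars <- c("MF", "LP", "SM", "SNV", "GC", "EG", "TIC")
  tab <- do.call(rbind, lapply(need, function(g) {
    parts <- strsplit(g, "_(?=[A-Z]+$)", perl = TRUE)[[1]]
    scores <- matrix(stats::rnorm(n * length(vars), mean = group_means[g],
                                  sd = score_sd),
                     nrow = n, dimnames = list(NULL, vars))
    data.frame(fish_id = sprintf("histo_%s_%02d", g, seq_len(n)),
               strain = parts[1], diet = parts[2], group = g,
               scores, stringsAsFactors = FALSE)
  }))
  sc <- as.matrix(tab[, vars])
  if (any(sc < 1) || any(sc > 5)) {
    warning("histology scores outside [1, 5] were clipped")
    sc[] <- pmin(5, pmax(1, sc))
    tab[, vars] <- sc
  }
  rownames(tab) <- NULL
  tab
}

#' Simulate the complete synthetic study
#'
#' Convenience wrapper running \code{\link{simulate_design}},
#' \code{\link{simulate_counts}}, FPKM computation,
#' \code{\link{simulate_annotation}} and \code{\link{simulate_histology}}
#' from one configuration, optionally writing all tables as TSV.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param out_dir Optional directory; when given, writes
#'   \code{samples.tsv}, \code{counts.tsv}, \code{fpkm.tsv},
#'   \code{lengths.tsv}, \code{annotation.tsv}, \code{histology.tsv} and
#'   the configuration as \code{config.json} (if \pkg{jsonlite} is
#'   available) into it.
#' @param ... Passed to \code{\link{simulate_annotation}} (e.g.
#'   \code{planted_go}).
#' @return A list with elements \code{config}, \code{design},
#'   \code{counts}, \code{gene_lengths}, \code{library_sizes},
#'   \code{gene_info}, \code{fpkm}, \code{annotation}, \code{histology}.
#' @export
simulate_study <- function(cfg = sim_config(), out_dir = NULL, ...) {
  design <- simulate_design(cfg)
  cnt <- simulate_counts(design, cfg)
  fpkm <- compute_fpkm(cnt$counts, cnt$gene_lengths, cnt$library_sizes)
  ann <- simulate_annotation(rownames(cnt$counts), cfg,
                             gene_info = cnt$gene_info, ...)
  histo <- simulate_histology(cfg)
  res <- list(config = cfg, design = design, counts = cnt$counts,
              gene_lengths = cnt$gene_lengths,
              library_sizes = cnt$library_sizes,
              gene_info = cnt$gene_info, fpkm = fpkm, annotation = ann,
              histology = histo)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE,
      row.names = is.matrix(x), col.names = if (is.matrix(x)) NA else TRUE)
    wt(design, "samples.tsv")
    wt(res$counts, "counts.tsv")
    wt(round(fpkm, 4), "fpkm.tsv")
    wt(data.frame(gene = names(cnt$gene_lengths),
                  length_bp = cnt$gene_lengths), "lengths.tsv")
    wt(ann, "annotation.tsv")
    wt(histo, "histology.tsv")
    if (requireNamespace("jsonlite", quietly = TRUE))
      jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                           auto_unbox = TRUE)
  }
  res
}
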
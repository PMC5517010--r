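histology_variables <- c("MF", "LP", "SM", "SNV", "GC", "EG", "TIC")

#' Cumulative histopathology score
#'
#' Sums the seven enteritis scoring variables (mucosal fold fusion,
#' lamina propria, sub-epithelial mucosa, supranuclear vacuolization,
#' goblet cells, eosinophilic granulocytes, total inflammatory cells;
#' each on a 1--5 scale) per fish, and reports group means per variable
#' and in total.
#'
#' @param tab Histology data.frame with \code{fish_id}, \code{group} and
#'   the seven variable columns.
#' @return List with \code{per_fish} (fish_id, group, total in [7, 35])
#'   and \code{per_group} (group means of each variable and of the
#'   total).
#' @export
cumulative_score <- function(tab) {
  missing_vars <- setdiff(histology_variables, names(tab))
  if (length(missing_vars))
    stop("missing histology variable(s): ",
         paste(missing_vars, collapse = ", "))
  total <- rowSums(tab[, histology_variables])
  per_fish <- data.frame(fish_id = tab$fish_id, group = tab$group,
                         total = total, stringsAsFactors = FALSE)
  agg <- stats::aggregate(tab[, histology_variables], list(group = tab$group),
                          mean)
  agg$total <- stats::aggregate(total, list(group = tab$group), mean)$x
  list(per_fish = per_fish, per_group = agg)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H with the chi-square approximation on
#' k - 1 degrees of freedom (via \code{stats::kruskal.test}). With all
#' observations identical, H = 0 and p = 1.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels (same length).
#' @return List: \code{H}, \code{df}, \code{p}.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (stats::var(values) == 0)
    return(list(H = 0, df = nlevels(groups) - 1L, p = 1))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Dunn's post-hoc test
#'
#' Pairwise rank comparisons following a Kruskal-Wallis test: on pooled
#' midranks, z_gh = (Rbar_g - Rbar_h) / sqrt((N(N+1)/12 -
#' sum(t^3 - t)/(12(N-1))) (1/n_g + 1/n_h)) with the tie correction, a
#' two-sided normal p-value, and Benjamini-Hochberg adjusted p alongside.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels.
#' @return Data.frame: \code{group1}, \code{group2}, \code{z}, \code{p},
#'   \code{padj}. Pairs with a zero variance term give missing values.
#' @export
dunn_posthoc <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  r <- rank(values)
  n_tot <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties)
  base_var <- n_tot * (n_tot + 1) / 12 - tie_term / (12 * (n_tot - 1))
  mean_r <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  pairs <- utils::combn(levels(groups), 2)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    z = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    g <- pairs[1, i]; h <- pairs[2, i]
    v <- base_var * (1 / n_g[[g]] + 1 / n_g[[h]])
    if (!is.finite(v) || v <= 0) next
    z <- (mean_r[[g]] - mean_r[[h]]) / sqrt(v)
    out$z[i] <- z
    out$p[i] <- 2 * stats::pnorm(-abs(z))
  }
  out$padj <- bh_adjust(out$p)
  out
}
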
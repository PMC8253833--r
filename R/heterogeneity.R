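# ---- cell-to-cell heterogeneity --------------------------------------------
# The heterogeneity statistic: Pearson correlation of log2(FPKM + 1) over the
# top-variance genes for every unordered pair of CTCs within a vascular site.
# A lower mean correlation means a more heterogeneous site. Sites are compared
# on their pairwise-correlation distributions.

#' Select the most variable genes
#'
#' Variance is computed on `log2(x + 1)` across the included cells;
#' all-constant genes are removed first. Ties at the variance cutoff are
#' broken by ascending gene id, so the selection is deterministic.
#'
#' @param matrix A `ctc_expr` matrix.
#' @param k Number of genes to keep (default 2000).
#' @param cell_subset Optional cell ids defining the population.
#' @return Character vector of gene ids, most variable first.
#' @export
select_variable_genes <- function(matrix, k = 2000, cell_subset = NULL) {
  if (!is.null(cell_subset)) matrix <- matrix[, cell_subset, drop = FALSE]
  lg <- log2(unclass(matrix) + 1)
  v <- apply(lg, 1, stats::var)
  v <- v[v > 0]
  if (length(v) < k) {
    warning(sprintf(
      "select_variable_genes: only %d non-constant genes (< k = %d); returning all",
      length(v), k))
    k <- length(v)
  }
  ord <- order(-v, names(v))
  names(v)[ord][seq_len(k)]
}

# pairwise Pearson correlations between all unordered column pairs of a
# log2(x+1) submatrix; constant columns yield dropped pairs (counted)
pairwise_cors <- function(lg) {
  n <- ncol(lg)
  keep <- apply(lg, 2, stats::sd) > 0
  dropped <- 0L
  cm <- suppressWarnings(stats::cor(lg))
  ut <- upper.tri(cm)
  vals <- cm[ut]
  ok <- outer(keep, keep, "&")[ut]
  dropped <- sum(!ok)
  list(r = vals[ok], n_pairs = sum(ut), dropped = dropped)
}

#' Per-site heterogeneity report
#'
#' For every unordered pair of CTCs within a site (within patients by
#' default; `pairing = "pooled"` also pairs cells of different patients),
#' computes the Pearson correlation of `log2(x + 1)` over `genes`, then
#' compares the per-site correlation distributions between all site pairs
#' with a two-sided Wilcoxon rank-sum test (default) or Welch t test.
#'
#' @param matrix A `ctc_expr` matrix.
#' @param cells Cell metadata aligned to the matrix (only `CTC`-class cells
#'   enter the statistic).
#' @param genes Gene ids to correlate over (e.g.
#'   [select_variable_genes()] output).
#' @param pairing `"within_patient"` (default) or `"pooled"`.
#' @param test `"wilcoxon"` (default), `"welch"`, or `"both"`.
#' @return A `ctc_heterogeneity` report: per-site correlation vectors, site
#'   mean r, and pairwise site comparisons.
#' @export
site_heterogeneity <- function(matrix, cells, genes,
                               pairing = c("within_patient", "pooled"),
                               test = c("wilcoxon", "welch", "both")) {
  pairing <- match.arg(pairing)
  test <- match.arg(test)
  al <- align_cells(matrix, cells)
  cells <- al$cells
  ctc <- cells[cells$cell_class == "CTC", , drop = FALSE]
  lg <- log2(unclass(al$matrix)[genes, , drop = FALSE] + 1)

  site_r <- list(); dropped <- integer(0)
  for (s in unique(ctc$site)) {
    ids <- ctc$cell_id[ctc$site == s]
    if (length(ids) < 2) {
      warning(sprintf("site_heterogeneity: site %s has < 2 CTCs; excluded", s))
      next
    }
    if (pairing == "within_patient") {
      pats <- ctc$patient_id[ctc$site == s]
      rs <- numeric(0); drp <- 0L
      for (p in unique(pats)) {
        pid <- ids[pats == p]
        if (length(pid) < 2) next
        pc <- pairwise_cors(lg[, pid, drop = FALSE])
        rs <- c(rs, pc$r); drp <- drp + pc$dropped
      }
      if (length(rs) == 0) {
        warning(sprintf(
          "site_heterogeneity: site %s has no within-patient pair; excluded", s))
        next
      }
      site_r[[s]] <- rs; dropped[s] <- drp
    } else {
      pc <- pairwise_cors(lg[, ids, drop = FALSE])
      site_r[[s]] <- pc$r; dropped[s] <- pc$dropped
    }
  }

  sites <- names(site_r)
  comparisons <- list()
  if (length(sites) >= 2) {
    for (i in seq_len(length(sites) - 1)) for (j in (i + 1):length(sites)) {
      a <- site_r[[sites[i]]]; b <- site_r[[sites[j]]]
      res <- list()
      if (test %in% c("wilcoxon", "both"))
        res$wilcoxon <- wilcoxon_rank_sum(a, b)
      if (test %in% c("welch", "both"))
        res$welch <- welch_t(a, b)
      comparisons[[sprintf("%s_vs_%s", sites[i], sites[j])]] <- res
    }
  }

  out <- list(genes = genes,
              site_r = site_r,
              mean_r = vapply(site_r, mean, numeric(1)),
              dropped_pairs = dropped,
              comparisons = comparisons,
              pairing = pairing, test = test)
  class(out) <- "ctc_heterogeneity"
  out
}

#' @export
print.ctc_heterogeneity <- function(x, ...) {
  cat(sprintf("Heterogeneity over %d genes (%s pairing)\n",
              length(x$genes), x$pairing))
  for (s in names(x$mean_r))
    cat(sprintf("  %-4s mean r = %.4f (%d pairs)\n",
                s, x$mean_r[[s]], length(x$site_r[[s]])))
  for (nm in names(x$comparisons)) {
    res <- x$comparisons[[nm]][[1]]
    cat(sprintf("  %s: p = %.3g (%s)\n", nm, res$p_value, res$method))
  }
  invisible(x)
}

#' @export
plot.ctc_heterogeneity <- function(x, ...) {
  graphics::boxplot(x$site_r, ylab = "pairwise Pearson r",
                    xlab = "vascular site", ...)
  invisible(x)
}
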
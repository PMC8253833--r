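# ---- staged marker cascade and gene-set enrichment -------------------------
# Cascade stages over a two-group contrast:
#   tested    -> all genes surviving the CPM prefilter
#   initial   -> |log2FC| > 1 AND p < 0.05 AND BH q < 0.05
#   potential -> initial, up-group mean log2 fold change > 1 toward the
#                up-group AND expressed (FPKM > 1) in >= 90% of up-group cells
#   final     -> potential AND confirmatory rank-sum p < 0.05
# log2FC is the difference of group means of log2(x + 1) (pseudocount 1).

#' CPM prefilter
#'
#' Removes a gene when its CPM is below `min_cpm` in more than
#' `max_low_samples` samples.
#'
#' @param matrix A `ctc_expr` matrix tagged CPM.
#' @param max_low_samples Tolerated low-expression samples (default 2).
#' @param min_cpm Low-expression threshold (default 1, strict `<`).
#' @return Named logical keep-mask over genes.
#' @export
cpm_prefilter <- function(matrix, max_low_samples = 2, min_cpm = 1) {
  require_unit(matrix, "CPM")
  low <- rowSums(unclass(matrix) < min_cpm)
  stats::setNames(low <= max_low_samples, rownames(matrix))
}

# per-gene two-sided rank-sum p over the rows of log2 submatrices
rowwise_wilcoxon <- function(la, lb, exact_limit = 12) {
  n1 <- ncol(la); n2 <- ncol(lb)
  vapply(seq_len(nrow(la)), function(i) {
    wilcoxon_rank_sum(la[i, ], lb[i, ], exact_limit = exact_limit)$p_value
  }, numeric(1))
}

#' Two-group differential expression test
#'
#' Per gene: two-sided Wilcoxon rank-sum on `log2(x + 1)`, log2 fold change
#' as the difference of group means of `log2(x + 1)`, BH adjustment over the
#' tested genes, and the `initial` stage call.
#'
#' @param matrix A `ctc_expr` matrix (FPKM) restricted to prefiltered genes.
#' @param group_a,group_b Cell ids of the two groups (>= 2 each); fold
#'   change is `mean(A) - mean(B)` on the log2 scale.
#' @param fc_threshold,p_threshold,q_threshold Initial-stage cutoffs.
#' @param contrast Label stored with the table.
#' @param exact_limit Passed to the rank-sum test.
#' @return A `ctc_marker_table` data.frame with per-gene statistics and a
#'   `stage` column in `{tested, initial}`.
#' @export
differential_test <- function(matrix, group_a, group_b,
                              fc_threshold = 1, p_threshold = 0.05,
                              q_threshold = 0.05,
                              contrast = "A_vs_B", exact_limit = 12) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("differential_test: each group needs >= 2 cells")
  la <- log2(unclass(matrix)[, group_a, drop = FALSE] + 1)
  lb <- log2(unclass(matrix)[, group_b, drop = FALSE] + 1)
  mean_a <- rowMeans(la); mean_b <- rowMeans(lb)
  p <- rowwise_wilcoxon(la, lb, exact_limit)
  q <- bh_fdr(p)
  log2fc <- mean_a - mean_b
  stage <- ifelse(abs(log2fc) > fc_threshold & p < p_threshold &
                    q < q_threshold, "initial", "tested")
  tab <- data.frame(gene_id = rownames(matrix),
                    mean_a = mean_a, mean_b = mean_b,
                    log2fc = log2fc, p = p, q = q,
                    expressed_frac_a = rowMeans(unclass(matrix)[, group_a,
                                                                drop = FALSE] > 1),
                    expressed_frac_b = rowMeans(unclass(matrix)[, group_b,
                                                                drop = FALSE] > 1),
                    stage = stage, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  attr(tab, "contrast") <- contrast
  attr(tab, "groups") <- list(a = group_a, b = group_b)
  class(tab) <- c("ctc_marker_table", "data.frame")
  tab
}

#' Refine initial DEGs into potential and final markers
#'
#' Promotes an `initial` gene to `potential` when its group-mean log2 fold
#' change exceeds `fc_threshold` toward the up-group and it is expressed
#' (FPKM > `expressed_fpkm`) in at least `expressed_min_fraction` of the
#' up-group cells, and to `final` when the confirmatory rank-sum p is below
#' `confirm_p`.
#'
#' @param table A `ctc_marker_table` from [differential_test()].
#' @param matrix The FPKM matrix the table was computed from.
#' @param expressed_min_fraction Up-group expressed fraction (default 0.90,
#'   `>=`).
#' @param expressed_fpkm Expression threshold (default 1, strict `>`).
#' @param fc_threshold Fold-change requirement (log2, strict `>`).
#' @param confirm_p Confirmatory p threshold (default 0.05).
#' @return The table with stages upgraded in place.
#' @export
refine_upregulated <- function(table, matrix,
                               expressed_min_fraction = 0.90,
                               expressed_fpkm = 1,
                               fc_threshold = 1, confirm_p = 0.05) {
  up_a <- table$log2fc > 0
  expressed_up <- ifelse(up_a, table$expressed_frac_a, table$expressed_frac_b)
  if (expressed_fpkm != 1) {
    groups <- attr(table, "groups")
    fa <- rowMeans(unclass(matrix)[table$gene_id, groups$a,
                                   drop = FALSE] > expressed_fpkm)
    fb <- rowMeans(unclass(matrix)[table$gene_id, groups$b,
                                   drop = FALSE] > expressed_fpkm)
    expressed_up <- ifelse(up_a, fa, fb)
  }
  potential <- table$stage == "initial" &
    abs(table$log2fc) > fc_threshold &
    expressed_up >= expressed_min_fraction
  table$stage[potential] <- "potential"
  final <- potential & table$p < confirm_p
  table$stage[final] <- "final"
  table
}

#' Genes at or above a cascade stage
#' @param table A `ctc_marker_table`.
#' @param stage One of `initial`, `potential`, `final`.
#' @return Character vector of gene ids whose stage is `stage` or later.
#' @export
stage_genes <- function(table, stage = c("initial", "potential", "final")) {
  stage <- match.arg(stage)
  ladder <- c(initial = 1, potential = 2, final = 3)
  lev <- ladder[table$stage]
  lev[is.na(lev)] <- 0
  table$gene_id[lev >= ladder[[stage]]]
}

#' @export
print.ctc_marker_table <- function(x, ...) {
  cat(sprintf("Marker table [%s]: %d genes tested\n",
              attr(x, "contrast"), nrow(x)))
  for (s in c("initial", "potential", "final"))
    cat(sprintf("  >= %-9s %d\n", s, length(stage_genes(x, s))))
  invisible(x)
}

#' Hypergeometric gene-set over-representation
#'
#' Upper-tail hypergeometric overlap test of a query gene list against each
#' set, BH-adjusted across sets, sorted by q then p.
#'
#' @param query Character vector of genes (e.g. final markers).
#' @param sets A `ctc_gene_sets` collection (or named list).
#' @param universe Either the universe size (count) or a character vector of
#'   universe gene ids; sets and query are intersected with a character
#'   universe.
#' @return data.frame: set, set_size, overlap, p, q.
#' @export
enrich <- function(query, sets, universe) {
  if (length(query) == 0) stop("enrich: empty query")
  if (is.character(universe)) {
    query <- intersect(query, universe)
    sets <- lapply(sets, intersect, universe)
    universe_n <- length(universe)
  } else {
    universe_n <- as.integer(universe)
  }
  if (any(vapply(sets, length, numeric(1)) > universe_n))
    stop("enrich: a set is larger than the universe")
  res <- data.frame(
    set = names(sets),
    set_size = vapply(sets, length, numeric(1)),
    overlap = vapply(sets, function(s) length(intersect(s, query)),
                     numeric(1)),
    stringsAsFactors = FALSE)
  res$p <- vapply(seq_len(nrow(res)), function(i) {
    hypergeom_overlap(universe_n, res$set_size[i], length(query),
                      res$overlap[i])$p_value
  }, numeric(1))
  res$q <- bh_fdr(res$p)
  res <- res[order(res$q, res$p), , drop = FALSE]
  rownames(res) <- NULL
  res
}
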
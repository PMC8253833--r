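# ---- transcription-factor / target correlation screen ----------------------
# Ranks candidate TFs by the Pearson correlation of their log2(x + 1)
# expression with a target gene across cells (the MAX -> CCL5 style screen),
# with t-distribution p-values, BH adjustment, and an optional restriction to
# TFs at a given marker-cascade stage (e.g. "upregulated in CTCs").

#' Screen TFs for correlation with a target gene
#'
#' @param matrix A `ctc_expr` matrix.
#' @param tf_list Candidate TF gene ids; TFs absent from the matrix are
#'   dropped with a warning.
#' @param target Target gene id (must be non-constant over the cells).
#' @param cells Optional cell ids to restrict to (e.g. QC-passing CTCs).
#' @param restrict_to Optional `ctc_marker_table` plus stage: a list
#'   `list(table =, stage =)`; only TFs at or above that stage are screened.
#' @param exact_p Use an exact permutation p-value when the cell count is
#'   at most `exact_limit`.
#' @param exact_limit Cell-count bound for the permutation p (default 10).
#' @return A `ctc_tf_screen` data.frame sorted by descending r with columns
#'   tf, r, p, q, rank; attribute `n_positive` counts TFs with r > 0 and
#'   p < 0.05.
#' @export
screen_tfs <- function(matrix, tf_list, target, cells = NULL,
                       restrict_to = NULL, exact_p = TRUE,
                       exact_limit = 10) {
  if (!target %in% rownames(matrix))
    stop("screen_tfs: target gene not in matrix")
  if (!is.null(cells)) matrix <- matrix[, cells, drop = FALSE]
  if (ncol(matrix) < 3) stop("screen_tfs: need >= 3 cells")
  if (!is.null(restrict_to))
    tf_list <- intersect(tf_list,
                         stage_genes(restrict_to$table, restrict_to$stage))
  missing <- setdiff(tf_list, rownames(matrix))
  if (length(missing)) {
    warning(sprintf("screen_tfs: %d TF(s) not in matrix; dropped",
                    length(missing)))
    tf_list <- setdiff(tf_list, missing)
  }
  tf_list <- setdiff(tf_list, target)
  if (length(tf_list) == 0) stop("screen_tfs: no screenable TFs")

  lg <- log2(unclass(matrix) + 1)
  y <- lg[target, ]
  if (stats::sd(y) == 0) stop("screen_tfs: target is constant over cells")
  n <- length(y)

  r <- vapply(tf_list, function(tf) {
    xv <- lg[tf, ]
    if (stats::sd(xv) == 0) return(NA_real_)
    pearson_cor(xv, y)
  }, numeric(1))
  constant <- is.na(r)
  if (any(constant)) {
    warning(sprintf("screen_tfs: %d constant TF(s) dropped", sum(constant)))
    tf_list <- tf_list[!constant]; r <- r[!constant]
  }

  p <- vapply(seq_along(r), function(i) {
    if (exact_p && n <= exact_limit) {
      # exact permutation two-sided p over all orderings (n <= 10)
      xv <- lg[tf_list[i], ]
      perms <- permute_all(n)
      robs <- abs(r[i])
      rs <- apply(perms, 1, function(idx) stats::cor(xv[idx], y))
      mean(abs(rs) >= robs - 1e-12)
    } else {
      tt <- r[i] * sqrt((n - 2) / (1 - r[i]^2))
      2 * stats::pt(-abs(tt), n - 2)
    }
  }, numeric(1))

  out <- data.frame(tf = tf_list, r = r, p = p, q = bh_fdr(p),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$r), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "n_positive") <- sum(out$r > 0 & out$p < 0.05)
  attr(out, "target") <- target
  attr(out, "n_cells") <- n
  class(out) <- c("ctc_tf_screen", "data.frame")
  out
}

# all permutations of 1..n (n small)
permute_all <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permute_all(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' @export
print.ctc_tf_screen <- function(x, ...) {
  cat(sprintf("TF screen vs %s over %d cells: %d TFs, %d positive (r > 0, p < 0.05)\n",
              attr(x, "target"), attr(x, "n_cells"), nrow(x),
              attr(x, "n_positive")))
  print.data.frame(utils::head(x, 5))
  invisible(x)
}
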
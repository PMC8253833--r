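# ---- cell-cycle scoring and classification ---------------------------------
# Relative expression E[i, j] = log2(FPKM[i, j] + 1) - mean_j log2(FPKM[i, ] + 1)
# centred across the cells passed in. A cell's G1/S and G2/M scores are the
# means of E over the two signature sets; cycling cells are separated either
# by 2-cluster hierarchical clustering in score space or by a plain score
# threshold.

#' Row-centred relative expression
#'
#' @param matrix A `ctc_expr` matrix (>= 2 cells).
#' @param genes Gene ids to include; genes absent from the matrix are
#'   dropped with a warning.
#' @return Numeric matrix of relative expression, rows summing to zero.
#' @export
relative_expression <- function(matrix, genes) {
  if (ncol(matrix) < 2) stop("relative_expression: need >= 2 cells")
  present <- intersect(genes, rownames(matrix))
  if (length(present) == 0)
    stop("relative_expression: none of the listed genes are in the matrix")
  if (length(present) < length(genes))
    warning(sprintf("relative_expression: %d listed gene(s) not in matrix; dropped",
                    length(genes) - length(present)))
  lg <- log2(unclass(matrix)[present, , drop = FALSE] + 1)
  lg - rowMeans(lg)
}

#' G1/S and G2/M cycle scores per cell
#'
#' Averages the relative expression of each signature set for every cell.
#' The centring population is exactly the cell set of `matrix`; pass a
#' subset to centre within it.
#'
#' @param matrix A `ctc_expr` matrix.
#' @param g1s_set,g2m_set Character vectors of signature gene ids.
#' @param cells Optional metadata to attach sites to the scores.
#' @return A `ctc_cycle_scores` data.frame: cell_id, g1s_score, g2m_score,
#'   site (NA when no metadata), cycling (NA until classified).
#' @export
cycle_scores <- function(matrix, g1s_set, g2m_set, cells = NULL) {
  e1 <- relative_expression(matrix, g1s_set)
  e2 <- relative_expression(matrix, g2m_set)
  out <- data.frame(cell_id = colnames(matrix),
                    g1s_score = colMeans(e1),
                    g2m_score = colMeans(e2),
                    site = NA_character_,
                    cycling = NA,
                    stringsAsFactors = FALSE)
  if (!is.null(cells))
    out$site <- cells$site[match(out$cell_id, cells$cell_id)]
  rownames(out) <- NULL
  class(out) <- c("ctc_cycle_scores", "data.frame")
  out
}

#' Classify cells as cycling or noncycling
#'
#' `method = "hclust2"`: hierarchical clustering (Euclidean, Ward) of cells
#' in the 2-D (g1s, g2m) score space, cut at two clusters; the cluster with
#' the larger mean of `max(g1s, g2m)` is called cycling. `method =
#' "threshold"`: cycling iff `max(g1s, g2m) >= threshold`.
#'
#' @param scores A `ctc_cycle_scores` data.frame.
#' @param method `"hclust2"` or `"threshold"`.
#' @param threshold Score threshold for the threshold method (log2 units).
#' @return The scores with the `cycling` flag set.
#' @export
classify_cycling <- function(scores, method = c("hclust2", "threshold"),
                             threshold = 1.0) {
  method <- match.arg(method)
  if (method == "threshold") {
    scores$cycling <- pmax(scores$g1s_score, scores$g2m_score) >= threshold
    return(scores)
  }
  if (nrow(scores) < 2) stop("classify_cycling: hclust2 needs >= 2 cells")
  m <- as.matrix(scores[, c("g1s_score", "g2m_score")])
  if (all(stats::dist(m) == 0)) {
    warning("classify_cycling: all cells identical in score space; all noncycling")
    scores$cycling <- FALSE
    return(scores)
  }
  hc <- stats::hclust(stats::dist(m), method = "ward.D2")
  cl <- stats::cutree(hc, k = 2)
  peak <- pmax(scores$g1s_score, scores$g2m_score)
  cyc_cluster <- which.max(c(mean(peak[cl == 1]), mean(peak[cl == 2])))
  scores$cycling <- cl == cyc_cluster
  scores
}

#' Per-site cycling proportions
#'
#' @param scores Classified `ctc_cycle_scores`.
#' @param digits Decimals for the reported percentage (default 1).
#' @return data.frame with site, n, n_cycling and percent cycling.
#' @export
cycling_proportions <- function(scores, digits = 1) {
  scores <- scores[!is.na(scores$site) & scores$site != "NA", , drop = FALSE]
  sites <- unique(scores$site)
  data.frame(site = sites,
             n = vapply(sites, function(s) sum(scores$site == s), numeric(1)),
             n_cycling = vapply(sites, function(s)
               sum(scores$cycling[scores$site == s]), numeric(1)),
             percent = vapply(sites, function(s)
               round(100 * mean(scores$cycling[scores$site == s]), digits),
               numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
plot.ctc_cycle_scores <- function(x, ...) {
  col <- ifelse(is.na(x$cycling), "grey50",
                ifelse(x$cycling, "firebrick", "steelblue"))
  graphics::plot(x$g1s_score, x$g2m_score, col = col, pch = 19,
                 xlab = "G1/S score", ylab = "G2/M score", ...)
  invisible(x)
}
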
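# ---- hierarchical clustering convention ------------------------------------
# Euclidean distance on log2(x + 1), Ward linkage by default; the convention
# shared by the cycling classification and available standalone.

#' Hierarchical clustering of cells
#'
#' @param matrix A `ctc_expr` matrix.
#' @param cells Optional cell ids to cluster (default all columns).
#' @param genes Optional gene ids to cluster on (default all rows).
#' @param linkage `"ward"` (ward.D2), `"average"` or `"complete"`.
#' @return A `ctc_dendrogram` wrapping the `hclust` object.
#' @export
hcluster <- function(matrix, cells = NULL, genes = NULL,
                     linkage = c("ward", "average", "complete")) {
  linkage <- match.arg(linkage)
  if (!is.null(cells)) matrix <- matrix[, cells, drop = FALSE]
  if (!is.null(genes)) matrix <- matrix[genes, , drop = FALSE]
  if (ncol(matrix) < 2) stop("hcluster: need >= 2 cells")
  lg <- t(log2(unclass(matrix) + 1))
  method <- c(ward = "ward.D2", average = "average",
              complete = "complete")[[linkage]]
  hc <- stats::hclust(stats::dist(lg), method = method)
  structure(list(hclust = hc, linkage = linkage, distance = "euclidean_log2"),
            class = "ctc_dendrogram")
}

#' Cut a dendrogram into k clusters
#' @param dendrogram A `ctc_dendrogram`.
#' @param k Number of clusters.
#' @return Named integer vector of cluster labels per cell.
#' @export
cut_cells <- function(dendrogram, k) {
  stats::cutree(dendrogram$hclust, k = k)
}

#' Export a dendrogram as Newick
#' @param dendrogram A `ctc_dendrogram`.
#' @param path Output file.
#' @export
write_newick <- function(dendrogram, path) {
  ape::write.tree(ape::as.phylo(dendrogram$hclust), file = path)
  invisible(path)
}

#' @export
print.ctc_dendrogram <- function(x, ...) {
  cat(sprintf("Dendrogram: %d cells, %s linkage, %s distance\n",
              length(x$hclust$order), x$linkage, x$distance))
  invisible(x)
}

#' @export
plot.ctc_dendrogram <- function(x, ...) {
  graphics::plot(x$hclust, ...)
  invisible(x)
}
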
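# ---- quality control --------------------------------------------------------
# Boundary semantics are deliberate and literal: a cell fails when detected
# genes (FPKM > 0) < min_genes OR mapped reads <= min_reads; a gene passes the
# expressed filter only with value > min_fpkm in strictly more than
# min_cell_fraction of cells. Off-by-one conventions differ across tools, so
# they are pinned here and tested.

#' Cell-level QC filter
#'
#' A cell fails if its number of detected genes (recomputed from the matrix
#' as genes with expression > 0 when a matrix is supplied, which overrides
#' the metadata with a warning on discrepancy) is below `min_genes`, or its
#' mapped-read count is at or below `min_reads`.
#'
#' @param matrix Optional `ctc_expr` matrix covering all cells in `cells`.
#' @param cells Cell metadata `data.frame`.
#' @param min_genes Minimum detected genes (fail when `< min_genes`).
#' @param min_reads Read floor (fail when `<= min_reads`).
#' @return A `ctc_qc_report`: per-cell pass flags with failure reasons and
#'   attrition counts.
#' @export
filter_cells <- function(matrix = NULL, cells, min_genes = 3000,
                         min_reads = 1e6) {
  detected <- cells$detected_genes
  if (!is.null(matrix)) {
    missing <- setdiff(colnames(matrix), cells$cell_id)
    if (length(missing))
      stop("filter_cells: cells missing from metadata: ",
           paste(utils::head(missing, 5), collapse = ", "))
    recomputed <- colSums(unclass(matrix) > 0)[cells$cell_id]
    recomputed <- recomputed[!is.na(recomputed)]
    idx <- match(names(recomputed), cells$cell_id)
    mismatch <- which(detected[idx] != recomputed)
    if (length(mismatch))
      warning(sprintf(
        "filter_cells: detected_genes metadata disagrees with matrix for %d cell(s); matrix wins",
        length(mismatch)))
    detected[idx] <- recomputed
  }
  fail_genes <- detected < min_genes
  fail_reads <- cells$mapped_reads <= min_reads
  pass <- !(fail_genes | fail_reads)
  reason <- mapply(function(g, r) {
    paste(c(if (g) "genes" else NULL, if (r) "reads" else NULL),
          collapse = "+")
  }, fail_genes, fail_reads)
  report <- list(
    n_input = nrow(cells),
    n_pass = sum(pass),
    cells = data.frame(cell_id = cells$cell_id, pass = pass,
                       detected_genes = detected,
                       mapped_reads = cells$mapped_reads,
                       reason = reason, stringsAsFactors = FALSE),
    min_genes = min_genes, min_reads = min_reads)
  class(report) <- "ctc_qc_report"
  report
}

#' @export
print.ctc_qc_report <- function(x, ...) {
  cat(sprintf("QC: %d/%d cells pass (min genes %d, reads floor %g)\n",
              x$n_pass, x$n_input, x$min_genes, x$min_reads))
  if (x$n_pass < x$n_input) {
    tab <- table(x$cells$reason[!x$cells$pass])
    for (r in names(tab)) cat(sprintf("  failed [%s]: %d\n", r, tab[[r]]))
  }
  invisible(x)
}

#' Cells passing a QC report
#' @param report A `ctc_qc_report`.
#' @return Character vector of passing cell ids.
#' @export
qc_passing_cells <- function(report) {
  report$cells$cell_id[report$cells$pass]
}

#' Expressed-gene filter
#'
#' Keeps a gene only if its expression exceeds `min_fpkm` in strictly more
#' than `min_cell_fraction` of the analysed cells.
#'
#' @param matrix A `ctc_expr` matrix in FPKM.
#' @param min_fpkm Expression threshold (strict `>`).
#' @param min_cell_fraction Cell-fraction threshold (strict `>`).
#' @param cell_subset Optional cell ids to restrict to (e.g. CTCs).
#' @return Named logical vector over genes (`TRUE` = keep).
#' @export
filter_genes_expressed <- function(matrix, min_fpkm = 1,
                                   min_cell_fraction = 0.10,
                                   cell_subset = NULL) {
  require_unit(matrix, "FPKM")
  if (!is.null(cell_subset)) {
    if (length(cell_subset) == 0) stop("filter_genes_expressed: empty subset")
    matrix <- matrix[, cell_subset, drop = FALSE]
  }
  if (ncol(matrix) == 0) stop("filter_genes_expressed: no cells to filter on")
  frac <- rowMeans(unclass(matrix) > min_fpkm)
  stats::setNames(frac > min_cell_fraction, rownames(matrix))
}
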
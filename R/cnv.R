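# ---- expression-based CNV inference ----------------------------------------
# Smoothed relative-expression tracks against diploid reference cells:
#   1. retain genes with mean FPKM across all cells >= mean_cutoff
#   2. per gene, signal = log2(x + 1) minus the reference-cell mean
#   3. centred moving average (window genes) along genome order, truncated at
#      chromosome edges; chromosomes with < 3 retained genes are dropped
#   4. per-cell median re-centring (library-size guard)
#   5. sigmoidal denoising: each value v is shrunk by the logistic weight
#      w = 1 / (1 + exp(-s * (|v| / sd_ref - midpoint))) so that values near
#      the reference noise floor are attenuated more than distant ones

# truncated centred moving average of a vector
moving_average <- function(x, window) {
  n <- length(x)
  half <- window %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Infer copy-number profiles from expression
#'
#' @param matrix A `ctc_expr` matrix in FPKM (all cells, including the
#'   reference cells).
#' @param loci Locus table from [read_loci()] (or the generator); genes
#'   without a locus are dropped with a warning.
#' @param reference_cells Cell ids of the diploid reference population.
#' @param window Moving-average window in genes (odd; default 201).
#' @param mean_cutoff Minimum mean FPKM across all cells for a gene to be
#'   retained (default 1).
#' @param sd_amplifier_midpoint Midpoint of the logistic denoising curve in
#'   units of the reference-signal SD (default 2).
#' @param steepness Logistic steepness (default 4).
#' @param denoise Apply the sigmoidal denoising step (default TRUE).
#' @return A `ctc_cnv` object: `signal` (genes x cells smoothed matrix,
#'   genome order), `loci` (retained, ordered), `reference_cells`, `sd_ref`.
#' @export
infer_cnv <- function(matrix, loci, reference_cells, window = 201,
                      mean_cutoff = 1, sd_amplifier_midpoint = 2,
                      steepness = 4, denoise = TRUE) {
  require_unit(matrix, "FPKM")
  if (length(reference_cells) < 1) stop("infer_cnv: no reference cells")
  if (!all(reference_cells %in% colnames(matrix)))
    stop("infer_cnv: reference cells missing from matrix")
  if (window %% 2 == 0) stop("infer_cnv: window must be odd")

  uncovered <- setdiff(rownames(matrix), loci$gene_id)
  if (length(uncovered))
    warning(sprintf("infer_cnv: %d gene(s) without locus dropped",
                    length(uncovered)))
  loci <- loci[loci$gene_id %in% rownames(matrix), , drop = FALSE]
  loci <- sort_loci(loci)

  x <- unclass(matrix)[loci$gene_id, , drop = FALSE]
  keep <- rowMeans(x) >= mean_cutoff
  loci <- loci[keep, , drop = FALSE]
  x <- x[keep, , drop = FALSE]

  # drop sparse chromosomes
  tab <- table(loci$chrom)
  small <- names(tab)[tab < 3]
  if (length(small)) {
    warning("infer_cnv: dropping chromosome(s) with < 3 genes: ",
            paste(small, collapse = ", "))
    ok <- !(loci$chrom %in% small)
    loci <- loci[ok, , drop = FALSE]
    x <- x[ok, , drop = FALSE]
  }
  if (nrow(x) == 0) stop("infer_cnv: no genes retained")
  loci <- sort_loci(loci)
  x <- x[loci$gene_id, , drop = FALSE]

  lg <- log2(x + 1)
  signal <- lg - rowMeans(lg[, reference_cells, drop = FALSE])

  smooth <- signal
  for (ch in unique(loci$chrom)) {
    rows <- which(loci$chrom == ch)
    smooth[rows, ] <- apply(signal[rows, , drop = FALSE], 2,
                            moving_average, window = window)
  }

  # per-cell median re-centring
  smooth <- sweep(smooth, 2, apply(smooth, 2, stats::median))

  sd_ref <- stats::sd(as.vector(smooth[, reference_cells, drop = FALSE]))
  if (denoise && sd_ref > 0) {
    w <- 1 / (1 + exp(-steepness *
                        (abs(smooth) / sd_ref - sd_amplifier_midpoint)))
    smooth <- smooth * w
  }

  out <- list(signal = smooth, loci = loci,
              reference_cells = reference_cells,
              window = window, mean_cutoff = mean_cutoff,
              sd_amplifier_midpoint = sd_amplifier_midpoint,
              steepness = steepness, sd_ref = sd_ref, denoised = denoise)
  class(out) <- "ctc_cnv"
  out
}

#' @export
print.ctc_cnv <- function(x, ...) {
  cat(sprintf(
    "CNV profiles: %d genes x %d cells (window %d, cutoff %g, midpoint %g%s)\n",
    nrow(x$signal), ncol(x$signal), x$window, x$mean_cutoff,
    x$sd_amplifier_midpoint, if (x$denoised) ", denoised" else ""))
  invisible(x)
}

#' Mean CNV signal over a gene span
#'
#' @param cnv A `ctc_cnv` object.
#' @param gene_ids Genes defining the segment.
#' @param cells Optional cell ids (default: all non-reference cells).
#' @return Mean smoothed signal (log2 units) over the span and cells.
#' @export
segment_signal <- function(cnv, gene_ids, cells = NULL) {
  if (is.null(cells))
    cells <- setdiff(colnames(cnv$signal), cnv$reference_cells)
  rows <- intersect(gene_ids, rownames(cnv$signal))
  if (length(rows) == 0) stop("segment_signal: no segment genes retained")
  mean(cnv$signal[rows, cells, drop = FALSE])
}
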
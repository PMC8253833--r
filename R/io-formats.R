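# ---- shared data model and on-disk formats ---------------------------------
# The expression container is a plain numeric matrix (genes x cells) carrying
# a unit tag ("FPKM" or "CPM"); cell metadata is a data.frame. Coordinates in
# locus tables are 0-based half-open (BED convention).

VALID_SITES <- c("HV", "PA", "PV", "PoV", "NA")
VALID_CLASSES <- c("CTC", "WBC", "cell_line", "tumor_bulk", "peritumor_bulk")

#' Construct a tagged expression matrix
#'
#' @param values Non-negative numeric matrix, genes in rows, cells in columns.
#' @param gene_ids,cell_ids Unique identifiers; default to dimnames.
#' @param unit Expression unit, `"FPKM"` or `"CPM"`.
#' @return A numeric matrix of class `ctc_expr` with a `unit` attribute.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values),
                              unit = c("FPKM", "CPM")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("expression_matrix: gene and cell ids are required")
  if (anyDuplicated(gene_ids))
    stop("expression_matrix: duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(cell_ids))
    stop("expression_matrix: duplicate cell ids: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  if (any(values < 0)) stop("expression_matrix: negative expression values")
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(values, unit = unit, class = c("ctc_expr", "matrix", "array"))
}

#' @export
print.ctc_expr <- function(x, ...) {
  cat(sprintf("Expression matrix [%s]: %d genes x %d cells\n",
              attr(x, "unit"), nrow(x), ncol(x)))
  invisible(x)
}

expr_unit <- function(x) attr(x, "unit")

require_unit <- function(x, unit) {
  if (!identical(expr_unit(x), unit))
    stop(sprintf("expected %s values but matrix is tagged %s",
                 unit, expr_unit(x)))
  invisible(x)
}

# subsetting keeps the unit tag and class when the result is still a matrix
#' @export
`[.ctc_expr` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, unit = attr(x, "unit"),
                     class = c("ctc_expr", "matrix", "array"))
  out
}

#' Construct a cell metadata table
#'
#' @param cell_id,patient_id Character vectors.
#' @param site Vascular site, one of `HV`, `PA`, `PV`, `PoV`, `NA`.
#' @param cell_class One of `CTC`, `WBC`, `cell_line`, `tumor_bulk`,
#'   `peritumor_bulk`.
#' @param mapped_reads,detected_genes Non-negative counts.
#' @return A `data.frame` with one row per cell.
#' @export
cell_records <- function(cell_id, patient_id, site, cell_class,
                         mapped_reads, detected_genes) {
  site <- as.character(site)
  if (!all(site %in% VALID_SITES))
    stop("cell_records: invalid site: ",
         paste(setdiff(site, VALID_SITES), collapse = ", "))
  if (!all(cell_class %in% VALID_CLASSES))
    stop("cell_records: invalid cell class")
  if (any(mapped_reads < 0) || any(detected_genes < 0))
    stop("cell_records: counts must be non-negative")
  if (anyDuplicated(cell_id)) stop("cell_records: duplicate cell ids")
  data.frame(cell_id = as.character(cell_id),
             patient_id = as.character(patient_id),
             site = site, cell_class = cell_class,
             mapped_reads = as.numeric(mapped_reads),
             detected_genes = as.integer(detected_genes),
             stringsAsFactors = FALSE)
}

#' Align cell metadata to an expression matrix
#'
#' Joins by `cell_id`. Mismatch is a hard error by default; with
#' `on_mismatch = "intersect"` the common cells are used with a warning.
#'
#' @param matrix A `ctc_expr` matrix.
#' @param cells A cell metadata `data.frame`.
#' @param on_mismatch `"error"` (default) or `"intersect"`.
#' @return List with the (possibly subset) matrix and metadata, row-aligned
#'   to the matrix columns.
#' @export
align_cells <- function(matrix, cells, on_mismatch = c("error", "intersect")) {
  on_mismatch <- match.arg(on_mismatch)
  mc <- colnames(matrix)
  missing_meta <- setdiff(mc, cells$cell_id)
  extra_meta <- setdiff(cells$cell_id, mc)
  if (length(missing_meta) || length(extra_meta)) {
    if (on_mismatch == "error")
      stop("cell id mismatch between matrix and metadata (",
           length(missing_meta), " without metadata, ",
           length(extra_meta), " without expression)")
    common <- intersect(mc, cells$cell_id)
    warning(sprintf("intersecting to %d common cells", length(common)))
    matrix <- matrix[, common, drop = FALSE]
    mc <- common
  }
  cells <- cells[match(mc, cells$cell_id), , drop = FALSE]
  rownames(cells) <- NULL
  list(matrix = matrix, cells = cells)
}

#' Read an expression matrix
#'
#' TSV dialect: genes in rows, first column the gene id, header row of cell
#' ids. MatrixMarket triplet (`format = "mtx_triplet"`) expects sidecar files
#' `<path>.genes.txt` and `<path>.cells.txt` with one id per line. Gzipped
#' files are read transparently.
#'
#' @param path File path.
#' @param format `"tsv"` or `"mtx_triplet"`.
#' @param unit Unit tag to attach (`"FPKM"` or `"CPM"`).
#' @return A `ctc_expr` matrix.
#' @export
read_expression <- function(path, format = c("tsv", "mtx_triplet"),
                            unit = "FPKM") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_expression: no such file: ", path)
  if (format == "tsv") {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    gene_ids <- as.character(tab[[1]])
    if (anyDuplicated(gene_ids))
      stop("read_expression: duplicate gene id(s): ",
           paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
    vals <- as.matrix(tab[, -1, drop = FALSE])
    if (any(is.na(vals))) stop("read_expression: non-numeric or missing value")
    expression_matrix(vals, gene_ids, colnames(tab)[-1], unit = unit)
  } else {
    m <- as.matrix(Matrix::readMM(path))
    gene_ids <- readLines(paste0(path, ".genes.txt"))
    cell_ids <- readLines(paste0(path, ".cells.txt"))
    if (nrow(m) != length(gene_ids) || ncol(m) != length(cell_ids))
      stop("read_expression: sidecar id lengths do not match matrix")
    expression_matrix(m, gene_ids, cell_ids, unit = unit)
  }
}

#' Write an expression matrix as TSV
#'
#' @param matrix A `ctc_expr` matrix.
#' @param path Output path (`.gz` suffix writes gzipped).
#' @export
write_expression <- function(matrix, path) {
  tab <- data.frame(gene_id = rownames(matrix),
                    as.data.frame(unclass(matrix)[, , drop = FALSE]),
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(tab) <- c("gene_id", colnames(matrix))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then members, tab-separated.
#' Duplicate members within a line are removed with a warning.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of class `ctc_gene_sets`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("read_gmt: no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("read_gmt: line %d has fewer than 3 fields", i))
    members <- fields[-(1:2)]
    if (anyDuplicated(members)) {
      warning(sprintf("read_gmt: set '%s': %d duplicate member(s) removed",
                      fields[1], sum(duplicated(members))))
      members <- unique(members)
    }
    sets[[fields[1]]] <- members
  }
  structure(sets, class = "ctc_gene_sets")
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene loci from a BED-like file
#'
#' Columns: chromosome, start, end, gene_id (tab-separated, no header).
#' Coordinates are 0-based half-open. The result is sorted by
#' (chromosome, start) and gets an `order_index` column `0..n-1`.
#'
#' @param path BED file path.
#' @return A `data.frame` with columns chrom, start, end, gene_id,
#'   order_index.
#' @export
read_loci <- function(path) {
  if (!file.exists(path)) stop("read_loci: no such file: ", path)
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("read_loci: expected 4 columns (chrom start end gene)")
  names(tab)[1:4] <- c("chrom", "start", "end", "gene_id")
  bad <- which(tab$start >= tab$end)
  if (length(bad))
    stop("read_loci: start >= end at line(s) ", paste(bad, collapse = ", "))
  sort_loci(tab[, 1:4])
}

sort_loci <- function(tab) {
  tab <- tab[order(tab$chrom, tab$start), , drop = FALSE]
  tab$order_index <- seq_len(nrow(tab)) - 1L
  rownames(tab) <- NULL
  tab
}

#' Write gene loci as BED
#' @param loci Locus `data.frame` (chrom, start, end, gene_id).
#' @param path Output path.
#' @export
write_loci <- function(loci, path) {
  utils::write.table(loci[, c("chrom", "start", "end", "gene_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read cell metadata from CSV
#' @param path CSV with columns cell_id, patient_id, site, cell_class,
#'   mapped_reads, detected_genes.
#' @return A validated metadata `data.frame`.
#' @export
read_cell_metadata <- function(path) {
  if (!file.exists(path)) stop("read_cell_metadata: no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("cell_id", "patient_id", "site", "cell_class",
              "mapped_reads", "detected_genes")
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    stop("read_cell_metadata: missing column(s): ",
         paste(missing, collapse = ", "))
  # the "no site" level is the literal string "NA"; CSV readers turn it into
  # a missing value
  tab$site[is.na(tab$site)] <- "NA"
  cell_records(tab$cell_id, tab$patient_id, tab$site, tab$cell_class,
               tab$mapped_reads, tab$detected_genes)
}

#' Write cell metadata as CSV
#' @param cells Metadata `data.frame`.
#' @param path Output path.
#' @export
write_cell_metadata <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
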
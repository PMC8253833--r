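# ---- synthetic cohorts with ground truth -----------------------------------
# Cohorts mimic a multi-patient, four-vascular-site CTC study: lognormal base
# expression, site-specific expression programs whose per-cell activation
# controls cell-to-cell heterogeneity, a cycling subpopulation with boosted
# G1/S or G2/M signatures, spiked DE genes, contiguous CNV segments scaling
# tumor-cell expression against diploid reference cells, and a TF whose
# log-expression tracks a target chemokine at a requested Pearson r.

#' Specification of a synthetic CTC cohort
#'
#' Defaults mirror the cohort structure of a four-site hepatocellular CTC
#' study: 45/12/40/16 CTCs in hepatic vein (HV), peripheral artery (PA),
#' peripheral vein (PV) and portal vein (PoV), with a handful of white-blood
#' cell (WBC) reference cells; high cell-to-cell dispersion in HV/PV/PoV and
#' markedly lower dispersion in PA; site cycling fractions near the reported
#' per-site proportions.
#'
#' @param n_genes Total genes (>= 1500 with the default layout).
#' @param site_cells Named integer vector of CTC counts per site.
#' @param n_reference_cells Diploid reference (WBC) cells.
#' @param n_patients Patients; site cells are assigned round-robin.
#' @param site_program_size Genes per site-specific program.
#' @param site_program_effect Mean program activation (log2 units).
#' @param site_dispersion Named per-site SD of per-cell program activation
#'   (log2 units); larger means more cell-to-cell heterogeneity.
#' @param cycling_fraction Scalar or named per-site fraction of cycling CTCs.
#' @param cycle_effect Log2 boost applied to the phase signature of a
#'   cycling cell.
#' @param cycle_cross_leak Fraction of `cycle_effect` applied to the other
#'   cycle signature of a cycling cell (default 0.5): replication and
#'   mitosis programs co-express in cycling cells, so their scores rise
#'   together rather than along orthogonal axes.
#' @param n_g1s,n_g2m Sizes of the G1/S and G2/M signature sets.
#' @param n_de_genes Spiked differentially expressed genes.
#' @param de_log2fc True log2 fold change of spiked genes.
#' @param de_up_site Site whose cells carry the DE up-shift.
#' @param cnv_segments List of segments, each
#'   `list(chrom =, from =, to =, copy_ratio =)` with `from:to` 1-based gene
#'   positions within the chromosome's genome order.
#' @param tf_target_r Target Pearson correlation between the planted TF and
#'   its target gene (log2 scale, CTC cells, pre-dropout).
#' @param n_null_tfs Uncoupled TFs included in the screen list.
#' @param dropout_rate Probability that any expression entry is zeroed.
#'   Default 0 (see the methods vignette for why the expression-independent
#'   dropout model is off by default).
#' @param base_log2_mean,base_log2_sd Gene-level mean layer of the lognormal
#'   base expression (log2 FPKM units).
#' @param noise_sd Cell-level lognormal noise SD (log2 units).
#' @param tf_log2_mean,tf_log2_sd Location/scale of the TF/target pair.
#' @param n_chromosomes Chromosomes the genome is split into (equal blocks).
#' @param seed Mandatory integer seed.
#' @return A `ctc_synth_spec` list.
#' @export
synthetic_spec <- function(n_genes = 3000,
                           site_cells = c(HV = 45, PA = 12, PV = 40, PoV = 16),
                           n_reference_cells = 8,
                           n_patients = 1,
                           site_program_size = 100,
                           site_program_effect = 2,
                           site_dispersion = c(HV = 1, PA = 0.2,
                                               PV = 1, PoV = 1),
                           cycling_fraction = c(HV = 0.40, PA = 0.083,
                                                PV = 0.35, PoV = 0.563),
                           cycle_effect = 2,
                           cycle_cross_leak = 0.5,
                           n_g1s = 42, n_g2m = 54,
                           n_de_genes = 0,
                           de_log2fc = 2,
                           de_up_site = "HV",
                           cnv_segments = list(list(chrom = "chr1",
                                                    from = 201, to = 500,
                                                    copy_ratio = 2)),
                           tf_target_r = 0.86,
                           n_null_tfs = 42,
                           dropout_rate = 0,
                           base_log2_mean = 4, base_log2_sd = 1.5,
                           noise_sd = 0.5,
                           tf_log2_mean = 5, tf_log2_sd = 1,
                           n_chromosomes = 2,
                           seed) {
  if (missing(seed)) stop("synthetic_spec: seed is mandatory")
  sites <- names(site_cells)
  if (is.null(sites) || !all(sites %in% c("HV", "PA", "PV", "PoV")))
    stop("synthetic_spec: site_cells must be named with HV/PA/PV/PoV")
  if (length(cycling_fraction) == 1)
    cycling_fraction <- stats::setNames(rep(cycling_fraction, length(sites)),
                                        sites)
  if (length(site_dispersion) == 1)
    site_dispersion <- stats::setNames(rep(site_dispersion, length(sites)),
                                       sites)
  stopifnot(all(cycling_fraction >= 0), all(cycling_fraction <= 1),
            all(site_dispersion >= 0), dropout_rate >= 0, dropout_rate <= 1,
            all(vapply(cnv_segments, function(s) s$copy_ratio > 0, logical(1))))
  spec <- list(n_genes = n_genes, site_cells = site_cells,
               n_reference_cells = n_reference_cells,
               n_patients = n_patients,
               site_program_size = site_program_size,
               site_program_effect = site_program_effect,
               site_dispersion = site_dispersion[sites],
               cycling_fraction = cycling_fraction[sites],
               cycle_effect = cycle_effect,
               cycle_cross_leak = cycle_cross_leak,
               n_g1s = n_g1s, n_g2m = n_g2m,
               n_de_genes = n_de_genes, de_log2fc = de_log2fc,
               de_up_site = de_up_site, cnv_segments = cnv_segments,
               tf_target_r = tf_target_r, n_null_tfs = n_null_tfs,
               dropout_rate = dropout_rate,
               base_log2_mean = base_log2_mean, base_log2_sd = base_log2_sd,
               noise_sd = noise_sd,
               tf_log2_mean = tf_log2_mean, tf_log2_sd = tf_log2_sd,
               n_chromosomes = n_chromosomes, seed = as.integer(seed))
  class(spec) <- "ctc_synth_spec"
  spec
}

# deterministic gene-role layout over gene indices 1..n_genes; roles are
# disjoint by construction so planted truths never overlap
synth_layout <- function(spec) {
  sites <- names(spec$site_cells)
  need <- spec$n_g1s + spec$n_g2m +
    length(sites) * spec$site_program_size + spec$n_de_genes +
    2 + spec$n_null_tfs
  # keep the default CNV span clear of role blocks by putting roles after it
  cnv_hi <- max(0, vapply(spec$cnv_segments,
                          function(s) s$to, numeric(1)))
  offset <- max(cnv_hi, 0)
  if (offset + need > spec$n_genes)
    stop("synthetic_spec: n_genes too small for the requested layout (need > ",
         offset + need, ")")
  cursor <- offset
  take <- function(k) {
    idx <- cursor + seq_len(k)
    cursor <<- cursor + k
    idx
  }
  programs <- list()
  g1s <- take(spec$n_g1s)
  g2m <- take(spec$n_g2m)
  for (s in sites) programs[[s]] <- take(spec$site_program_size)
  de <- take(spec$n_de_genes)
  tf <- take(1)
  target <- take(1)
  null_tfs <- take(spec$n_null_tfs)
  list(g1s = g1s, g2m = g2m, programs = programs, de = de,
       tf = tf, target = target, null_tfs = null_tfs)
}

synth_gene_ids <- function(n) sprintf("g%05d", seq_len(n))

# equal contiguous chromosome blocks; 0-based half-open positions
synth_loci <- function(n_genes, n_chromosomes, gene_ids) {
  sizes <- rep(n_genes %/% n_chromosomes, n_chromosomes)
  sizes[seq_len(n_genes %% n_chromosomes)] <-
    sizes[seq_len(n_genes %% n_chromosomes)] + 1
  chrom <- rep(sprintf("chr%d", seq_len(n_chromosomes)), sizes)
  within <- unlist(lapply(sizes, seq_len)) - 1L
  loci <- data.frame(chrom = chrom, start = within * 1000L,
                     end = within * 1000L + 500L, gene_id = gene_ids,
                     stringsAsFactors = FALSE)
  sort_loci(loci)
}

#' Generate a synthetic CTC cohort with full ground truth
#'
#' Deterministic given `spec$seed`. A hierarchical seed stream gives each
#' generative component (base expression, site programs, cycling, DE, TF
#' pair, dropout, metadata) its own substream, so enabling one component
#' never perturbs the others.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `matrix` (`ctc_expr`, FPKM), `cells` (metadata
#'   `data.frame`), `loci`, `sets` (`ctc_gene_sets`: cycle signatures and
#'   site programs), and `truth` (planted labels and effect sizes).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "ctc_synth_spec"))
  layout <- synth_layout(spec)
  sites <- names(spec$site_cells)
  gene_ids <- synth_gene_ids(spec$n_genes)

  set.seed(spec$seed)
  sub <- sample.int(.Machine$integer.max - 1L, 8)

  # cells: CTCs per site (round-robin patients), then reference WBCs
  patient <- character(0); site <- character(0)
  for (s in sites) {
    n <- spec$site_cells[[s]]
    patient <- c(patient, sprintf("P%d", ((seq_len(n) - 1) %% spec$n_patients) + 1))
    site <- c(site, rep(s, n))
  }
  n_ctc <- length(site)
  cell_id <- sprintf("%s_%s_c%03d", patient, site, seq_len(n_ctc))
  wbc_id <- sprintf("WBC_c%03d", seq_len(spec$n_reference_cells))
  all_ids <- c(cell_id, wbc_id)
  n_cells <- length(all_ids)
  is_ctc <- c(rep(TRUE, n_ctc), rep(FALSE, spec$n_reference_cells))

  # base lognormal expression in log2 space
  set.seed(sub[1])
  mu_g <- stats::rnorm(spec$n_genes, spec$base_log2_mean, spec$base_log2_sd)
  L <- matrix(stats::rnorm(spec$n_genes * n_cells, 0, spec$noise_sd),
              spec$n_genes, n_cells) + mu_g

  # site programs: per-cell activation ~ N(effect, sigma_site)
  set.seed(sub[2])
  activation <- numeric(n_ctc)
  for (s in sites) {
    cols <- which(site == s)
    act <- stats::rnorm(length(cols), spec$site_program_effect,
                        spec$site_dispersion[[s]])
    activation[cols] <- act
    L[layout$programs[[s]], cols] <-
      L[layout$programs[[s]], cols] + rep(act, each = spec$site_program_size)
  }

  # cycling subpopulation: boost one of the two signatures
  set.seed(sub[3])
  cycling <- rep(FALSE, n_cells); phase <- rep(NA_character_, n_cells)
  for (s in sites) {
    cols <- which(site == s)
    cyc <- stats::runif(length(cols)) < spec$cycling_fraction[[s]]
    ph <- ifelse(stats::runif(length(cols)) < 0.5, "G1S", "G2M")
    cycling[cols] <- cyc
    phase[cols][cyc] <- ph[cyc]
    for (j in cols[cyc]) {
      main <- if (phase[j] == "G1S") layout$g1s else layout$g2m
      other <- if (phase[j] == "G1S") layout$g2m else layout$g1s
      L[main, j] <- L[main, j] + spec$cycle_effect
      L[other, j] <- L[other, j] + spec$cycle_cross_leak * spec$cycle_effect
    }
  }

  # spiked DE genes, up in de_up_site
  if (spec$n_de_genes > 0) {
    up_cols <- which(site == spec$de_up_site)
    L[layout$de, up_cols] <- L[layout$de, up_cols] + spec$de_log2fc
  }

  # TF/target pair: exact empirical Pearson r over CTC cells (log2 scale)
  set.seed(sub[4])
  z1 <- as.numeric(scale(stats::rnorm(n_ctc)))
  z2 <- stats::rnorm(n_ctc)
  z2 <- as.numeric(scale(stats::residuals(stats::lm(z2 ~ z1))))
  r <- spec$tf_target_r
  y <- r * z1 + sqrt(1 - r^2) * z2
  L[layout$tf, is_ctc] <- spec$tf_log2_mean + spec$tf_log2_sd * z1
  L[layout$target, is_ctc] <- spec$tf_log2_mean + spec$tf_log2_sd * y
  L[layout$tf, !is_ctc] <- spec$tf_log2_mean +
    spec$tf_log2_sd * stats::rnorm(sum(!is_ctc))
  L[layout$target, !is_ctc] <- spec$tf_log2_mean +
    spec$tf_log2_sd * stats::rnorm(sum(!is_ctc))

  fpkm <- 2^L

  # CNV segments scale tumor-cell expression; reference cells stay diploid
  loci <- synth_loci(spec$n_genes, spec$n_chromosomes, gene_ids)
  cnv_truth <- list()
  for (seg in spec$cnv_segments) {
    on_chr <- loci$gene_id[loci$chrom == seg$chrom]
    if (seg$to > length(on_chr))
      stop("generate_cohort: CNV segment extends past chromosome ", seg$chrom)
    seg_genes <- on_chr[seg$from:seg$to]
    rows <- match(seg_genes, gene_ids)
    fpkm[rows, is_ctc] <- fpkm[rows, is_ctc] * seg$copy_ratio
    cnv_truth[[length(cnv_truth) + 1]] <-
      list(chrom = seg$chrom, gene_ids = seg_genes,
           copy_ratio = seg$copy_ratio)
  }

  # dropout
  set.seed(sub[5])
  if (spec$dropout_rate > 0) {
    drop <- matrix(stats::runif(length(fpkm)) < spec$dropout_rate,
                   nrow(fpkm), ncol(fpkm))
    fpkm[drop] <- 0
  }

  # metadata consistent with the matrix
  set.seed(sub[6])
  detected <- colSums(fpkm > 0)
  reads <- round(stats::runif(n_cells, 1.5e6, 6e6))
  cells <- cell_records(all_ids,
                        patient_id = c(patient, rep("P1", sum(!is_ctc))),
                        site = c(site, rep("NA", sum(!is_ctc))),
                        cell_class = ifelse(is_ctc, "CTC", "WBC"),
                        mapped_reads = reads, detected_genes = detected)

  mat <- expression_matrix(fpkm, gene_ids, all_ids, unit = "FPKM")

  sets <- c(list(G1S = gene_ids[layout$g1s], G2M = gene_ids[layout$g2m]),
            stats::setNames(lapply(sites, function(s)
              gene_ids[layout$programs[[s]]]),
              sprintf("PROGRAM_%s", sites)))
  class(sets) <- "ctc_gene_sets"

  truth <- list(
    cycling = stats::setNames(cycling, all_ids),
    phase = stats::setNames(phase, all_ids),
    site_program_genes = lapply(layout$programs, function(i) gene_ids[i]),
    program_activation = stats::setNames(activation, cell_id),
    de_genes = gene_ids[layout$de], de_log2fc = spec$de_log2fc,
    de_up_site = spec$de_up_site,
    cnv_segments = cnv_truth,
    tf_id = gene_ids[layout$tf], target_id = gene_ids[layout$target],
    null_tf_ids = gene_ids[layout$null_tfs],
    tf_target_r = spec$tf_target_r,
    site_dispersion = spec$site_dispersion,
    cycling_fraction = spec$cycling_fraction)

  list(matrix = mat, cells = cells, loci = loci, sets = sets, truth = truth)
}

#' Generate cell metadata that stresses the QC filters
#'
#' Exactly `round(n_cells * failing_fraction)` cells violate at least one QC
#' rule (too few detected genes, or mapped reads at or below the read
#' floor); failures alternate between the two modes.
#'
#' @param n_cells Number of cells.
#' @param failing_fraction Fraction in `[0, 1]` that must fail.
#' @param seed Integer seed.
#' @param min_genes,min_reads The QC thresholds being stressed.
#' @return Metadata `data.frame` with a hidden `qc_should_fail` attribute.
#' @export
generate_qc_stress <- function(n_cells, failing_fraction, seed,
                               min_genes = 3000, min_reads = 1e6) {
  stopifnot(failing_fraction >= 0, failing_fraction <= 1)
  set.seed(seed)
  n_fail <- round(n_cells * failing_fraction)
  fail <- rep(FALSE, n_cells)
  fail[seq_len(n_fail)] <- TRUE
  genes <- round(stats::runif(n_cells, min_genes + 200, min_genes + 5000))
  reads <- round(stats::runif(n_cells, min_reads * 1.5, min_reads * 5))
  mode <- rep(c("genes", "reads"), length.out = n_fail)
  for (i in seq_len(n_fail)) {
    if (mode[i] == "genes") {
      genes[i] <- round(stats::runif(1, 200, min_genes - 1))
    } else {
      reads[i] <- round(stats::runif(1, min_reads / 5, min_reads))
    }
  }
  perm <- sample.int(n_cells)
  cells <- cell_records(sprintf("stress_c%04d", seq_len(n_cells)),
                        patient_id = "P1", site = "PV", cell_class = "CTC",
                        mapped_reads = reads[perm],
                        detected_genes = genes[perm])
  attr(cells, "qc_should_fail") <- fail[perm]
  cells
}

#' Write a cohort bundle to disk
#'
#' Writes the matrix (TSV), metadata (CSV), loci (BED), gene sets (GMT) and
#' ground truth (JSON) under `dir`.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(matrix = file.path(dir, "expression.tsv"),
             cells = file.path(dir, "cells.csv"),
             loci = file.path(dir, "loci.bed"),
             sets = file.path(dir, "sets.gmt"),
             truth = file.path(dir, "truth.json"))
  write_expression(cohort$matrix, paths["matrix"])
  write_cell_metadata(cohort$cells, paths["cells"])
  write_loci(cohort$loci, paths["loci"])
  write_gmt(cohort$sets, paths["sets"])
  jsonlite::write_json(cohort$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  paths
}
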
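# ---- pipeline orchestration -------------------------------------------------
# One config (R list or JSON file) drives simulate -> qc -> heterogeneity /
# cycle / markers / enrichment / cnv / tf screen / clustering. Every run
# writes stage outputs plus a manifest (file, stage, md5) and a resolved-
# config snapshot; identical config + seed give byte-identical manifests.

default_config <- function() {
  list(seed = 1,
       simulate = list(),          # overrides for synthetic_spec()
       inputs = NULL,              # or list(matrix=, cells=, loci=, sets=, tf_list=, target=)
       qc = list(min_genes = 3000, min_reads = 1e6),
       het = list(top_k = 2000, test = "wilcoxon", pairing = "within_patient"),
       cycle = list(method = "hclust2", threshold = 1.0),
       markers = list(site_a = "HV", site_b = "PA"),
       cnv = list(window = 201, mean_cutoff = 1, sd_amplifier_midpoint = 2,
                  steepness = 4),
       cluster = list(linkage = "ward", k = 2))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

config_error <- function(msg) {
  stop(structure(class = c("ctcflow_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Run the full analysis pipeline
#'
#' With no `inputs` entry in the config the cohort is simulated from
#' `config$simulate` (see [synthetic_spec()]); otherwise the listed files
#' are loaded. All stage outputs, a `manifest.csv` of md5 checksums and a
#' resolved `config.json` are written under `outdir`. A missing input file
#' or invalid config aborts with a `ctcflow_config_error` before any output
#' is written.
#'
#' @param config Named list (merged over defaults) or path to a JSON config.
#' @param outdir Output directory.
#' @return Invisibly, a list with `status` (0), `manifest` (data.frame) and
#'   the per-stage result objects.
#' @export
run_pipeline <- function(config = list(), outdir) {
  if (is.character(config)) {
    if (!file.exists(config)) config_error(paste("no such config:", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- merge_config(default_config(), config)
  if (!is.numeric(cfg$seed)) config_error("config: seed must be numeric")

  # validate inputs up front: fail before writing anything
  if (!is.null(cfg$inputs)) {
    for (f in c("matrix", "cells", "loci", "sets")) {
      path <- cfg$inputs[[f]]
      if (is.null(path)) config_error(paste("config: inputs$", f, " missing"))
      if (!file.exists(path))
        config_error(paste("config: missing input file:", path))
    }
  }

  if (is.null(cfg$inputs)) {
    # JSON configs arrive with named lists where the generator wants named
    # numeric vectors; flatten scalar-valued lists (never cnv_segments)
    sim <- lapply(cfg$simulate, function(x) {
      if (is.list(x) && length(x) && !is.null(names(x)) &&
          all(vapply(x, function(e) is.numeric(e) && length(e) == 1,
                     logical(1))))
        unlist(x)
      else x
    })
    spec <- do.call(synthetic_spec,
                    c(sim[setdiff(names(sim), "seed")],
                      list(seed = cfg$seed)))
    cohort <- generate_cohort(spec)
    tf_list <- c(cohort$truth$tf_id, cohort$truth$null_tf_ids)
    target <- cohort$truth$target_id
  } else {
    cohort <- list(matrix = read_expression(cfg$inputs$matrix),
                   cells = read_cell_metadata(cfg$inputs$cells),
                   loci = read_loci(cfg$inputs$loci),
                   sets = read_gmt(cfg$inputs$sets),
                   truth = NULL)
    tf_list <- if (!is.null(cfg$inputs$tf_list))
      readLines(cfg$inputs$tf_list) else character(0)
    target <- cfg$inputs$target
  }

  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  paths <- character(0)
  emit <- function(name, writer) {
    path <- file.path(outdir, name)
    writer(path)
    paths[[name]] <<- path
  }

  # qc
  qc <- filter_cells(cohort$matrix, cohort$cells,
                     min_genes = cfg$qc$min_genes,
                     min_reads = cfg$qc$min_reads)
  results$qc <- qc
  passing <- qc_passing_cells(qc)
  emit("qc.csv", function(p) utils::write.csv(qc$cells, p, row.names = FALSE))
  emit("qc.json", function(p)
    jsonlite::write_json(list(n_input = qc$n_input, n_pass = qc$n_pass),
                         p, auto_unbox = TRUE))
  mat <- cohort$matrix[, passing, drop = FALSE]
  cells <- cohort$cells[cohort$cells$cell_id %in% passing, , drop = FALSE]
  ctc_ids <- cells$cell_id[cells$cell_class == "CTC"]
  ref_ids <- cells$cell_id[cells$cell_class == "WBC"]

  # heterogeneity
  hv_genes <- select_variable_genes(mat, k = cfg$het$top_k,
                                    cell_subset = ctc_ids)
  het <- site_heterogeneity(mat, cells, hv_genes,
                            pairing = cfg$het$pairing, test = cfg$het$test)
  results$het <- het
  emit("heterogeneity.csv", function(p) {
    long <- do.call(rbind, lapply(names(het$site_r), function(s)
      data.frame(site = s, r = het$site_r[[s]])))
    utils::write.csv(long, p, row.names = FALSE)
  })
  emit("heterogeneity.json", function(p)
    jsonlite::write_json(list(
      mean_r = as.list(het$mean_r),
      comparisons = lapply(het$comparisons, function(cc)
        lapply(cc, function(t) list(p = t$p_value, method = t$method)))),
      p, auto_unbox = TRUE, digits = NA))

  # cell cycle (CTCs only)
  sc <- cycle_scores(mat[, ctc_ids, drop = FALSE],
                     cohort$sets$G1S, cohort$sets$G2M, cells = cells)
  sc <- classify_cycling(sc, method = cfg$cycle$method,
                         threshold = cfg$cycle$threshold)
  results$cycle <- sc
  emit("cycle.csv", function(p) utils::write.csv(sc, p, row.names = FALSE))
  emit("cycle_summary.json", function(p)
    jsonlite::write_json(cycling_proportions(sc), p, auto_unbox = TRUE,
                         digits = NA))

  # markers between two sites
  ga <- cells$cell_id[cells$site == cfg$markers$site_a]
  gb <- cells$cell_id[cells$site == cfg$markers$site_b]
  markers <- NULL
  if (length(ga) >= 2 && length(gb) >= 2) {
    markers <- differential_test(mat, ga, gb,
                                 contrast = sprintf("%s_vs_%s",
                                                    cfg$markers$site_a,
                                                    cfg$markers$site_b))
    markers <- refine_upregulated(markers, mat)
    results$markers <- markers
    emit("markers.csv", function(p)
      utils::write.csv(markers, p, row.names = FALSE))
    finals <- stage_genes(markers, "initial")
    if (length(finals)) {
      enr <- enrich(finals, cohort$sets, universe = rownames(mat))
      results$enrich <- enr
      emit("enrichment.csv", function(p)
        utils::write.csv(enr, p, row.names = FALSE))
    }
  }

  # cnv
  if (length(ref_ids) >= 1) {
    cnv <- infer_cnv(mat, cohort$loci, ref_ids,
                     window = cfg$cnv$window,
                     mean_cutoff = cfg$cnv$mean_cutoff,
                     sd_amplifier_midpoint = cfg$cnv$sd_amplifier_midpoint,
                     steepness = cfg$cnv$steepness)
    results$cnv <- cnv
    emit("cnv_profiles.tsv", function(p)
      utils::write.table(round(cnv$signal, 6), p, sep = "\t", quote = FALSE))
  }

  # tf screen (CTCs)
  if (length(tf_list) && !is.null(target)) {
    screen <- screen_tfs(mat, tf_list, target, cells = ctc_ids)
    results$tfscreen <- screen
    emit("tfscreen.csv", function(p)
      utils::write.csv(screen, p, row.names = FALSE))
  }

  # clustering
  dend <- hcluster(mat, linkage = cfg$cluster$linkage)
  results$cluster <- dend
  emit("dendrogram.nwk", function(p) write_newick(dend, p))

  # resolved config snapshot (without machine-local paths) + manifest
  emit("config.json", function(p)
    jsonlite::write_json(cfg, p, auto_unbox = TRUE, digits = NA,
                         null = "null"))
  manifest <- data.frame(file = names(paths),
                         md5 = unname(tools::md5sum(unlist(paths))),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE)
  invisible(list(status = 0L, manifest = manifest, results = results))
}
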
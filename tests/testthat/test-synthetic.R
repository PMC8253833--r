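small_spec <- function(seed, ...) {
  synthetic_spec(n_genes = 1600, site_cells = c(HV = 10, PA = 8),
                 site_dispersion = c(HV = 1, PA = 0.2), seed = seed, ...)
}

test_that("identical spec and seed reproduce the cohort exactly", {
  a <- generate_cohort(small_spec(42))
  b <- generate_cohort(small_spec(42))
  expect_identical(unclass(a$matrix), unclass(b$matrix))
  expect_identical(a$cells, b$cells)
  expect_identical(a$truth, b$truth)
  d <- generate_cohort(small_spec(43))
  expect_false(identical(unclass(a$matrix), unclass(d$matrix)))
})

test_that("written cohort bundles are byte-stable given the seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_cohort(generate_cohort(small_spec(7)), d1)
  p2 <- write_cohort(generate_cohort(small_spec(7)), d2)
  for (f in names(p1))
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]),
                     label = paste("file", f))
})

test_that("spiked DE genes reach the requested fold change on average", {
  co <- generate_cohort(synthetic_spec(
    n_genes = 2000, site_cells = c(HV = 25, PA = 25),
    site_program_effect = 0, site_dispersion = 0.5, cycling_fraction = 0,
    n_de_genes = 60, de_log2fc = 2, de_up_site = "HV", seed = 13))
  lg <- log2(unclass(co$matrix) + 1)
  up <- co$cells$cell_id[co$cells$site == "HV"]
  dn <- co$cells$cell_id[co$cells$site == "PA"]
  fc <- rowMeans(lg[co$truth$de_genes, up]) - rowMeans(lg[co$truth$de_genes, dn])
  expect_lt(abs(mean(fc) - 2), 0.3)
})

test_that("the TF/target pair achieves the requested correlation pre-dropout", {
  for (s in 1:3) {
    co <- generate_cohort(synthetic_spec(
      n_genes = 1600, site_cells = c(HV = 60, PV = 60),
      tf_target_r = 0.86, dropout_rate = 0, seed = s))
    ctc <- co$cells$cell_id[co$cells$cell_class == "CTC"]
    lg <- log2(unclass(co$matrix) + 1)
    r <- cor(lg[co$truth$tf_id, ctc], lg[co$truth$target_id, ctc])
    expect_lt(abs(r - 0.86), 0.05)
  }
})

test_that("CNV segments scale tumor expression by the requested copy ratio", {
  co <- generate_cohort(synthetic_spec(
    n_genes = 1600, site_cells = c(HV = 60, PV = 53),
    n_reference_cells = 8, dropout_rate = 0,
    cnv_segments = list(list(chrom = "chr1", from = 201, to = 500,
                             copy_ratio = 2)),
    seed = 17))
  seg <- co$truth$cnv_segments[[1]]
  ctc <- co$cells$cell_id[co$cells$cell_class == "CTC"]
  wbc <- co$cells$cell_id[co$cells$cell_class == "WBC"]
  x <- unclass(co$matrix)
  ratio <- rowMeans(x[seg$gene_ids, ctc]) / rowMeans(x[seg$gene_ids, wbc])
  expect_lt(abs(mean(ratio) / 2 - 1), 0.15)
})

test_that("dropout zeroes the requested fraction of entries deterministically", {
  co <- generate_cohort(small_spec(3, dropout_rate = 0.1))
  zero_frac <- mean(unclass(co$matrix) == 0)
  expect_lt(abs(zero_frac - 0.1), 0.01)
  co2 <- generate_cohort(small_spec(3, dropout_rate = 0.1))
  expect_identical(unclass(co$matrix), unclass(co2$matrix))
  expect_equal(co$cells$detected_genes,
               unname(colSums(unclass(co$matrix) > 0)))
})

test_that("a zero-cycling cohort classifies no cell as cycling", {
  co <- generate_cohort(small_spec(5, cycling_fraction = 0, cycle_effect = 0))
  sc <- cycle_scores(co$matrix, co$sets$G1S, co$sets$G2M, cells = co$cells)
  sc <- classify_cycling(sc, method = "threshold", threshold = 1)
  expect_equal(sum(sc$cycling), 0)
})

test_that("higher program dispersion lowers within-site pairwise correlation", {
  wins <- 0L
  for (s in 1:20) {
    co <- generate_cohort(synthetic_spec(
      n_genes = 1500, site_cells = c(HV = 12, PA = 12),
      site_dispersion = c(HV = 1, PA = 0.2), seed = 100 + s))
    ctc <- co$cells$cell_id[co$cells$cell_class == "CTC"]
    g <- select_variable_genes(co$matrix, 1000, cell_subset = ctc)
    het <- site_heterogeneity(co$matrix, co$cells, g)
    # direct-correlation cross-check of the module's per-site means
    lg <- log2(unclass(co$matrix)[g, ] + 1)
    pa <- co$cells$cell_id[co$cells$site == "PA"]
    cm <- cor(lg[, pa]); direct_pa <- mean(cm[upper.tri(cm)])
    expect_equal(unname(het$mean_r["PA"]), direct_pa, tolerance = 1e-12)
    if (het$mean_r["PA"] > het$mean_r["HV"]) wins <- wins + 1L
  }
  expect_gte(wins, 19)
})

test_that("QC stress fixtures plant the exact failing fraction in both modes", {
  cells <- generate_qc_stress(10, 0.5, seed = 1)
  fail <- cells$detected_genes < 3000 | cells$mapped_reads <= 1e6
  expect_equal(sum(fail), 5)
  expect_identical(fail, attr(cells, "qc_should_fail"))

  cells <- generate_qc_stress(3, 0, seed = 2)
  expect_equal(sum(cells$detected_genes < 3000 |
                     cells$mapped_reads <= 1e6), 0)

  cells <- generate_qc_stress(8, 0.5, seed = 3)
  expect_gte(sum(cells$detected_genes < 3000), 1)
  expect_gte(sum(cells$mapped_reads <= 1e6), 1)
})

test_that("a too-small genome for the requested layout is refused", {
  expect_error(generate_cohort(synthetic_spec(
    n_genes = 300, site_cells = c(HV = 3, PA = 3), seed = 1)),
    "too small")
})
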
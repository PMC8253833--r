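test_that("CPM prefilter keeps the 'more than two low samples' rule literal", {
  v <- rbind(c(0.5, 0.5, 0.5, rep(5, 7)),   # low in 3 of 10 -> removed
             c(0.5, 0.5, rep(5, 8)),        # low in exactly 2 -> kept
             rep(5, 10),                    # never low -> kept
             c(1, 1, 1, rep(5, 7)))         # exactly 1 CPM is not low
  m <- make_expr(v, unit = "CPM")
  keep <- cpm_prefilter(m)
  expect_equal(unname(keep), c(FALSE, TRUE, TRUE, TRUE))
})

test_that("a gene identical in both groups tests at exact p = 1", {
  v <- rbind(rep(2, 8), 2^c(1, 1, 1, 1, 5, 5, 5, 5))
  m <- make_expr(v, cell_ids = sprintf("c%d", 1:8))
  tab <- differential_test(m, sprintf("c%d", 1:4), sprintf("c%d", 5:8))
  expect_equal(tab$p[1], 1)
  expect_equal(tab$stage[1], "tested")
  expect_equal(tab$log2fc[2], log2(3) - log2(33))
  expect_error(differential_test(m, "c1", sprintf("c%d", 5:8)), ">= 2 cells")
})

test_that("swapping group labels negates fold changes and mirrors markers", {
  co <- generate_cohort(synthetic_spec(
    n_genes = 1600, site_cells = c(HV = 12, PA = 12),
    site_program_effect = 0, site_dispersion = 0.3, cycling_fraction = 0,
    n_de_genes = 30, de_log2fc = 2, seed = 59))
  a <- co$cells$cell_id[co$cells$site == "HV"]
  b <- co$cells$cell_id[co$cells$site == "PA"]
  ab <- refine_upregulated(differential_test(co$matrix, a, b), co$matrix)
  ba <- refine_upregulated(differential_test(co$matrix, b, a), co$matrix)
  expect_equal(ab$log2fc, -ba$log2fc)
  expect_equal(ab$p, ba$p)
  up_ab <- stage_genes(ab, "final")[ab$log2fc[match(stage_genes(ab, "final"),
                                                    ab$gene_id)] > 0]
  up_ba <- stage_genes(ba, "final")[ba$log2fc[match(stage_genes(ba, "final"),
                                                    ba$gene_id)] < 0]
  expect_setequal(up_ab, up_ba)
})

test_that("the cascade output is invariant to gene order and stages nest", {
  co <- generate_cohort(synthetic_spec(
    n_genes = 1600, site_cells = c(HV = 10, PA = 10),
    site_program_effect = 0, cycling_fraction = 0,
    n_de_genes = 20, seed = 61))
  a <- co$cells$cell_id[co$cells$site == "HV"]
  b <- co$cells$cell_id[co$cells$site == "PA"]
  t1 <- refine_upregulated(differential_test(co$matrix, a, b), co$matrix)
  shuf <- co$matrix[sample(nrow(co$matrix)), , drop = FALSE]
  t2 <- refine_upregulated(differential_test(shuf, a, b), shuf)
  expect_setequal(stage_genes(t1, "final"), stage_genes(t2, "final"))
  expect_true(all(stage_genes(t1, "final") %in% stage_genes(t1, "potential")))
  expect_true(all(stage_genes(t1, "potential") %in% stage_genes(t1, "initial")))
})

test_that("a hand-built toy walks through every cascade stage as the oracle says", {
  # 5 genes x 12 cells; groups of 6; oracle = wilcox.test + p.adjust + the
  # stage rules applied step by step with base R
  set.seed(67)
  ga <- sprintf("a%d", 1:6); gb <- sprintf("b%d", 1:6)
  v <- rbind(
    c(rep(40, 6), rep(2, 6)),           # strong up in A, always expressed
    c(38, 42, 44, 40, 36, 0.4, rep(2, 6)),  # strong but expressed in 5/6 (83%)
    c(rep(2, 6), rep(40, 6)),           # up in B
    c(rep(3, 6), rep(2.4, 6)),          # small fold change
    2^(rnorm(12, 3)))                   # noise
  m <- make_expr(v, cell_ids = c(ga, gb))
  tab <- differential_test(m, ga, gb, exact_limit = 0)  # approx path
  tab <- refine_upregulated(tab, m)

  lg <- log2(v + 1)
  p_or <- sapply(1:5, function(i)
    suppressWarnings(wilcox.test(lg[i, 1:6], lg[i, 7:12],
                                 exact = FALSE, correct = TRUE)$p.value))
  q_or <- p.adjust(p_or, "BH")
  fc_or <- rowMeans(lg[, 1:6]) - rowMeans(lg[, 7:12])
  init_or <- abs(fc_or) > 1 & p_or < 0.05 & q_or < 0.05
  expr_up <- ifelse(fc_or > 0, rowMeans(v[, 1:6] > 1), rowMeans(v[, 7:12] > 1))
  pot_or <- init_or & abs(fc_or) > 1 & expr_up >= 0.9
  fin_or <- pot_or & p_or < 0.05

  expect_equal(tab$p, unname(p_or), tolerance = 1e-12)
  expect_equal(tab$q, unname(q_or), tolerance = 1e-12)
  expect_setequal(stage_genes(tab, "initial"), tab$gene_id[init_or])
  expect_setequal(stage_genes(tab, "final"), tab$gene_id[fin_or])
  expect_equal(tab$stage[1], "final")
  expect_equal(tab$stage[3], "final")
})

test_that("the 90%-expressed rule holds an initial gene back from potential", {
  set.seed(69)
  ga <- sprintf("a%d", 1:20); gb <- sprintf("b%d", 1:20)
  up <- 2^rnorm(20, 6, 0.2); up[1:3] <- 0.5    # expressed in 17/20 = 85%
  held <- c(up, 2^rnorm(20, 2, 0.2))
  clean <- c(2^rnorm(20, 6, 0.2), 2^rnorm(20, 2, 0.2))
  m <- make_expr(rbind(held, clean), cell_ids = c(ga, gb))
  tab <- refine_upregulated(differential_test(m, ga, gb), m)
  expect_equal(tab$stage, c("initial", "final"))
})

test_that("an empty initial set refines to an empty final set", {
  set.seed(71)
  m <- make_expr(matrix(2^rnorm(40 * 10, 3, 0.2), nrow = 40),
                 cell_ids = sprintf("c%d", 1:10))
  tab <- differential_test(m, sprintf("c%d", 1:5), sprintf("c%d", 6:10))
  tab <- refine_upregulated(tab, m)
  expect_equal(length(stage_genes(tab, "initial")), 0)
  expect_equal(length(stage_genes(tab, "final")), 0)
})

test_that("planted DE genes are recovered with high precision and nulls controlled", {
  co <- generate_cohort(synthetic_spec(
    n_genes = 3000, site_cells = c(HV = 20, PA = 20),
    site_program_effect = 0, site_dispersion = 0.5, cycling_fraction = 0,
    n_de_genes = 100, de_log2fc = 2, de_up_site = "HV", seed = 73))
  a <- co$cells$cell_id[co$cells$site == "HV"]
  b <- co$cells$cell_id[co$cells$site == "PA"]
  tab <- refine_upregulated(differential_test(co$matrix, a, b), co$matrix)
  fin <- stage_genes(tab, "final")
  expect_gte(mean(co$truth$de_genes %in% fin), 0.8)
  expect_gte(mean(fin %in% co$truth$de_genes), 0.9)
  nulls <- setdiff(tab$gene_id, co$truth$de_genes)
  expect_lte(mean(nulls %in% stage_genes(tab, "initial")), 0.05)
})

test_that("hypergeometric enrichment matches enumeration and ranks planted sets first", {
  sets <- list(HIT = sprintf("m%d", 1:5))
  res <- enrich(sprintf("m%d", 1:5), sets, universe = 10)
  expect_equal(res$p, 1 / 252)          # C(10,5) enumeration
  res2 <- enrich(c("x1", "x2"), list(S = c("y1", "y2")), universe = 50)
  expect_equal(res2$overlap, 0)
  expect_equal(res2$p, 1)
  expect_error(enrich(character(0), sets, 10), "empty query")

  co <- generate_cohort(synthetic_spec(n_genes = 1600,
                                       site_cells = c(HV = 10, PA = 10),
                                       seed = 79))
  query <- co$truth$site_program_genes$HV
  res3 <- enrich(query, co$sets, universe = rownames(co$matrix))
  expect_equal(res3$set[1], "PROGRAM_HV")
  expect_equal(res3$q, bh_fdr(res3$p))
})
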
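test_that("relative expression centres every gene across cells", {
  m <- make_expr(rbind(c(1, 3, 7), c(5, 5, 5)), cell_ids = c("a", "b", "c"))
  e <- relative_expression(m, rownames(m))
  expect_equal(unname(e[1, ]), c(-1, 0, 1))      # log2(2,4,8) centred
  expect_equal(unname(e[2, ]), c(0, 0, 0))       # constant gene
  expect_true(all(abs(rowSums(e)) < 1e-9))
})

test_that("relative expression is equivariant under cell permutation", {
  set.seed(81)
  m <- make_expr(matrix(2^rnorm(12, 3), nrow = 3),
                 cell_ids = sprintf("c%d", 1:4))
  e <- relative_expression(m, rownames(m))
  perm <- c(3, 1, 4, 2)
  e2 <- relative_expression(m[, perm, drop = FALSE], rownames(m))
  expect_equal(e2, e[, perm])
})

test_that("missing signature genes are dropped with a warning, all-missing errors", {
  m <- make_expr(matrix(2^rnorm(9, 3), nrow = 3),
                 cell_ids = c("a", "b", "c"))
  expect_warning(e <- relative_expression(m, c("g01", "nope")), "dropped")
  expect_equal(nrow(e), 1)
  expect_error(relative_expression(m, c("no1", "no2")), "none of the listed")
})

test_that("cycle scores are zero for identical cells and stable to gene order", {
  base <- 2^rnorm(20, 4)
  m <- make_expr(matrix(rep(base, 4), ncol = 4),
                 gene_ids = sprintf("g%02d", 1:20),
                 cell_ids = sprintf("c%d", 1:4))
  sc <- cycle_scores(m, sprintf("g%02d", 1:8), sprintf("g%02d", 9:20))
  expect_true(all(sc$g1s_score == 0) && all(sc$g2m_score == 0))

  co <- generate_cohort(synthetic_spec(n_genes = 1600,
                                       site_cells = c(HV = 8, PA = 6),
                                       seed = 31))
  sc1 <- cycle_scores(co$matrix, co$sets$G1S, co$sets$G2M)
  shuf <- co$matrix[sample(nrow(co$matrix)), , drop = FALSE]
  sc2 <- cycle_scores(shuf, co$sets$G1S, co$sets$G2M)
  expect_equal(sc1, sc2)
})

test_that("a planted cycle boost raises scores by the centring-adjusted effect", {
  # closed form: a +effect boost on a fraction f of cells raises a boosted
  # cell's set score by ~effect * (1 - f) after centring (cross-leak makes
  # the same-phase fraction the effective f for the main set)
  co <- generate_cohort(synthetic_spec(
    n_genes = 1600, site_cells = c(HV = 40, PV = 40),
    cycling_fraction = 0.25, cycle_effect = 2, cycle_cross_leak = 0,
    seed = 37))
  ctc <- co$cells$cell_id[co$cells$cell_class == "CTC"]
  sc <- cycle_scores(co$matrix[, ctc], co$sets$G1S, co$sets$G2M,
                     cells = co$cells)
  g1s_cells <- names(which(co$truth$phase[ctc] == "G1S"))
  f <- length(g1s_cells) / length(ctc)
  expect_equal(mean(sc$g1s_score[sc$cell_id %in% g1s_cells]),
               2 * (1 - f), tolerance = 0.25)
  non <- !co$truth$cycling[sc$cell_id]
  expect_gt(min(sc$g1s_score[sc$cell_id %in% g1s_cells]),
            max(sc$g1s_score[non]))
})

test_that("both classifiers recover planted cycling cells", {
  sens <- spec_ <- numeric(0)
  for (s in 1:5) {
    co <- generate_cohort(synthetic_spec(cycling_fraction = 0.25,
                                         cycle_effect = 2, seed = 200 + s))
    ctc <- co$cells$cell_id[co$cells$cell_class == "CTC"]
    sc <- cycle_scores(co$matrix[, ctc], co$sets$G1S, co$sets$G2M,
                       cells = co$cells)
    truth <- co$truth$cycling[sc$cell_id]
    for (meth in c("hclust2", "threshold")) {
      cl <- classify_cycling(sc, meth)
      sens <- c(sens, mean(cl$cycling[truth]))
      spec_ <- c(spec_, mean(!cl$cycling[!truth]))
    }
  }
  expect_gte(mean(sens), 0.9)
  expect_gte(mean(spec_), 0.9)
})

test_that("recovered sensitivity is monotone in the cycle effect", {
  sens_at <- function(effect) {
    out <- numeric(0)
    for (s in 1:3) {
      co <- generate_cohort(synthetic_spec(
        n_genes = 1600, site_cells = c(HV = 30, PV = 30),
        cycling_fraction = 0.3, cycle_effect = effect, seed = 300 + s))
      ctc <- co$cells$cell_id[co$cells$cell_class == "CTC"]
      sc <- classify_cycling(cycle_scores(co$matrix[, ctc], co$sets$G1S,
                                          co$sets$G2M, cells = co$cells),
                             "threshold")
      out <- c(out, mean(sc$cycling[co$truth$cycling[sc$cell_id]]))
    }
    mean(out)
  }
  s <- vapply(c(0.5, 1.5, 3), sens_at, numeric(1))
  expect_true(all(diff(s) >= 0))
})

test_that("classification is deterministic and stable to cell relabeling", {
  co <- generate_cohort(synthetic_spec(cycling_fraction = 0.25, seed = 53))
  ctc <- co$cells$cell_id[co$cells$cell_class == "CTC"]
  sc <- cycle_scores(co$matrix[, ctc], co$sets$G1S, co$sets$G2M,
                     cells = co$cells)
  c1 <- classify_cycling(sc, "hclust2")
  c2 <- classify_cycling(sc, "hclust2")
  expect_identical(c1, c2)
  perm <- sample(nrow(sc))
  c3 <- classify_cycling(sc[perm, ], "hclust2")
  expect_equal(c3$cycling[order(perm)], c1$cycling)
})

test_that("identical score space yields an all-noncycling warning under hclust2", {
  sc <- data.frame(cell_id = c("a", "b"), g1s_score = 0, g2m_score = 0,
                   site = "HV", cycling = NA)
  class(sc) <- c("ctc_cycle_scores", "data.frame")
  expect_warning(out <- classify_cycling(sc, "hclust2"), "identical")
  expect_false(any(out$cycling))
})

test_that("per-site cycling proportions recover the planted fractions", {
  props <- NULL
  for (s in 1:5) {
    co <- generate_cohort(synthetic_spec(cycling_fraction = 0.25, seed = 400 + s))
    ctc <- co$cells$cell_id[co$cells$cell_class == "CTC"]
    sc <- classify_cycling(cycle_scores(co$matrix[, ctc], co$sets$G1S,
                                        co$sets$G2M, cells = co$cells),
                           "hclust2")
    props <- rbind(props, cycling_proportions(sc)$percent)
  }
  expect_true(all(abs(colMeans(props) - 25) <= 10))
})

test_that("the packaged signature GMT carries 42 G1/S and 54 G2/M genes", {
  sets <- cycle_signature_sets()
  expect_equal(length(sets$G1S), 42)
  expect_equal(length(sets$G2M), 54)
  expect_equal(length(intersect(sets$G1S, sets$G2M)), 0)
})
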
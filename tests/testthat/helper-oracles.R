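# Brute-force oracles, independent of the package implementations.

# two-sided rank-sum p by full enumeration of group labelings
oracle_wilcoxon_enum <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  r <- rank(c(a, b))
  mu <- n1 * (n - n1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2 - mu)
  combs <- utils::combn(n, n1)
  ws <- apply(combs, 2, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
  mean(abs(ws - mu) >= obs - 1e-9)
}

# BH step-up computed directly from the definition on the sorted sequence
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  qs <- rev(cummin(rev(m * ps / seq_len(m))))
  pmin(1, qs)[order(ord)]
}

# upper-tail hypergeometric by enumerating all draws (universe <= 12)
oracle_hyper_enum <- function(universe_n, set_k, query_n, overlap_k) {
  members <- seq_len(universe_n)
  in_set <- members <= set_k
  draws <- utils::combn(universe_n, query_n)
  mean(apply(draws, 2, function(d) sum(in_set[d])) >= overlap_k)
}

# Welch t from the textbook formula
oracle_welch <- function(a, b) {
  v1 <- var(a) / length(a); v2 <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(a) - 1) + v2^2 / (length(b) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# small tagged expression matrix from a plain matrix
make_expr <- function(values, unit = "FPKM",
                      gene_ids = sprintf("g%02d", seq_len(nrow(values))),
                      cell_ids = sprintf("c%02d", seq_len(ncol(values)))) {
  expression_matrix(values, gene_ids, cell_ids, unit = unit)
}

# adjusted Rand index between two labelings
oracle_ari <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * cc / choose(n, 2)
  (a - expected) / ((b + cc) / 2 - expected)
}
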
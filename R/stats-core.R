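# ---- statistical primitives -------------------------------------------------
# Small, self-contained tests used by every downstream stage. Each routine is
# written so that a brute-force oracle (enumeration / textbook formula) can
# verify it on small inputs.

new_test_result <- function(statistic, p_value, method) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(
    list(statistic = unname(statistic),
         p_value = unname(min(p_value, 1)),
         method = method),
    class = "ctc_test_result"
  )
}

#' @export
print.ctc_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g\n",
              x$method, x$statistic, x$p_value))
  invisible(x)
}

#' Pearson correlation with an explicit constant-vector contract
#'
#' Thin wrapper around [stats::cor()] that refuses constant vectors instead of
#' silently returning `NA`; callers decide their own drop/propagate policy.
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("pearson_cor: vectors must have equal length >= 2")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson_cor: correlation undefined for a constant vector")
  r <- stats::cor(x, y, method = "pearson")
  max(-1, min(1, r))
}

# Wilcoxon rank-sum statistic W = rank-sum of group a minus its minimum,
# using midranks for ties.
rank_sum_W <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Unpaired rank-sum (Mann-Whitney) test. For small samples (combined
#' `n <= exact_limit`) the p-value is computed by exact enumeration of all
#' group labelings, which remains exact under ties; larger samples use the
#' normal approximation with midrank tie correction and continuity
#' correction.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param exact_limit Combined-sample-size switchover to enumeration
#'   (default 12).
#' @return A `ctc_test_result` with the rank-sum statistic `W` (group `a`).
#' @export
wilcoxon_rank_sum <- function(a, b, exact_limit = 12) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1 || n2 < 1) stop("wilcoxon_rank_sum: both groups must be non-empty")
  W <- rank_sum_W(a, b)
  n <- n1 + n2
  if (n <= exact_limit) {
    # enumerate every C(n, n1) assignment of the pooled values to group a
    pooled <- c(a, b)
    r <- rank(pooled)
    combs <- utils::combn(n, n1)
    mu <- n1 * n2 / 2
    obs_dev <- abs(W - mu)
    ws <- apply(combs, 2, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
    p <- mean(abs(ws - mu) >= obs_dev - 1e-9)
  } else {
    mu <- n1 * n2 / 2
    r <- rank(c(a, b))
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
    if (sigma2 <= 0) return(new_test_result(W, 1, "wilcoxon_rank_sum"))
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  new_test_result(W, min(p, 1), "wilcoxon_rank_sum")
}

#' Two-sample t test (Welch default, pooled option)
#'
#' Welch unequal-variance t test with the Welch-Satterthwaite degrees of
#' freedom; `pooled = TRUE` gives the classical equal-variance Student t.
#' Two groups that are both constant and equal give `p = 1` by convention;
#' any other degenerate-variance configuration is an error.
#'
#' @param a,b Numeric vectors with at least 2 observations each.
#' @param pooled Use the pooled-variance Student t instead of Welch.
#' @return A `ctc_test_result`; statistic sign equals `sign(mean(a) - mean(b))`.
#' @export
welch_t <- function(a, b, pooled = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    stop("welch_t: each group needs >= 2 observations")
  v1 <- stats::var(a); v2 <- stats::var(b)
  m1 <- mean(a); m2 <- mean(b)
  if (v1 == 0 && v2 == 0) {
    if (isTRUE(all.equal(m1, m2)))
      return(new_test_result(0, 1, if (pooled) "student_t" else "welch_t"))
    stop("welch_t: zero variance in both groups with unequal means")
  }
  n1 <- length(a); n2 <- length(b)
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    method <- "student_t"
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    method <- "welch_t"
  }
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  new_test_result(tstat, p, method)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_(i) = min over j >= i of m * p_(j) / j`, clipped to 1, returned in the
#' original order. Monotone in the input ordering.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("bh_fdr: p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  q
}

#' Upper-tail hypergeometric overlap test
#'
#' `P(X >= overlap_k)` where `X` counts members of a `set_k`-gene set among
#' `query_n` genes drawn without replacement from a universe of `universe_n`.
#'
#' @param universe_n,set_k,query_n,overlap_k Non-negative integer counts.
#' @return A `ctc_test_result`; statistic is the observed overlap.
#' @export
hypergeom_overlap <- function(universe_n, set_k, query_n, overlap_k) {
  if (set_k > universe_n || query_n > universe_n)
    stop("hypergeom_overlap: set or query larger than universe")
  if (overlap_k > min(set_k, query_n))
    stop("hypergeom_overlap: overlap exceeds set or query size")
  if (overlap_k < max(0, set_k + query_n - universe_n))
    stop("hypergeom_overlap: impossible overlap for this configuration")
  p <- stats::phyper(overlap_k - 1, set_k, universe_n - set_k, query_n,
                     lower.tail = FALSE)
  new_test_result(overlap_k, p, "hypergeometric")
}
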
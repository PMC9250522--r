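# Row-wise two-sided Mann-Whitney U tests.
#
# The shuffle-null machinery needs hundreds of thousands of U tests on the
# same pooled samples under permuted group labels. Ranks (and the tie
# correction) depend only on the pooled sample, so they are computed once
# per row; each permutation then costs one rank sum. Default p-values use
# the normal approximation with tie and continuity correction (the
# convention whose achievable level at alpha = 0.05 matches the shuffle
# null this statistic is calibrated against); an exact method (tie-free
# samples only) is available. stats::wilcox.test is the per-cell oracle in
# the test suite.

row_ranks <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  t(apply(x, 1, rank))
}

# per-row sum of (t^3 - t) over tie groups
row_tie_term <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  apply(x, 1, function(r) {
    t <- table(r)
    sum(t^3 - t)
  })
}

# p-values from rank sums of group A given pooled ranks
# ra: per-row rank sum of the m group-A columns; tie_term from row_tie_term
mw_p_from_ranksum <- function(ra, m, n, tie_term = 0,
                              method = c("asymptotic", "exact"),
                              correct = TRUE) {
  method <- match.arg(method)
  u <- ra - m * (m + 1) / 2
  if (method == "exact") {
    if (any(tie_term > 0))
      abort("exact Mann-Whitney p-values require tie-free samples")
    p <- pmin(1, 2 * pmin(pwilcox(u, m, n), 1 - pwilcox(u - 1, m, n)))
    return(list(u = u, p = p))
  }
  N <- m + n
  mu <- m * n / 2
  sigma2 <- (m * n / 12) * ((N + 1) - tie_term / (N * (N - 1)))
  z <- u - mu
  if (correct) z <- z - sign(z) * 0.5
  sigma <- sqrt(sigma2)
  p <- ifelse(sigma > 0, pmin(1, 2 * pnorm(-abs(z) / sigma)), NA_real_)
  list(u = u, p = p)
}

# full row-wise test on a cells x trials matrix; rows with missing values
# yield NA
mw_test_rows <- function(x, idx_a, idx_b, method = "asymptotic",
                         correct = TRUE) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  sub <- x[, c(idx_a, idx_b), drop = FALSE]
  m <- length(idx_a); n <- length(idx_b)
  bad <- rowSums(is.na(sub)) > 0
  sub[bad, ] <- seq_len(m + n)   # placeholder, result overwritten with NA
  R <- row_ranks(sub)
  tie <- row_tie_term(sub)
  ra <- rowSums(R[, seq_len(m), drop = FALSE])
  res <- mw_p_from_ranksum(ra, m, n, tie, method = method, correct = correct)
  res$p[bad] <- NA_real_
  res$u[bad] <- NA_real_
  list(p = unname(res$p), u = unname(res$u),
       mean_a = unname(rowMeans(x[, idx_a, drop = FALSE])),
       mean_b = unname(rowMeans(x[, idx_b, drop = FALSE])))
}
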
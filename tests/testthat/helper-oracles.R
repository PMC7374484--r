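# Independent brute-force oracles for the agreement statistics, written
# directly from the defining formulas with explicit loops; used to check the
# package implementations on small instances.

oracle_fleiss <- function(m) {
  m <- m[apply(m, 1, function(r) !any(is.na(r))), , drop = FALSE]
  n <- nrow(m); r <- ncol(m)
  cats <- sort(unique(as.vector(m)))
  # per-subject agreement: fraction of agreeing rater pairs
  P_i <- numeric(n)
  for (i in 1:n) {
    agree <- 0
    for (a in 1:(r - 1)) for (b in (a + 1):r)
      if (m[i, a] == m[i, b]) agree <- agree + 1
    P_i[i] <- agree / (r * (r - 1) / 2)
  }
  p_j <- vapply(cats, function(cc) sum(m == cc) / (n * r), numeric(1))
  (mean(P_i) - sum(p_j^2)) / (1 - sum(p_j^2))
}

oracle_cohen <- function(r1, r2) {
  n <- length(r1)
  po <- sum(r1 == r2) / n
  cats <- sort(unique(c(r1, r2)))
  pe <- 0
  for (cc in cats) pe <- pe + (sum(r1 == cc) / n) * (sum(r2 == cc) / n)
  (po - pe) / (1 - pe)
}

# average ranks computed by explicit counting, then the Pearson formula on
# ranks (handles ties, unlike the 6*sum(d^2) shortcut)
oracle_rank <- function(v) {
  vapply(seq_along(v), function(i)
    sum(v < v[i]) + (sum(v == v[i]) + 1) / 2, numeric(1))
}

oracle_spearman <- function(x, y) {
  rx <- oracle_rank(x); ry <- oracle_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
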
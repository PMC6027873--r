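# Independent oracles. Each re-derives an expected value by a different
# route than the implementation under test: the Mann-Whitney oracle uses
# R's pwilcox distribution (tie-free) or a direct pairwise-count
# enumeration (ties), the Fisher oracle enumerates hypergeometric tables,
# the BH oracle walks the step-up rule, and the background oracle
# enumerates the transcriptome exhaustively.

# two-sided exact Mann-Whitney p via R's null distribution (no ties)
oracle_mw_pwilcox <- function(x, y) {
  nx <- length(x); ny <- length(y)
  U <- sum(outer(x, y, ">"))
  p <- if (U > nx * ny / 2)
    pwilcox(U - 1, nx, ny, lower.tail = FALSE) else pwilcox(U, nx, ny)
  list(U = U, p = min(1, 2 * p))
}

# exact Mann-Whitney by pairwise-count enumeration over label assignments
# (handles ties; U counted as #{x > y} + 0.5 #{x == y})
oracle_mw_enum <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  u_of <- function(ix) {
    a <- pooled[ix]; b <- pooled[-ix]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  U <- u_of(seq_len(nx))
  Us <- apply(combn(n, nx), 2, u_of)
  eps <- 1e-9
  p <- min(1, 2 * min(mean(Us <= U + eps), mean(Us >= U - eps)))
  list(U = U, p = p)
}

# two-sided Fisher p by summing hypergeometric probabilities of all tables
# with the observed margins and probability <= the observed table's
oracle_fisher_enum <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(a_range, c1, n - c1, r1)
  p_obs <- dhyper(m[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# BH step-up by the textbook rule
oracle_bh_stepup <- function(p, fdr) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * fdr / m)
  reject <- logical(m)
  if (length(k) > 0) reject[o[seq_len(max(k))]] <- TRUE
  q_sorted <- rev(cummin(rev(m * ps / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  list(reject = reject, q = q)
}

# pooled/Welch t-test from the textbook formulas
oracle_t_formula <- function(x, y, pooled = TRUE) {
  nx <- length(x); ny <- length(y)
  if (pooled) {
    sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se2 <- var(x) / nx + var(y) / ny
    t <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((var(x) / nx)^2 / (nx - 1) + (var(y) / ny)^2 / (ny - 1))
  }
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# exhaustive depth-weighted upstream composition of a transcriptome:
# expected proportions the Monte Carlo background converges to
oracle_background_exact <- function(tx, coverage = NULL, depth = 9) {
  seqs <- lapply(tx$sequence, function(s)
    match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "T")))
  if (is.null(coverage)) coverage <- lapply(seqs, function(v) rep(1, length(v)))
  else coverage <- coverage[tx$id]
  prop <- array(NA_real_, dim = c(4, depth, 4))
  for (f in 1:4) for (d in seq_len(depth)) {
    num <- numeric(4); den <- 0
    for (k in seq_along(seqs)) {
      v <- seqs[[k]]; cov <- coverage[[k]]
      idx <- which(v == f & cov > 0 & seq_along(v) > d)
      if (length(idx) == 0) next
      w <- cov[idx]
      up <- v[idx - d]
      for (b in 1:4) num[b] <- num[b] + sum(w[up == b])
      den <- den + sum(w)
    }
    # conditioned on the focal position having > d upstream bases, matching
    # the Monte Carlo tally (truncated draws drop out at position d)
    prop[f, d, ] <- if (den > 0) num / den else NA
  }
  prop
}
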
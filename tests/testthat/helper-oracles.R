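# Independent oracles, coded straightforwardly (loops, closed forms,
# exhaustive enumeration) so they share no code path with the package.

make_expr <- function(values) {
  expression_matrix(values,
                    gene_ids = sprintf("g%03d", seq_len(nrow(values))),
                    subject_ids = sprintf("s%03d", seq_len(ncol(values))))
}

# Direct per-gene loop over the moderated-difference formula.
oracle_d <- function(X, i1, i2, s0) {
  n1 <- length(i1); n2 <- length(i2)
  out <- numeric(nrow(X))
  for (g in seq_len(nrow(X))) {
    x1 <- X[g, i1]; x2 <- X[g, i2]
    ss <- sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)
    s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
    out[g] <- (mean(x2) - mean(x1)) / (s + s0)
  }
  out
}

# Step-by-step percentile search for the exchangeability factor: for each
# candidate percentile of the standard errors, compute the coefficient of
# variation of the windowed MAD of d; ties resolve to the smallest value.
oracle_choose_s0 <- function(X, i1, i2, n_windows = 100L) {
  n1 <- length(i1); n2 <- length(i2)
  r <- s <- numeric(nrow(X))
  for (g in seq_len(nrow(X))) {
    x1 <- X[g, i1]; x2 <- X[g, i2]
    ss <- sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)
    s[g] <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
    r[g] <- mean(x2) - mean(x1)
  }
  cand <- unname(quantile(s, probs = seq(0, 1, by = 0.05)))
  nw <- max(1L, min(n_windows, length(s) %/% 5L))
  win <- if (nw < 2) rep(1L, length(s)) else
    cut(rank(s, ties.method = "first"), breaks = nw, labels = FALSE)
  cvs <- sapply(cand, function(s0) {
    d <- r / (s + s0)
    v <- sapply(seq_len(nw), function(w) stats::mad(d[win == w]))
    if (mean(v) == 0) NaN else stats::sd(v) / mean(v)
  })
  if (all(!is.finite(cvs))) return(min(cand))
  cvs[!is.finite(cvs)] <- Inf
  min(cand[cvs == min(cvs)])
}

# Exhaustive-permutation SAM oracle at a FIXED s0: enumerates every
# distinct assignment of the combined samples to group 1, scans the
# symmetric delta cuts on a 0.01 grid and returns the smallest delta whose
# median-based FDR estimate passes the threshold, with its called count.
oracle_sam_exhaustive <- function(X, i1, i2, s0, fdr_threshold) {
  m <- length(i1) + length(i2)
  n1 <- length(i1)
  cols <- c(i1, i2)
  d_obs <- oracle_d(X, i1, i2, s0)
  combos <- combn(m, n1)
  dperm <- matrix(NA_real_, nrow(X), ncol(combos))
  for (b in seq_len(ncol(combos))) {
    a1 <- cols[combos[, b]]
    a2 <- setdiff(cols, a1)
    dperm[, b] <- oracle_d(X, a1, a2, s0)
  }
  dsort <- sort(d_obs)
  dbar <- rowMeans(apply(dperm, 2, sort))
  deltas <- seq(0, max(abs(dsort - dbar)) + 0.01, by = 0.01)
  for (delta in deltas) {
    up <- dsort[dsort > 0 & (dsort - dbar) >= delta]
    lo <- dsort[dsort < 0 & (dbar - dsort) >= delta]
    cutup <- if (length(up)) min(up) else Inf
    cutlow <- if (length(lo)) max(lo) else -Inf
    called <- d_obs >= cutup - 1e-9 | d_obs <= cutlow + 1e-9
    nc <- sum(called)
    if (nc == 0) {
      return(list(delta = delta, fdr = 0, n_called = 0L,
                  called = rep(FALSE, nrow(X))))
    }
    false_counts <- apply(dperm, 2, function(db) {
      # tolerance: permuted values tied with the cut count as beyond it
      sum(db >= cutup - 1e-9 | db <= cutlow + 1e-9)
    })
    fdr <- min(1, mean(false_counts) / nc)
    if (fdr <= fdr_threshold) {
      return(list(delta = delta, fdr = fdr, n_called = nc, called = called))
    }
  }
  list(delta = NA_real_, fdr = NA_real_, n_called = 0L,
       called = rep(FALSE, nrow(X)))
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments.
oracle_mwu_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  vals <- c(x, y)
  u_stat <- function(ix) {
    rx <- rank(vals)[ix]
    sum(rx) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_stat(seq_len(n1))
  combos <- combn(n1 + n2, n1)
  us <- apply(combos, 2, u_stat)
  pl <- mean(us <= u_obs)
  pu <- mean(us >= u_obs)
  min(1, 2 * min(pl, pu))
}

# Two-sided Fisher p by direct hypergeometric summation: tables with the
# observed margins whose probability does not exceed the observed one
# (with the conventional relative tolerance).
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  probs <- dhyper(lo:hi, r1, n - r1, c1)
  p_obs <- dhyper(tab[1, 1], r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Upper-tail binomial probability by direct summation.
oracle_binom_upper <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(dbinom(k:n, n, p))
}

# One-sided over-representation p by hypergeometric enumeration.
oracle_hyper_upper <- function(overlap, pathway, universe, query) {
  hi <- min(pathway, query)
  if (overlap > hi) return(0)
  sum(dhyper(overlap:hi, pathway, universe - pathway, query))
}

# Deterministic objective stub for optimizer-contract tests: a fixed
# pseudo-random score attached to each partition of group 1.
stub_engine <- function(score_fn) {
  function(expr, g1, g2) score_fn(sort(g1), sort(g2))
}
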
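#' SAM engine parameters
#'
#' Tuning parameters of the two-class unpaired SAM (Significance Analysis
#' of Microarrays) engine used as the shuffling objective.
#'
#' @param n_permutations Number of label permutations for the FDR estimate.
#'   When it reaches or exceeds the number of distinct label assignments,
#'   assignments are enumerated exhaustively instead.
#' @param s0_mode `"tusher_percentile"` (default): the exchangeability
#'   factor s0 is chosen by minimizing the coefficient of variation of the
#'   d-statistic's dispersion across standard-error percentile windows;
#'   `"fixed"`: use `s0_value` as given.
#' @param s0_value Nonnegative s0 when `s0_mode = "fixed"`.
#' @param fdr_threshold Target median FDR in (0, 1). The optimizer default
#'   is the permissive 0.1 used to let a seed grouping emerge; reported
#'   comparisons conventionally use 0.05.
#' @param seed Integer seed fixing the sampled permutation set.
#'
#' @return A list of class `sam_params`.
#' @export
sam_params <- function(n_permutations = 1000L,
                       s0_mode = c("tusher_percentile", "fixed"),
                       s0_value = NULL,
                       fdr_threshold = 0.1,
                       seed = 1L) {
  s0_mode <- match.arg(s0_mode)
  assert_scalar_number(n_permutations, "n_permutations", min = 1)
  assert_scalar_number(fdr_threshold, "fdr_threshold")
  if (fdr_threshold <= 0 || fdr_threshold >= 1) {
    abort("`fdr_threshold` must lie strictly between 0 and 1")
  }
  if (s0_mode == "fixed") {
    if (is.null(s0_value)) abort("`s0_value` required when s0_mode = 'fixed'")
    assert_scalar_number(s0_value, "s0_value", min = 0)
  }
  structure(list(
    n_permutations = as.integer(n_permutations),
    s0_mode = s0_mode,
    s0_value = s0_value,
    fdr_threshold = fdr_threshold,
    seed = as.integer(seed)
  ), class = "sam_params")
}

# Validate groups against the matrix and return column indices.
resolve_groups <- function(expr, group1, group2) {
  stopifnot(inherits(expr, "expression_matrix"))
  group1 <- as.character(group1)
  group2 <- as.character(group2)
  if (length(intersect(group1, group2))) abort("groups must be disjoint")
  if (length(group1) < 2L || length(group2) < 2L) {
    abort("each group must contain at least 2 subjects")
  }
  miss <- setdiff(c(group1, group2), colnames(expr))
  if (length(miss)) {
    abort(sprintf("subjects not in expression matrix: %s",
                  paste(head(miss, 5), collapse = ", ")))
  }
  list(i1 = match(group1, colnames(expr)), i2 = match(group2, colnames(expr)))
}

# Per-gene difference of means and pooled standard error for columns
# idx1 (group 1) vs idx2 (group 2) of numeric matrix X.
gene_stats <- function(X, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  x1 <- X[, idx1, drop = FALSE]
  x2 <- X[, idx2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
  list(r = m2 - m1, s = s)
}

#' SAM d-statistic
#'
#' The moderated difference statistic `d_i = (mean2_i - mean1_i) / (s_i + s0)`
#' with `s_i` the pooled gene-wise standard error. Positive values mean the
#' gene is higher in `group2`.
#'
#' @param expr An [expression_matrix()].
#' @param group1,group2 Disjoint character vectors of subject ids, each of
#'   size at least 2.
#' @param s0 Nonnegative exchangeability (fudge) factor. When `s0 = 0`,
#'   every gene must have positive pooled standard error.
#'
#' @return Named numeric vector, one finite d per gene.
#' @export
sam_d_statistic <- function(expr, group1, group2, s0) {
  idx <- resolve_groups(expr, group1, group2)
  assert_scalar_number(s0, "s0", min = 0)
  gs <- gene_stats(unclass(expr), idx$i1, idx$i2)
  if (s0 == 0 && any(gs$s == 0)) {
    abort("s0 = 0 requires positive pooled standard error for every gene")
  }
  setNames(gs$r / (gs$s + s0), rownames(expr))
}

# s0 selection on precomputed (r, s): candidates are percentiles
# {0, 5, ..., 100} of s; pick the candidate minimizing the coefficient of
# variation of the windowed median absolute deviation of d across
# percentile windows of s. Ties (and all-NaN CVs) resolve to the smallest
# candidate.
choose_s0_impl <- function(r, s, n_windows = 100L) {
  cand <- unname(quantile(s, probs = seq(0, 1, by = 0.05), type = 7))
  p <- length(s)
  # keep at least ~5 genes per window so the windowed dispersion is defined
  n_windows <- max(1L, min(n_windows, p %/% 5L))
  win <- if (n_windows < 2L) rep(1L, p) else
    cut(rank(s, ties.method = "first"), breaks = n_windows, labels = FALSE)
  win_idx <- split(seq_len(p), win)
  cv <- vapply(cand, function(s0) {
    d <- r / (s + s0)
    v <- vapply(win_idx, function(ix) fmad(d[ix]), numeric(1))
    if (mean(v) == 0) return(NaN)
    sd(v) / mean(v)
  }, numeric(1))
  if (all(!is.finite(cv))) {
    warn("all candidate s0 give degenerate dispersion; using smallest candidate")
    return(min(cand))
  }
  cv[!is.finite(cv)] <- Inf
  best <- which(cv == min(cv))
  min(cand[best])
}

#' Choose the SAM exchangeability factor s0
#'
#' Implements the percentile-search rule: candidate s0 values are the
#' percentiles \{0, 5, ..., 100\} of the gene-wise pooled standard errors;
#' the chosen s0 minimizes the coefficient of variation of the median
#' absolute deviation of d across standard-error percentile windows.
#'
#' @inheritParams sam_d_statistic
#' @param n_windows Number of standard-error windows (default 100, reduced
#'   automatically so each window holds at least ~5 genes).
#'
#' @return A single nonnegative number.
#' @export
choose_s0 <- function(expr, group1, group2, n_windows = 100L) {
  idx <- resolve_groups(expr, group1, group2)
  gs <- gene_stats(unclass(expr), idx$i1, idx$i2)
  if (all(gs$s == 0)) {
    # degenerate: every candidate percentile is 0; fall back to a positive
    # value on the scale of the mean differences so d stays finite
    warn("all gene-wise standard errors are zero; using a positive fallback s0")
    return(max(mad(gs$r), 1e-6))
  }
  choose_s0_impl(gs$r, gs$s, n_windows)
}

# Build the permutation assignment matrix: m x B logical, TRUE marks the
# positions (within the combined group) assigned to group 1. Exhaustive
# enumeration when B >= choose(m, n1); otherwise B assignments sampled
# under `seed`. The observed assignment occupies positions 1..n1.
perm_assignments <- function(m, n1, B, seed) {
  total <- choose(m, n1)
  if (B >= total) {
    idx <- combn(m, n1)
    out <- matrix(FALSE, m, ncol(idx))
    out[cbind(as.vector(idx), rep(seq_len(ncol(idx)), each = n1))] <- TRUE
    attr(out, "exhaustive") <- TRUE
    return(out)
  }
  out <- local_seed(seed, {
    vapply(seq_len(B), function(b) {
      z <- logical(m)
      z[sample.int(m, n1)] <- TRUE
      z
    }, logical(m))
  })
  attr(out, "exhaustive") <- FALSE
  out
}

# d-statistics for every permuted assignment, sharing s0.
# X: p x m matrix of the combined groups; P: m x B logical assignment.
perm_d_matrix <- function(X, P, s0) {
  m <- ncol(X); n1 <- sum(P[, 1]); n2 <- m - n1
  Pn <- P * 1
  sum1 <- X %*% Pn
  sumsq1 <- (X^2) %*% Pn
  tot <- rowSums(X); totsq <- rowSums(X^2)
  mean1 <- sum1 / n1
  mean2 <- (tot - sum1) / n2
  ss <- (sumsq1 - n1 * mean1^2) + ((totsq - sumsq1) - n2 * mean2^2)
  ss[ss < 0] <- 0 # numerical guard
  s <- sqrt((1 / n1 + 1 / n2) * ss / (m - 2))
  (mean2 - mean1) / (s + s0)
}

# Symmetric delta cut on sorted observed d against the permutation-averaged
# order statistics dbar. Returns the calling thresholds. (Reference
# implementation of the per-delta rule; the main engine vectorizes the
# same computation over the whole delta grid.)
delta_cuts <- function(dsort, dbar, delta) {
  up <- dsort > 0 & (dsort - dbar) >= delta
  lo <- dsort < 0 & (dbar - dsort) >= delta
  list(
    cutup = if (any(up)) min(dsort[up]) else Inf,
    cutlow = if (any(lo)) max(dsort[lo]) else -Inf
  )
}

#' Count differentially expressed genes with SAM
#'
#' Two-class unpaired SAM with permutation-estimated FDR. Permuted
#' d-statistics (sharing the observed s0) are sorted per permutation and
#' averaged to give expected order statistics; a symmetric threshold delta
#' is scanned on a 0.01 grid, the estimated FDR at each delta being the
#' mean number of permuted genes beyond the cuts divided by the number of
#' genes called. The smallest delta with estimated FDR at or below
#' `params$fdr_threshold` defines the called set.
#'
#' The result is deterministic given `params$seed`, and invariant (up to
#' the sign of d) under exchanging `group1` and `group2`: the permutation
#' set is generated in a canonical group orientation.
#'
#' @inheritParams sam_d_statistic
#' @param params A [sam_params()] object.
#' @param assignments Optional precomputed permutation assignment matrix
#'   (as used internally by the optimizer to freeze the objective's
#'   permutation set across swap iterations).
#' @param keep_genes If `FALSE`, skip the per-gene q-value table (fast path
#'   for the optimizer).
#'
#' @return A `de_result` object; see [de_result()].
#' @export
sam_count_de <- function(expr, group1, group2, params = sam_params(),
                         assignments = NULL, keep_genes = TRUE) {
  stopifnot(inherits(params, "sam_params"))
  idx <- resolve_groups(expr, group1, group2)

  # canonical orientation: the group containing the lexicographically
  # smallest subject id is placed first, so the permutation set (and hence
  # n_called) is identical under label exchange; d is sign-flipped back.
  flip <- min(as.character(group1)) > min(as.character(group2))
  if (flip) {
    tmp <- group1; group1 <- group2; group2 <- tmp
    idx <- list(i1 = idx$i2, i2 = idx$i1)
  }

  X <- unclass(expr)[, c(idx$i1, idx$i2), drop = FALSE]
  n1 <- length(idx$i1); n2 <- length(idx$i2); m <- n1 + n2
  p <- nrow(X)

  gs <- gene_stats(X, seq_len(n1), n1 + seq_len(n2))
  s0 <- if (params$s0_mode == "fixed") params$s0_value else choose_s0_impl(gs$r, gs$s)
  d <- gs$r / (gs$s + s0)

  if (is.null(assignments)) {
    assignments <- perm_assignments(m, n1, params$n_permutations, params$seed)
    if (isTRUE(attr(assignments, "exhaustive")) &&
        params$n_permutations > ncol(assignments)) {
      inform(sprintf(
        "n_permutations exceeds the %d distinct label assignments; enumerating exhaustively",
        ncol(assignments)
      ))
    }
  } else if (nrow(assignments) != m || sum(assignments[, 1]) != n1) {
    abort("`assignments` does not match the group sizes")
  }

  dperm <- perm_d_matrix(X, assignments, s0)
  dperm_sorted <- apply(dperm, 2L, sort)
  dbar <- rowMeans(dperm_sorted)
  dsort <- sort(d)
  B <- ncol(dperm)

  deltas <- seq(0, max(abs(dsort - dbar)) + 0.01, by = 0.01)
  D <- length(deltas)

  # calling thresholds for every delta at once. On the positive side the
  # qualifying set {i : dsort_i > 0, dsort_i - dbar_i >= delta} shrinks as
  # delta grows, so cutup(delta) = min dsort over it is the prefix-min of
  # dsort ordered by decreasing excess; symmetrically below the origin.
  iu <- which(dsort > 0)
  if (length(iu)) {
    exc_up <- (dsort - dbar)[iu]
    ord <- order(exc_up, decreasing = TRUE)
    pref_min <- cummin(dsort[iu][ord])
    exc_sorted <- sort(exc_up) # ascending
    k_up <- length(iu) - findInterval(deltas - 1e-12, exc_sorted)
    cutup <- ifelse(k_up > 0, pref_min[pmax(k_up, 1L)], Inf)
  } else {
    cutup <- rep(Inf, D)
  }
  il <- which(dsort < 0)
  if (length(il)) {
    exc_lo <- (dbar - dsort)[il]
    ord <- order(exc_lo, decreasing = TRUE)
    pref_max <- cummax(dsort[il][ord])
    exc_sorted <- sort(exc_lo)
    k_lo <- length(il) - findInterval(deltas - 1e-12, exc_sorted)
    cutlow <- ifelse(k_lo > 0, pref_max[pmax(k_lo, 1L)], -Inf)
  } else {
    cutlow <- rep(-Inf, D)
  }

  # observed calls and per-permutation false calls beyond the cuts,
  # vectorized over the delta grid (cutup is non-decreasing, cutlow
  # non-increasing, so findInterval applies)
  # values at the cut are called: eps absorbs float jitter, e.g. a permuted
  # assignment equal to the cut by symmetry but recomputed through a
  # different arithmetic path
  eps <- 1e-9
  count_beyond <- function(sorted_vals) {
    up <- length(sorted_vals) - findInterval(cutup - eps, sorted_vals)
    lo <- findInterval(cutlow + eps, sorted_vals)
    up + lo
  }
  nc_at <- count_beyond(dsort)
  false_mat <- vapply(seq_len(B), function(b) count_beyond(dperm_sorted[, b]),
                      numeric(D))
  # expected false calls at each delta: the mean count of permuted genes
  # beyond the cuts. The mean (rather than the per-permutation median) is
  # essential for the automated delta search: a singleton cut at the
  # observed extreme has median false count 0 in about half of null data
  # sets, which would let the search manufacture one spurious call.
  mean_false <- rowMeans(false_mat)
  fdr_at <- ifelse(nc_at == 0L, 0, pmin(1, mean_false / pmax(nc_at, 1L)))

  k_star <- which(fdr_at <= params$fdr_threshold)[1]
  called <- if (is.na(k_star)) {
    rep(FALSE, p)
  } else {
    d >= cutup[k_star] - eps | d <= cutlow[k_star] + eps
  }

  # per-gene q: the smallest estimated FDR at any delta calling the gene.
  # Called sets are nested in delta, so a gene's calling range is
  # delta indices 1..m_g and its q is the running minimum of fdr there.
  q <- rep(1, p)
  if (keep_genes) {
    cmin <- cummin(fdr_at)
    m_up <- findInterval(d + eps, cutup) # cutup non-decreasing: # deltas with cutup <= d_g
    m_lo <- D - findInterval(d - eps, rev(cutlow)) # cutlow non-increasing
    m_g <- pmax(m_up, m_lo)
    q[m_g > 0] <- cmin[m_g[m_g > 0]]
  }

  d_out <- if (flip) -d else d
  de_result(
    gene_ids = rownames(X),
    statistic = d_out,
    q_or_fdr = q,
    called = called,
    engine = "sam",
    fdr_threshold = params$fdr_threshold,
    extra = list(s0 = s0, n_permutations = B,
                 exhaustive = isTRUE(attr(assignments, "exhaustive")),
                 seed = params$seed,
                 delta = if (is.na(k_star)) NA_real_ else deltas[k_star],
                 estimated_fdr = if (is.na(k_star)) NA_real_ else fdr_at[k_star])
  )
}

#' Count differentially expressed genes with Welch t / Benjamini-Hochberg
#'
#' The fast alternative objective: per-gene Welch two-sample t-test,
#' Benjamini-Hochberg adjustment across genes, called at adjusted
#' p at or below `fdr_threshold`. A gene with zero variance in both groups
#' has its p-value set to 1 (degenerate test).
#'
#' @inheritParams sam_d_statistic
#' @param fdr_threshold BH-adjusted p-value cutoff in (0, 1).
#'
#' @return A `de_result` object; see [de_result()].
#' @export
ttest_count_de <- function(expr, group1, group2, fdr_threshold = 0.05) {
  idx <- resolve_groups(expr, group1, group2)
  if (fdr_threshold <= 0 || fdr_threshold >= 1) {
    abort("`fdr_threshold` must lie strictly between 0 and 1")
  }
  X <- unclass(expr)
  n1 <- length(idx$i1); n2 <- length(idx$i2)
  x1 <- X[, idx$i1, drop = FALSE]; x2 <- X[, idx$i2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- rep(0, nrow(X))
  pval <- rep(1, nrow(X))
  pos <- se2 > 0
  if (any(!pos)) {
    inform(sprintf("%d gene(s) with zero variance in both groups; p set to 1", sum(!pos)))
  }
  if (any(pos)) {
    tstat[pos] <- (m2[pos] - m1[pos]) / sqrt(se2[pos])
    df <- se2[pos]^2 / (v1[pos]^2 / (n1^2 * (n1 - 1)) + v2[pos]^2 / (n2^2 * (n2 - 1)))
    pval[pos] <- 2 * pt(-abs(tstat[pos]), df)
  }
  padj <- p.adjust(pval, method = "BH")
  de_result(
    gene_ids = rownames(X),
    statistic = setNames(tstat, rownames(X)),
    q_or_fdr = padj,
    called = padj <= fdr_threshold,
    engine = "ttest_bh",
    fdr_threshold = fdr_threshold
  )
}

#' Differential expression result
#'
#' Container for one two-group comparison: per-gene statistic (SAM d or
#' Welch t), per-gene q-value/FDR, the called set and its size.
#'
#' @param gene_ids Character vector of gene ids.
#' @param statistic Per-gene statistic (positive = higher in group 2).
#' @param q_or_fdr Per-gene q-value (SAM) or BH-adjusted p (t engine).
#' @param called Logical vector of significance calls.
#' @param engine `"sam"` or `"ttest_bh"`.
#' @param fdr_threshold The FDR cutoff used.
#' @param extra Optional list of engine-specific metadata (s0, seed, ...).
#'
#' @return An object of class `de_result`.
#' @export
de_result <- function(gene_ids, statistic, q_or_fdr, called, engine,
                      fdr_threshold, extra = list()) {
  stopifnot(length(gene_ids) == length(statistic),
            length(statistic) == length(q_or_fdr),
            length(q_or_fdr) == length(called))
  structure(c(list(
    gene_ids = as.character(gene_ids),
    statistic = unname(statistic),
    q_or_fdr = unname(q_or_fdr),
    called = unname(called),
    n_called = sum(called),
    engine = engine,
    fdr_threshold = fdr_threshold
  ), extra), class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("<de_result> engine=%s, FDR threshold %.3g: %d of %d genes called\n",
              x$engine, x$fdr_threshold, x$n_called, length(x$gene_ids)))
  invisible(x)
}

#' @export
#' @method tidy de_result
tidy.de_result <- function(x, ...) {
  tibble(
    gene_id = x$gene_ids,
    statistic = x$statistic,
    q_value = x$q_or_fdr,
    called = x$called
  )
}

#' @export
#' @method glance de_result
glance.de_result <- function(x, ...) {
  tibble(
    engine = x$engine,
    fdr_threshold = x$fdr_threshold,
    n_genes = length(x$gene_ids),
    n_called = x$n_called,
    s0 = x$s0 %||% NA_real_
  )
}

#' Genes called significant in a differential expression result
#'
#' @param x A [de_result()].
#' @return Character vector of called gene ids.
#' @export
called_genes <- function(x) {
  stopifnot(inherits(x, "de_result"))
  x$gene_ids[x$called]
}
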
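# The SAM engine: moderated d-statistic, s0 search, permutation FDR;
# the Welch/BH engine; and their contracts.

test_that("d-statistic matches closed forms and the direct-formula oracle", {
  # within-group-constant gene: s = 0, d = (2 - 0) / (0 + 1) = 2
  X <- matrix(c(0, 0, 0, 2, 2, 2), 1)
  em <- make_expr(X)
  d <- sam_d_statistic(em, colnames(em)[1:3], colnames(em)[4:6], s0 = 1)
  expect_equal(unname(d), 2)

  # identical distributions per gene in both groups: d = 0 everywhere
  Y <- matrix(rep(c(1, 5, 9, 1, 5, 9), each = 4), 4, byrow = FALSE)
  emy <- make_expr(Y)
  dy <- sam_d_statistic(emy, colnames(emy)[1:3], colnames(emy)[4:6], s0 = 0.5)
  expect_equal(unname(dy), rep(0, 4))

  # random 50-gene 6v6 fixture against the loop oracle
  set.seed(71)
  Z <- matrix(rnorm(50 * 12, mean = 8), 50, 12)
  emz <- make_expr(Z)
  dz <- sam_d_statistic(emz, colnames(emz)[1:6], colnames(emz)[7:12], s0 = 0.3)
  expect_lt(max(abs(unname(dz) - oracle_d(Z, 1:6, 7:12, 0.3))), 1e-10)
})

test_that("group validation rejects overlap, tiny groups, and s0 = 0 with zero SE", {
  em <- make_expr(matrix(rnorm(40), 5, 8))
  ids <- colnames(em)
  expect_error(sam_d_statistic(em, ids[1:4], ids[4:8], 1), "disjoint")
  expect_error(sam_d_statistic(em, ids[1], ids[2:5], 1), "at least 2")
  const <- make_expr(matrix(5, 2, 6))
  expect_error(sam_d_statistic(const, colnames(const)[1:3], colnames(const)[4:6], 0),
               "positive pooled standard error")
})

test_that("s0 search reproduces the independent percentile-search oracle", {
  set.seed(72)
  X <- matrix(rnorm(100 * 10, mean = 8, sd = exp(rnorm(100, 0, 0.4))), 100, 10)
  em <- make_expr(X)
  s0_pkg <- choose_s0(em, colnames(em)[1:5], colnames(em)[6:10])
  s0_oracle <- oracle_choose_s0(X, 1:5, 6:10)
  expect_equal(s0_pkg, s0_oracle, tolerance = 1e-12)

  # identical s for every gene: every candidate ties, smallest wins —
  # which is the 0th percentile, i.e. the common pooled SE itself
  Y <- matrix(c(rep(c(0, 1), 3), rep(c(10, 11), 3)), 4, 6, byrow = TRUE)
  emy <- make_expr(Y)
  s0_tie <- suppressWarnings(choose_s0(emy, colnames(emy)[1:3], colnames(emy)[4:6]))
  expect_equal(s0_tie, oracle_choose_s0(Y, 1:3, 4:6))
  expect_equal(s0_tie, sqrt((1 / 3 + 1 / 3) * (4 / 3) / 4))

  # fixed mode bypasses the search entirely
  sp <- sam_params(n_permutations = 10, s0_mode = "fixed", s0_value = 0.5, seed = 1)
  res <- suppressMessages(sam_count_de(em, colnames(em)[1:5], colnames(em)[6:10], sp))
  expect_equal(res$s0, 0.5)
})

test_that("permutation FDR is exhaustive on tiny designs and matches the oracle", {
  set.seed(73)
  X <- matrix(rnorm(30 * 4, mean = 8), 30, 4)
  X[1:5, 3:4] <- X[1:5, 3:4] + 3
  em <- make_expr(X)
  sp <- sam_params(n_permutations = 1000, s0_mode = "fixed", s0_value = 0.2,
                   fdr_threshold = 0.25, seed = 9)
  expect_message(res <- sam_count_de(em, colnames(em)[1:2], colnames(em)[3:4], sp),
                 "enumerating exhaustively")
  orc <- oracle_sam_exhaustive(X, 1:2, 3:4, s0 = 0.2, fdr_threshold = 0.25)
  expect_identical(res$n_called, orc$n_called)
  expect_equal(res$estimated_fdr, orc$fdr)
  expect_equal(res$delta, orc$delta)
  expect_identical(res$called, orc$called)
})

test_that("under the global null, spurious calls are rare across seeds", {
  set.seed(74)
  positive <- 0L
  for (s in 1:50) {
    X <- matrix(rnorm(100 * 12, mean = 8), 100, 12)
    em <- make_expr(X)
    sp <- sam_params(n_permutations = 60, fdr_threshold = 0.05, seed = s)
    res <- suppressMessages(sam_count_de(em, colnames(em)[1:6], colnames(em)[7:12], sp,
                                         keep_genes = FALSE))
    positive <- positive + (res$n_called > 0L)
  }
  # the permutation FDR is conservative in expectation, not per run
  expect_lte(positive / 50, 0.2)
})

test_that("a strongly planted signal is recovered by both engines concordantly", {
  set.seed(75)
  X <- matrix(rnorm(200 * 20, mean = 8), 200, 20)
  X[1:10, 11:20] <- X[1:10, 11:20] + 4 # 10 genes, 4 x SD shift
  em <- make_expr(X)
  g1 <- colnames(em)[1:10]; g2 <- colnames(em)[11:20]
  planted <- rownames(em)[1:10]

  tt <- ttest_count_de(em, g1, g2, fdr_threshold = 0.05)
  expect_true(all(planted %in% called_genes(tt)))

  sp <- sam_params(n_permutations = 200, fdr_threshold = 0.05, seed = 7)
  sm <- suppressMessages(sam_count_de(em, g1, g2, sp))
  expect_true(all(planted %in% called_genes(sm)))
  expect_lte(abs(sm$n_called - tt$n_called), 2)

  # direct Welch + BH oracle via stats::t.test and p.adjust
  pvals <- apply(X, 1, function(row) t.test(row[11:20], row[1:10])$p.value)
  called_oracle <- p.adjust(pvals, "BH") <= 0.05
  expect_identical(tt$called, unname(called_oracle))
})

test_that("Welch/BH engine handles degenerate genes and matches hand computation", {
  X <- rbind(
    c(1, 2, 3, 4, 7, 8, 9, 10),   # clear shift
    c(5, 5, 5, 5, 5, 5, 5, 5),    # zero variance both groups -> p = 1
    c(2, 4, 6, 8, 3, 5, 7, 9)     # mild shift
  )
  em <- make_expr(X)
  expect_message(res <- ttest_count_de(em, colnames(em)[1:4], colnames(em)[5:8], 0.05),
                 "zero variance")
  p1 <- t.test(X[1, 5:8], X[1, 1:4])$p.value
  p3 <- t.test(X[3, 5:8], X[3, 1:4])$p.value
  expect_equal(res$q_or_fdr, p.adjust(c(p1, 1, p3), "BH"), tolerance = 1e-9)
  expect_identical(res$n_called, 1L)
})

test_that("raising the FDR threshold never shrinks the called set (same seed)", {
  set.seed(76)
  X <- matrix(rnorm(80 * 12, mean = 8), 80, 12)
  X[1:8, 7:12] <- X[1:8, 7:12] + 1.5
  em <- make_expr(X)
  counts <- vapply(c(0.01, 0.05, 0.1, 0.2, 0.4), function(thr) {
    sp <- sam_params(n_permutations = 50, fdr_threshold = thr, seed = 11)
    suppressMessages(sam_count_de(em, colnames(em)[1:6], colnames(em)[7:12], sp,
                                  keep_genes = FALSE))$n_called
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("exchanging the groups negates d and preserves the called count", {
  set.seed(77)
  X <- matrix(rnorm(60 * 10, mean = 8), 60, 10)
  X[1:6, 6:10] <- X[1:6, 6:10] + 2
  em <- make_expr(X)
  g1 <- colnames(em)[1:5]; g2 <- colnames(em)[6:10]
  sp <- sam_params(n_permutations = 40, fdr_threshold = 0.1, seed = 3)
  a <- suppressMessages(sam_count_de(em, g1, g2, sp))
  b <- suppressMessages(sam_count_de(em, g2, g1, sp))
  expect_equal(a$statistic, -b$statistic)
  expect_identical(a$n_called, b$n_called)
  expect_identical(a$called, b$called)
})

test_that("de_result bookkeeping and broom methods are consistent", {
  set.seed(78)
  em <- make_expr(matrix(rnorm(40, mean = 8), 10, 4))
  res <- ttest_count_de(em, colnames(em)[1:2], colnames(em)[3:4], 0.5)
  expect_identical(res$n_called, sum(tidy(res)$called))
  g <- glance(res)
  expect_identical(g$n_genes, 10L)
  expect_identical(g$engine, "ttest_bh")
})
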
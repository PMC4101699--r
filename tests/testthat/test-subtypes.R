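# Downstream subtype machinery: binned single-trait DE, rule-based
# subgroup construction, set decomposition, fold changes, enrichment.

make_cohort <- function(seed = 33, n = 60, p = 200, n_de = 20, shift = 3) {
  set.seed(seed)
  cls <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(p * n, mean = 8), p, n)
  X[seq_len(n_de), cls == 1] <- X[seq_len(n_de), cls == 1] + shift
  em <- make_expr(X)
  clinical <- clinical_table(
    tibble::tibble(
      subject_id = colnames(em),
      GOLD = cls * 2 + 2, # 2 vs 4
      BMI = rnorm(n, 27, 4),
      NOISE = rnorm(n)
    ),
    c(GOLD = "ordinal", BMI = "continuous", NOISE = "continuous")
  )
  list(em = em, clinical = clinical, cls = cls,
       planted = rownames(em)[seq_len(n_de)])
}

test_that("single-trait extremes recover a planted class split", {
  ch <- make_cohort()
  bc <- suppressMessages(single_trait_analysis(
    ch$em, ch$clinical, "GOLD", trait_bins(low_max = 2, high_min = 4),
    fdr_threshold = 0.05, engine = "ttest"
  ))
  expect_s3_class(bc, "binned_comparison")
  expect_identical(sort(c(bc$low_ids, bc$high_ids)), colnames(ch$em))
  expect_true(all(ch$planted %in% called_genes(bc$de)))
  expect_gte(length(intersect(called_genes(bc$de), ch$planted)) / length(ch$planted), 0.95)
})

test_that("single-trait extremes on an unrelated trait stay near the null", {
  # spurious call sets from the automated delta search are rare and tiny;
  # a planted signal produces tens of calls (previous test)
  calls <- integer(10)
  for (s in 1:10) {
    ch <- make_cohort(seed = 100 + s, n_de = 0)
    bc <- suppressMessages(single_trait_analysis(
      ch$em, ch$clinical, "NOISE",
      trait_bins(low_max = stats::quantile(ch$clinical$data$NOISE, 0.25),
                 high_min = stats::quantile(ch$clinical$data$NOISE, 0.75)),
      fdr_threshold = 0.05, engine = "sam",
      sam = sam_params(n_permutations = 60, seed = s)
    ))
    calls[s] <- bc$de$n_called
  }
  expect_gte(sum(calls == 0L), 7L)
  expect_lte(max(calls), 5L)
})

test_that("bin specifications are validated", {
  ch <- make_cohort()
  expect_error(trait_bins(), "cut-points.*level lists")
  expect_error(trait_bins(low_max = 1), "both")
  expect_error(suppressMessages(single_trait_analysis(
    ch$em, ch$clinical, "GOLD", trait_bins(low_max = 4, high_min = 2))),
    "overlapping extremes")
  expect_error(suppressMessages(single_trait_analysis(
    ch$em, ch$clinical, "GOLD", trait_bins(low_max = -5, high_min = 10))),
    "empty extreme")
})

test_that("subtype rules build disjoint groups and catch contradictions", {
  ch <- make_cohort()
  def <- subtype_definition("Group I",
                            a_rule = ~ GOLD >= 4 & BMI < 27,
                            b_rule = "GOLD <= 2 & BMI >= 27",
                            distinctive_trait = "BMI")
  grp <- suppressMessages(build_subtype_groups(ch$clinical, def))
  expect_length(intersect(grp$A, grp$B), 0)
  expect_true(all(lengths(grp) > 0))

  bad <- subtype_definition("Impossible", ~ BMI < 21 & BMI > 30, ~ GOLD <= 2)
  expect_error(suppressMessages(build_subtype_groups(ch$clinical, bad)),
               "side A is empty")

  # four definitions, two sides each: eight groups
  defs <- list(
    subtype_definition("I", ~ GOLD >= 4 & BMI < 27, ~ GOLD <= 2 & BMI >= 27),
    subtype_definition("II", ~ GOLD >= 4 & NOISE < 0, ~ GOLD <= 2 & NOISE >= 0),
    subtype_definition("III", ~ GOLD >= 4 & BMI >= 27, ~ GOLD <= 2 & BMI < 27),
    subtype_definition("IV", ~ GOLD >= 4 & NOISE >= 0, ~ GOLD <= 2 & NOISE < 0)
  )
  groups <- suppressMessages(lapply(defs, build_subtype_groups, clinical = ch$clinical))
  expect_length(unlist(lapply(groups, names)), 8)
})

test_that("venn decomposition does exact set algebra and matches brute force", {
  mk <- function(called_ids, universe) {
    de_result(universe, rep(0, length(universe)), rep(1, length(universe)),
              universe %in% called_ids, "ttest_bh", 0.05)
  }
  uni <- paste0("g", 1:6)
  v <- venn_decompose(list(x = mk(c("g1", "g2", "g3"), uni),
                           y = mk(c("g2", "g3", "g4"), uni)))
  expect_identical(v$unique_sets$x, "g1")
  expect_identical(v$unique_sets$y, "g4")
  expect_identical(v$common, c("g2", "g3"))

  same <- venn_decompose(list(a = mk(c("g1", "g5"), uni), b = mk(c("g1", "g5"), uni)))
  expect_length(unlist(same$unique_sets), 0)
  expect_identical(same$common, c("g1", "g5"))

  set.seed(34)
  uni2 <- sprintf("g%04d", 1:1000)
  results <- lapply(1:4, function(i) mk(sample(uni2, 300), uni2))
  names(results) <- paste0("s", 1:4)
  v2 <- venn_decompose(results)
  # brute force per-gene tally
  for (j in 1:4) {
    in_j <- results[[j]]$gene_ids[results[[j]]$called]
    others <- unlist(lapply(results[-j], called_genes))
    expect_setequal(v2$unique_sets[[j]], setdiff(in_j, others))
  }
  expect_setequal(v2$common, Reduce(intersect, lapply(results, called_genes)))
  # membership-cell counts conserve each subtype's n_called
  for (j in 1:4) {
    cells_j <- v2$cells[substr(v2$cells$pattern, j, j) == "1", ]
    expect_identical(sum(cells_j$count), results[[j]]$n_called)
  }

  ref_genes <- utils::head(v2$common, 3)
  ref <- mk(c(ref_genes, setdiff(uni2, v2$common)[1:5]), uni2)
  v3 <- venn_decompose(results, reference = ref)
  expect_equal(v3$reference_overlap, length(ref_genes) / length(v2$common))

  expect_error(venn_decompose(list(mk("g1", uni), mk("g1", uni2))),
               "same gene universe")
})

test_that("fold-change lists respect the inclusive boundary and swap on reversal", {
  n <- 6
  X <- rbind(
    rep(c(0, 2), each = 3),     # log2 FC exactly +2 -> FC 4
    rep(c(0, 1), each = 3),     # +1 -> FC 2, boundary inclusive
    rep(c(1, 0), each = 3),     # -1 -> FC 0.5
    rep(c(0, 0.3), each = 3),   # +0.3 -> excluded at min_fc 2
    rep(c(0, 0.5), each = 3)    # +0.5 -> excluded
  )
  em <- make_expr(X)
  A <- colnames(em)[1:3]; B <- colnames(em)[4:6]
  de <- de_result(rownames(em), rep(1, 5), rep(0.01, 5), rep(TRUE, 5),
                  "ttest_bh", 0.05)
  fc <- fold_change_genes(em, A, B, min_fc = 2, de_result = de)
  expect_identical(fc$up$gene_id, c("g001", "g002"))
  expect_identical(fc$down$gene_id, "g003")
  expect_equal(fc$up$fc, c(4, 2))
  expect_length(intersect(fc$up$gene_id, fc$down$gene_id), 0)

  rev_fc <- fold_change_genes(em, B, A, min_fc = 2, de_result = de)
  expect_identical(rev_fc$up$gene_id, fc$down$gene_id)
  expect_identical(rev_fc$down$gene_id, fc$up$gene_id)

  # a called gene below the threshold stays out even though significant
  fc15 <- fold_change_genes(em, A, B, min_fc = 1.2, de_result = de)
  expect_true("g005" %in% fc15$up$gene_id)
})

test_that("enrichment reproduces hypergeometric closed forms", {
  uni <- sprintf("u%03d", 1:100)
  sets <- list(PERFECT = uni[1:10], MISS = uni[90:95])
  res <- enrich(uni[1:10], sets, uni)
  expect_equal(res$p_value[res$pathway == "PERFECT"], 1 / choose(100, 10),
               tolerance = 1e-9)
  expect_equal(res$p_value[res$pathway == "MISS"],
               oracle_hyper_upper(0, 6, 100, 10), tolerance = 1e-9)

  # hand fixture: universe 20, query 5, pathway 4, overlap 3
  uni2 <- sprintf("v%02d", 1:20)
  res2 <- enrich(c(uni2[1:3], uni2[10:11]), list(P = uni2[1:4]), uni2)
  expect_equal(res2$p_value, oracle_hyper_upper(3, 4, 20, 5), tolerance = 1e-9)

  # the universe as query is never enriched
  res3 <- enrich(uni, sets, uni)
  expect_true(all(res3$p_value == 1))

  # relabeling genes leaves p-values unchanged
  relab <- setNames(sprintf("w%03d", 1:100), uni)
  res4 <- enrich(unname(relab[uni[1:10]]),
                 lapply(sets, function(s) unname(relab[s])), unname(relab))
  expect_equal(res4$p_value, res$p_value)

  expect_error(enrich(c("zzz"), sets, uni), "outside the universe")
  expect_error(enrich(character(), sets, uni), "non-empty")
})
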
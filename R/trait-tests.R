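#' Two-sided Mann-Whitney U test
#'
#' Exact null distribution when both groups have at most 8 observations and
#' there are no ties; otherwise the normal approximation on midranks with
#' the tie-corrected variance (no continuity correction).
#'
#' @param x,y Numeric vectors (missing values removed), each with at least
#'   one observation.
#' @return Two-sided p-value.
#' @export
#'
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6)) # 0.1
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) abort("each group needs at least one non-missing value")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && length(x) <= 8L && length(y) <= 8L
  res <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact, correct = FALSE)
  )
  unname(res$p.value)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Sums hypergeometric probabilities of tables at most as probable as the
#' observed one (the standard two-sided rule). A table with a zero margin
#' is degenerate and returns p = 1.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return Two-sided p-value.
#' @export
#'
#' @examples
#' fisher_2x2(matrix(c(3, 0, 0, 3), 2)) # 0.1
fisher_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0) || any(tab != round(tab))) {
    abort("`tab` must be a 2x2 matrix of nonnegative integer counts")
  }
  if (sum(tab) == 0) abort("at least one margin must be nonzero")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    inform("2x2 table has a zero margin; returning p = 1")
    return(1)
  }
  unname(fisher.test(tab, alternative = "two.sided")$p.value)
}

#' Test every clinical characteristic on one division
#'
#' For the given division, each characteristic is compared between GROUP1
#' and GROUP2: Mann-Whitney U for continuous and ordinal characteristics,
#' Fisher's exact test for binary ones. Only subjects with observed values
#' enter a test; a characteristic with no observed values in one group is
#' untestable (`significant = NA`) and excluded from the significant set.
#' No multiple-testing correction is applied across characteristics (the
#' raw p <= alpha rule); pass the result through
#' [stats::p.adjust()] yourself if you want one.
#'
#' @param division A `vista_division`, or a bare partition.
#' @param clinical A [clinical_table()] covering the partitioned subjects.
#' @param alpha Significance threshold (inclusive; default 0.05).
#'
#' @return If given a division record, the record with `trait_tests`
#'   (tibble) and `significant_traits` filled in; if given a partition,
#'   the tibble itself. Columns: `trait`, `kind`, `test`, `n1_used`,
#'   `n2_used`, `p_value`, `significant`.
#' @export
test_division <- function(division, clinical, alpha = 0.05) {
  stopifnot(inherits(clinical, "clinical_table"))
  part <- if (inherits(division, "vista_division")) division$partition else division
  stopifnot(inherits(part, "partition"))
  g1 <- group_ids(part, GROUP1)
  g2 <- group_ids(part, GROUP2)
  miss <- setdiff(c(g1, g2), clinical$data$subject_id)
  if (length(miss)) {
    abort(sprintf("division subjects absent from clinical table: %s",
                  paste(head(miss, 5), collapse = ", ")))
  }
  d <- clinical$data
  rows1 <- match(g1, d$subject_id)
  rows2 <- match(g2, d$subject_id)

  out <- purrr::map_dfr(names(clinical$kinds), function(nm) {
    kind <- clinical$kinds[[nm]]
    v1 <- d[[nm]][rows1]
    v2 <- d[[nm]][rows2]
    n1u <- sum(!is.na(v1)); n2u <- sum(!is.na(v2))
    if (n1u == 0L || n2u == 0L) {
      return(tibble(trait = nm, kind = kind,
                    test = if (kind == "binary") "fisher_exact" else "mann_whitney",
                    n1_used = n1u, n2_used = n2u,
                    p_value = NA_real_, significant = NA))
    }
    if (kind == "binary") {
      lev <- levels(d[[nm]])
      tab <- rbind(table(factor(v1, levels = lev)), table(factor(v2, levels = lev)))
      p <- suppressMessages(fisher_2x2(tab))
      test <- "fisher_exact"
    } else {
      p <- mann_whitney(as.numeric(v1), as.numeric(v2))
      test <- "mann_whitney"
    }
    tibble(trait = nm, kind = kind, test = test, n1_used = n1u, n2_used = n2u,
           p_value = p, significant = p <= alpha)
  })

  if (inherits(division, "vista_division")) {
    division$trait_tests <- out
    division$significant_traits <- out$trait[!is.na(out$significant) & out$significant]
    division
  } else {
    out
  }
}

#' Test clinical characteristics on every division of a fit
#'
#' @param fit A `vista_fit` from [vista_drive()].
#' @param clinical A [clinical_table()].
#' @param alpha Significance threshold (inclusive).
#' @return The fit with each division's `trait_tests` and
#'   `significant_traits` filled in.
#' @export
test_divisions <- function(fit, clinical, alpha = 0.05) {
  stopifnot(inherits(fit, "vista_fit"))
  fit$divisions <- purrr::map(fit$divisions, test_division,
                              clinical = clinical, alpha = alpha)
  fit$alpha <- alpha
  fit
}

#' Runs-by-traits significance matrix
#'
#' @param fit A `vista_fit` whose divisions carry trait tests
#'   (see [test_divisions()]), or a list of tested divisions.
#' @return Logical matrix, one row per run, one column per trait;
#'   untestable traits count as not significant.
#' @export
significance_matrix <- function(fit) {
  divisions <- if (inherits(fit, "vista_fit")) fit$divisions else fit
  if (is.null(divisions[[1]]$trait_tests)) {
    abort("divisions carry no trait tests; run test_divisions() first")
  }
  traits <- divisions[[1]]$trait_tests$trait
  out <- t(vapply(divisions, function(d) {
    s <- d$trait_tests$significant
    s[is.na(s)] <- FALSE
    setNames(s, d$trait_tests$trait)[traits]
  }, logical(length(traits))))
  rownames(out) <- vapply(divisions, function(d) as.character(d$run_id), character(1))
  out
}

#' Long tibble of trait tests across all divisions
#'
#' @param fit A tested `vista_fit`.
#' @return Tibble with `run_id` plus the [test_division()] columns.
#' @export
trait_tests_tbl <- function(fit) {
  stopifnot(inherits(fit, "vista_fit"))
  purrr::map_dfr(fit$divisions, function(d) {
    if (is.null(d$trait_tests)) abort("divisions carry no trait tests")
    dplyr::mutate(d$trait_tests, run_id = d$run_id, .before = 1)
  })
}
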
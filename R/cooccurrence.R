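#' Counts of significant traits and trait tuples across runs
#'
#' From a runs-by-traits significance matrix, counts how often each trait
#' — and each pair, triplet and quartet of traits up to `max_order` — is
#' significant in the same division. Tuples are restricted to traits that
#' are significant at least once.
#'
#' @param sig_matrix Logical matrix (runs x traits).
#' @param max_order Largest tuple size, 2 to 4.
#' @return List with `singles` (tibble: trait, k) and `tuples` (tibble:
#'   order, traits (collapsed with "+"), members (list-column), observed).
#' @export
tuple_counts <- function(sig_matrix, max_order = 4L) {
  stopifnot(is.matrix(sig_matrix), is.logical(sig_matrix))
  if (!max_order %in% 2:4) abort("`max_order` must be 2, 3 or 4")
  traits <- colnames(sig_matrix)
  if (is.null(traits)) abort("`sig_matrix` must have trait column names")
  k_c <- colSums(sig_matrix)
  singles <- tibble(trait = traits, k = as.integer(k_c))
  active <- traits[k_c > 0]
  empty <- tibble(order = integer(), traits = character(),
                  members = list(), observed = integer())
  tuples <- purrr::map_dfr(2:max_order, function(ord) {
    if (length(active) < ord) return(empty)
    combos <- combn(active, ord, simplify = FALSE)
    obs <- vapply(combos, function(tr) {
      sum(rowSums(sig_matrix[, tr, drop = FALSE]) == ord)
    }, numeric(1))
    tibble(
      order = ord,
      traits = vapply(combos, paste, character(1), collapse = "+"),
      members = combos,
      observed = as.integer(obs)
    )
  })
  if (!nrow(tuples)) tuples <- empty
  list(singles = singles, tuples = tuples)
}

#' Binomial co-occurrence test
#'
#' Tests whether a tuple of traits is jointly significant across runs more
#' often than expected if the traits occurred independently: under the
#' null, the joint probability is the product of the marginal frequencies
#' `p0 = prod(k_c / R)`, and the p-value is the upper tail
#' `P(Binomial(R, p0) >= k_T)`.
#'
#' @param k_T Observed number of runs where all tuple members are
#'   significant together.
#' @param k_members Integer vector of the members' marginal counts.
#' @param R Total number of runs.
#' @return List with `expected` (`R * p0`) and `p_value`.
#' @export
binomial_cooccurrence_test <- function(k_T, k_members, R) {
  assert_scalar_number(k_T, "k_T", min = 0, max = R)
  if (any(k_members < 0) || any(k_members > R)) {
    abort("member counts must lie in [0, R]")
  }
  p0 <- prod(k_members / R)
  if (p0 == 0) {
    if (k_T > 0) abort("a member with count 0 cannot co-occur; inconsistent input")
    return(list(expected = 0, p_value = 1))
  }
  list(
    expected = R * p0,
    p_value = pbinom(k_T - 1, size = R, prob = p0, lower.tail = FALSE)
  )
}

#' Co-occurrence report over all runs
#'
#' Aggregates the significant-trait sets of all divisions: per-trait
#' frequencies and, for every tuple up to `max_order`, the observed joint
#' count, the count expected under trait independence and the upper-tail
#' binomial p-value. Tuples containing a never-significant trait are
#' skipped (the test is degenerate there). P-values are reported raw, as
#' the number of tested tuples is part of the report.
#'
#' @param fit A tested `vista_fit` (see [test_divisions()]) or a logical
#'   runs-by-traits significance matrix.
#' @param max_order Largest tuple size (2-4, default 4).
#' @return Object of class `cooccurrence_report`: list with `n_runs`,
#'   `singles` (trait, k, fraction) and `tuples` (order, traits, members,
#'   observed, expected, p_value).
#' @export
cooccurrence_report <- function(fit, max_order = 4L) {
  sig <- if (is.matrix(fit)) fit else significance_matrix(fit)
  R <- nrow(sig)
  tc <- tuple_counts(sig, max_order)
  k_by_trait <- setNames(tc$singles$k, tc$singles$trait)
  singles <- dplyr::mutate(tc$singles, fraction = .data$k / R)
  tuples <- tc$tuples
  if (nrow(tuples)) {
    stats <- purrr::map2(tuples$members, tuples$observed, function(mem, obs) {
      binomial_cooccurrence_test(obs, k_by_trait[mem], R)
    })
    tuples$expected <- vapply(stats, `[[`, numeric(1), "expected")
    tuples$p_value <- vapply(stats, `[[`, numeric(1), "p_value")
  } else {
    tuples$expected <- numeric()
    tuples$p_value <- numeric()
  }
  structure(list(n_runs = R, singles = singles, tuples = tuples),
            class = "cooccurrence_report")
}

#' @export
print.cooccurrence_report <- function(x, ...) {
  cat(sprintf("<cooccurrence_report> %d runs, %d traits, %d tuples tested\n",
              x$n_runs, nrow(x$singles), nrow(x$tuples)))
  top <- head(dplyr::arrange(x$singles, dplyr::desc(.data$k)), 5)
  cat("  most frequent traits:",
      paste(sprintf("%s (%d)", top$trait, top$k), collapse = ", "), "\n")
  invisible(x)
}

#' @export
#' @method tidy cooccurrence_report
tidy.cooccurrence_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$singles, order = 1L, traits = .data$trait,
                  observed = .data$k, expected = NA_real_, p_value = NA_real_),
    x$tuples
  ) |>
    dplyr::select("order", "traits", "observed", "expected", "p_value")
}

#' Random-division baseline
#'
#' How often do traits (and their combinations) come out significant for
#' partitions drawn uniformly at random with the same group sizes as the
#' optimized divisions? This quantifies the spurious-association level the
#' shuffling results must beat.
#'
#' @param clinical A [clinical_table()].
#' @param sizes Integer vector `c(n1, n2, nr)` of group sizes.
#' @param n_divisions Number of random divisions (the reference design uses
#'   10,000; scale down for quick checks).
#' @param alpha Trait significance threshold (inclusive).
#' @param max_order Largest tuple size.
#' @param seed Integer seed.
#' @return A `cooccurrence_report` (with `baseline = TRUE` attribute).
#' @export
random_division_baseline <- function(clinical, sizes, n_divisions = 10000L,
                                     alpha = 0.05, max_order = 4L, seed = 1L) {
  stopifnot(inherits(clinical, "clinical_table"))
  sizes <- as.integer(sizes)
  if (length(sizes) != 3L || any(sizes < 0L)) abort("`sizes` must be c(n1, n2, nr)")
  ids <- clinical$data$subject_id
  if (sum(sizes) != length(ids)) {
    abort(sprintf("sizes sum to %d but clinical table has %d subjects",
                  sum(sizes), length(ids)))
  }
  assert_scalar_number(n_divisions, "n_divisions", min = 1)
  lab <- rep(c(GROUP1, GROUP2, RESERVOIR), times = sizes)
  sig <- local_seed(seed, {
    t(vapply(seq_len(n_divisions), function(i) {
      part <- new_partition(setNames(sample(lab), ids))
      tt <- test_division(part, clinical, alpha = alpha)
      s <- tt$significant
      s[is.na(s)] <- FALSE
      setNames(s, tt$trait)
    }, logical(length(clinical$kinds))))
  })
  rep <- cooccurrence_report(sig, max_order = max_order)
  attr(rep, "baseline") <- TRUE
  rep
}

#' Plot per-trait significance frequencies
#'
#' Bar chart of how often each trait separates the two optimized groups,
#' optionally against the random-division baseline.
#'
#' @param report A `cooccurrence_report` from the optimized runs.
#' @param baseline Optional baseline `cooccurrence_report`.
#' @return A ggplot object.
#' @export
plot_trait_frequency <- function(report, baseline = NULL) {
  stopifnot(inherits(report, "cooccurrence_report"))
  df <- dplyr::mutate(report$singles, source = "optimized divisions")
  if (!is.null(baseline)) {
    df <- dplyr::bind_rows(
      df, dplyr::mutate(baseline$singles, source = "random divisions")
    )
  }
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$trait, -.data$fraction),
    y = .data$fraction, fill = .data$source
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "fraction of divisions significant", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
#' @method autoplot cooccurrence_report
autoplot.cooccurrence_report <- function(object, ...) {
  plot_trait_frequency(object)
}
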
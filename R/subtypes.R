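#' Bin specification for a single-trait extreme comparison
#'
#' Defines the low- and high-extreme bins of a clinical characteristic.
#' For numeric traits give cut-points (`low_max`, `high_min`, both
#' inclusive); for binary/categorical traits give explicit level lists.
#'
#' @param low_max Subjects with trait value <= `low_max` form the low extreme.
#' @param high_min Subjects with trait value >= `high_min` form the high extreme.
#' @param low_levels,high_levels Category lists defining the extremes.
#' @return A list of class `trait_bins`.
#' @export
trait_bins <- function(low_max = NULL, high_min = NULL,
                       low_levels = NULL, high_levels = NULL) {
  numeric_spec <- !is.null(low_max) || !is.null(high_min)
  level_spec <- !is.null(low_levels) || !is.null(high_levels)
  if (numeric_spec == level_spec) {
    abort("give either cut-points (low_max & high_min) or level lists (low_levels & high_levels)")
  }
  if (numeric_spec && (is.null(low_max) || is.null(high_min))) {
    abort("both `low_max` and `high_min` are required for a numeric bin spec")
  }
  if (level_spec && (is.null(low_levels) || is.null(high_levels))) {
    abort("both `low_levels` and `high_levels` are required for a level bin spec")
  }
  structure(list(low_max = low_max, high_min = high_min,
                 low_levels = low_levels, high_levels = high_levels),
            class = "trait_bins")
}

resolve_bins <- function(clinical, trait, bins) {
  stopifnot(inherits(bins, "trait_bins"))
  if (!trait %in% names(clinical$kinds)) {
    abort(sprintf("trait '%s' not declared in clinical table", trait))
  }
  v <- clinical$data[[trait]]
  ids <- clinical$data$subject_id
  if (!is.null(bins$low_max)) {
    vn <- as.numeric(v)
    low <- ids[!is.na(vn) & vn <= bins$low_max]
    high <- ids[!is.na(vn) & vn >= bins$high_min]
  } else {
    vc <- as.character(v)
    low <- ids[!is.na(vc) & vc %in% as.character(bins$low_levels)]
    high <- ids[!is.na(vc) & vc %in% as.character(bins$high_levels)]
  }
  if (!length(low) || !length(high)) {
    abort(sprintf("bins for trait '%s' produce an empty extreme", trait))
  }
  if (length(intersect(low, high))) {
    abort(sprintf("bins for trait '%s' produce overlapping extremes", trait))
  }
  list(low = low, high = high)
}

#' Differential expression between the extremes of one clinical trait
#'
#' The forward analysis: split subjects into low and high extremes of a
#' single characteristic by clinically motivated cut-points and count
#' differentially expressed genes between the extremes.
#'
#' @param expr An [expression_matrix()].
#' @param clinical A [clinical_table()].
#' @param trait Characteristic name.
#' @param bins A [trait_bins()] specification.
#' @param fdr_threshold FDR cutoff (reporting convention: 0.05).
#' @param engine `"sam"` (default) or `"ttest"`.
#' @param sam Optional [sam_params()] overriding the defaults when
#'   `engine = "sam"` (its `fdr_threshold` is superseded by the argument).
#'
#' @return Object of class `binned_comparison`: `trait`, `low_ids`,
#'   `high_ids`, `bins`, `de` (a [de_result()]).
#' @export
single_trait_analysis <- function(expr, clinical, trait, bins,
                                  fdr_threshold = 0.05,
                                  engine = c("sam", "ttest"),
                                  sam = NULL) {
  engine <- match.arg(engine)
  check_subject_alignment(expr, clinical)
  b <- resolve_bins(clinical, trait, bins)
  low <- intersect(b$low, colnames(expr))
  high <- intersect(b$high, colnames(expr))
  if (length(low) < 2L || length(high) < 2L) {
    abort(sprintf("trait '%s': each extreme needs >= 2 subjects with expression (got %d and %d)",
                  trait, length(low), length(high)))
  }
  de <- if (engine == "sam") {
    sp <- sam %||% sam_params()
    sp$fdr_threshold <- fdr_threshold
    sam_count_de(expr, low, high, params = sp)
  } else {
    ttest_count_de(expr, low, high, fdr_threshold = fdr_threshold)
  }
  structure(list(trait = trait, low_ids = low, high_ids = high,
                 bins = bins, de = de),
            class = "binned_comparison")
}

#' @export
print.binned_comparison <- function(x, ...) {
  cat(sprintf("<binned_comparison> '%s': %d (low) vs %d (high) subjects, %d DE genes at FDR <= %.3g\n",
              x$trait, length(x$low_ids), length(x$high_ids),
              x$de$n_called, x$de$fdr_threshold))
  invisible(x)
}

#' Subtype definition
#'
#' A candidate subtype combines a disease-severity core with one
#' distinctive characteristic; its A and B sides are rule-based subject
#' selections. Rules are R expressions over clinical columns, given as
#' strings or one-sided formulas, e.g. `~ GOLDCD >= 3 & BMI < 21`.
#'
#' @param name Subtype label (e.g. `"Group I"`).
#' @param a_rule,b_rule Membership rules for the two sides.
#' @param core_traits Optional character vector of core trait names
#'   (bookkeeping only).
#' @param distinctive_trait Optional distinctive trait name (bookkeeping).
#' @return A list of class `subtype_definition`.
#' @export
subtype_definition <- function(name, a_rule, b_rule,
                               core_traits = character(), distinctive_trait = NULL) {
  as_expr <- function(r, which) {
    if (inherits(r, "formula")) return(r[[length(r)]])
    if (is.character(r) && length(r) == 1L) return(str2lang(r))
    abort(sprintf("`%s` must be a one-sided formula or a string expression", which))
  }
  structure(list(
    name = name,
    a_rule = as_expr(a_rule, "a_rule"),
    b_rule = as_expr(b_rule, "b_rule"),
    core_traits = core_traits,
    distinctive_trait = distinctive_trait
  ), class = "subtype_definition")
}

eval_rule <- function(rule, data, name, side) {
  sel <- tryCatch(
    eval(rule, envir = data, enclos = baseenv()),
    error = function(e) abort(sprintf("subtype '%s' %s rule failed: %s",
                                      name, side, conditionMessage(e)))
  )
  if (!is.logical(sel) || length(sel) != nrow(data)) {
    abort(sprintf("subtype '%s' %s rule must evaluate to one logical per subject", name, side))
  }
  sel & !is.na(sel)
}

#' Build the A/B subject sets of a subtype
#'
#' @param clinical A [clinical_table()].
#' @param definition A [subtype_definition()].
#' @return List with `A` and `B` (character vectors of subject ids,
#'   disjoint, both non-empty).
#' @export
build_subtype_groups <- function(clinical, definition) {
  stopifnot(inherits(clinical, "clinical_table"),
            inherits(definition, "subtype_definition"))
  d <- clinical$data
  selA <- eval_rule(definition$a_rule, d, definition$name, "A")
  selB <- eval_rule(definition$b_rule, d, definition$name, "B")
  A <- d$subject_id[selA]
  B <- d$subject_id[selB]
  if (!length(A)) {
    abort(sprintf("subtype '%s' side A is empty (rule: %s)",
                  definition$name, deparse1(definition$a_rule)))
  }
  if (!length(B)) {
    abort(sprintf("subtype '%s' side B is empty (rule: %s)",
                  definition$name, deparse1(definition$b_rule)))
  }
  both <- intersect(A, B)
  if (length(both)) {
    abort(sprintf("subtype '%s': sides A and B overlap (%d subjects)",
                  definition$name, length(both)))
  }
  inform(sprintf("subtype '%s': |A| = %d, |B| = %d", definition$name,
                 length(A), length(B)))
  list(A = A, B = B)
}

#' Decompose called gene sets across subtypes
#'
#' Given the differential expression results of several subtypes over the
#' same gene universe, reports the genes called in exactly one subtype
#' (unique sets), the genes called in all (common core), every membership
#' cell of the Venn diagram, and — if a reference comparison is supplied —
#' the fraction of the common core also called in the reference.
#'
#' @param results Named list of two or more [de_result()] objects sharing
#'   one gene universe.
#' @param reference Optional [de_result()] (e.g. the severity-extremes
#'   comparison) to overlap the common core against.
#' @return Object of class `venn_decomposition`: `unique_sets` (named list),
#'   `common` (character), `cells` (tibble: pattern, n_subtypes, count),
#'   `reference_overlap` (fraction or `NA`), `membership` (logical matrix).
#' @export
venn_decompose <- function(results, reference = NULL) {
  if (length(results) < 2L) abort("need at least two de_result objects")
  if (is.null(names(results)) || any(!nzchar(names(results)))) {
    names(results) <- paste0("set", seq_along(results))
  }
  universe <- results[[1]]$gene_ids
  for (r in results) {
    stopifnot(inherits(r, "de_result"))
    if (!identical(sort(r$gene_ids), sort(universe))) {
      abort("all de_result objects must share the same gene universe")
    }
  }
  membership <- vapply(results, function(r) {
    setNames(r$called, r$gene_ids)[universe]
  }, logical(length(universe)))
  rownames(membership) <- universe

  n_in <- rowSums(membership)
  k <- ncol(membership)
  unique_sets <- lapply(seq_len(k), function(j) {
    universe[membership[, j] & n_in == 1L]
  })
  names(unique_sets) <- colnames(membership)
  common <- universe[n_in == k]

  pattern <- apply(membership, 1L, function(z) paste(as.integer(z), collapse = ""))
  cells <- tibble(pattern = pattern, n_subtypes = n_in) |>
    dplyr::count(.data$pattern, .data$n_subtypes, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$n_subtypes), .data$pattern)

  reference_overlap <- NA_real_
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "de_result"))
    if (!identical(sort(reference$gene_ids), sort(universe))) {
      abort("`reference` must share the gene universe")
    }
    if (length(common)) {
      reference_overlap <- length(intersect(common, called_genes(reference))) / length(common)
    }
  }

  structure(list(unique_sets = unique_sets, common = common, cells = cells,
                 reference_overlap = reference_overlap, membership = membership),
            class = "venn_decomposition")
}

#' @export
print.venn_decomposition <- function(x, ...) {
  cat(sprintf("<venn_decomposition> %d sets over %d genes\n",
              ncol(x$membership), nrow(x$membership)))
  cat("  unique:", paste(sprintf("%s = %d", names(x$unique_sets),
                                 lengths(x$unique_sets)), collapse = ", "), "\n")
  cat(sprintf("  common to all: %d\n", length(x$common)))
  if (!is.na(x$reference_overlap)) {
    cat(sprintf("  common-set overlap with reference: %.1f%%\n",
                100 * x$reference_overlap))
  }
  invisible(x)
}

#' @export
#' @method tidy venn_decomposition
tidy.venn_decomposition <- function(x, ...) x$cells

#' Fold-change gene lists
#'
#' For log2-scale expression, the fold change of the B side over the A side
#' is `2^(meanB - meanA)` (a geometric-mean ratio). Among the genes called
#' in `de_result`, reports those with FC at or above `min_fc` (up in B) and
#' those at or below `1/min_fc` (down in B), sorted by absolute log2 FC.
#'
#' @param expr An [expression_matrix()].
#' @param A,B Subject id vectors of the two sides.
#' @param min_fc Fold-change cutoff, >= 1 (boundary inclusive; default 2).
#' @param de_result The [de_result()] computed on (A, B).
#' @return List with tibbles `up` and `down` (gene_id, log2_fc, fc, q_value).
#' @export
fold_change_genes <- function(expr, A, B, min_fc = 2, de_result) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(de_result, "de_result"))
  assert_scalar_number(min_fc, "min_fc", min = 1)
  idx <- resolve_groups(expr, A, B)
  lfc <- rowMeans(unclass(expr)[, idx$i2, drop = FALSE]) -
    rowMeans(unclass(expr)[, idx$i1, drop = FALSE])
  tab <- tidy(de_result) |>
    dplyr::mutate(log2_fc = unname(lfc[.data$gene_id]), fc = 2^.data$log2_fc)
  called <- dplyr::filter(tab, .data$called)
  up <- dplyr::filter(called, .data$fc >= min_fc) |>
    dplyr::arrange(dplyr::desc(abs(.data$log2_fc)))
  down <- dplyr::filter(called, .data$fc <= 1 / min_fc) |>
    dplyr::arrange(dplyr::desc(abs(.data$log2_fc)))
  keep <- c("gene_id", "log2_fc", "fc", "q_value")
  list(up = up[keep], down = down[keep])
}

#' Gene-set over-representation analysis
#'
#' One-sided Fisher's exact test (hypergeometric upper tail) of the overlap
#' between a query gene list and each pathway, within a fixed gene
#' universe. Pathways are clipped to the universe before testing; p-values
#' are reported raw with a Benjamini-Hochberg column alongside.
#'
#' @param query Character vector of genes (must lie in `universe`).
#' @param sets A [read_gmt()] collection (or named list of gene id vectors).
#' @param universe Character vector: all genes eligible for the query
#'   (conventionally every gene on the expression matrix).
#' @param two_sided If `TRUE`, use the two-sided Fisher test instead of the
#'   over-representation tail.
#' @return Tibble sorted by p-value: `pathway`, `overlap`, `pathway_size`,
#'   `query_size`, `universe_size`, `p_value`, `p_adjust`.
#' @export
enrich <- function(query, sets, universe, two_sided = FALSE) {
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  stopifnot(is.list(sets), !is.null(names(sets)))
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  if (!length(universe)) abort("`universe` must be non-empty")
  if (!length(query)) abort("`query` must be non-empty")
  out <- setdiff(query, universe)
  if (length(out)) {
    abort(sprintf("query genes outside the universe: %s",
                  paste(head(out, 5), collapse = ", ")))
  }
  U <- length(universe); q <- length(query)
  res <- purrr::imap_dfr(sets, function(genes, nm) {
    pw <- intersect(unique(genes), universe)
    m <- length(pw)
    ov <- length(intersect(query, pw))
    p <- if (m == 0L) {
      1
    } else if (two_sided) {
      fisher_2x2(matrix(c(ov, q - ov, m - ov, U - q - m + ov), 2))
    } else {
      phyper(ov - 1, m, U - m, q, lower.tail = FALSE)
    }
    tibble(pathway = nm, overlap = ov, pathway_size = m,
           query_size = q, universe_size = U, p_value = p)
  })
  res$p_adjust <- p.adjust(res$p_value, method = "BH")
  dplyr::arrange(res, .data$p_value, .data$pathway)
}
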
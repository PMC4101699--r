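#' Construct a validated expression matrix
#'
#' The substrate of every differential-expression computation: a numeric
#' genes-by-subjects matrix of log2-scale expression values. Values are
#' assumed already normalized and log2-transformed; this package never
#' transforms expression data, it only checks it.
#'
#' @param values Numeric matrix, genes in rows, subjects in columns.
#' @param gene_ids Character vector of unique gene identifiers
#'   (default: `rownames(values)`).
#' @param subject_ids Character vector of unique subject identifiers
#'   (default: `colnames(values)`).
#'
#' @return A numeric matrix of class `expression_matrix` with gene ids as
#'   row names and subject ids as column names.
#' @export
#'
#' @examples
#' em <- expression_matrix(matrix(rnorm(12), 3, 4,
#'   dimnames = list(paste0("g", 1:3), paste0("s", 1:4))))
#' dim(em)
expression_matrix <- function(values, gene_ids = rownames(values),
                              subject_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x subjects)")
  }
  if (is.null(gene_ids) || is.null(subject_ids)) {
    abort("gene and subject ids are required (as dimnames or explicit arguments)")
  }
  gene_ids <- as.character(gene_ids)
  subject_ids <- as.character(subject_ids)
  if (length(gene_ids) != nrow(values)) {
    abort("length of `gene_ids` must equal nrow(values)")
  }
  if (length(subject_ids) != ncol(values)) {
    abort("length of `subject_ids` must equal ncol(values)")
  }
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) {
    abort(sprintf("duplicate gene ids: %s", paste(head(dup_g, 5), collapse = ", ")))
  }
  dup_s <- unique(subject_ids[duplicated(subject_ids)])
  if (length(dup_s)) {
    abort(sprintf("duplicate subject ids: %s", paste(head(dup_s, 5), collapse = ", ")))
  }
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf(
      "non-finite or missing expression value at gene '%s', subject '%s'",
      gene_ids[bad[1, 1]], subject_ids[bad[1, 2]]
    ))
  }
  dimnames(values) <- list(gene_ids, subject_ids)
  class(values) <- c("expression_matrix", class(values))
  values
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "<expression_matrix> %d genes x %d subjects (log2 scale)\n",
    nrow(x), ncol(x)
  ))
  invisible(x)
}

#' Read an expression matrix from TSV or GCT
#'
#' TSV layout: a header row of subject ids and a first column of gene ids.
#' GCT layout: the standard two header lines (`#1.2`, then dimensions)
#' followed by `Name`, `Description` and one column per subject; the
#' Description column is dropped.
#'
#' Missing or non-numeric cells are a hard error naming the offending gene
#' and subject: the shuffling objective requires a complete matrix and no
#' imputation rule is assumed.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (default) or `"gct"`.
#'
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, dialect = c("tsv", "gct")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (dialect == "gct") {
    header <- readLines(path, n = 2L)
    if (length(header) < 2L || !startsWith(header[1], "#1.2")) {
      abort("not a GCT file: expected '#1.2' on the first line")
    }
    raw <- readr::read_tsv(path, skip = 2L, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    if (ncol(raw) < 3L) abort("GCT file must have Name, Description and data columns")
    gene_ids <- raw[[1]]
    raw <- raw[, -c(1L, 2L), drop = FALSE]
  } else {
    raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    if (ncol(raw) < 2L) abort("expression TSV must have a gene id column and data columns")
    gene_ids <- raw[[1]]
    raw <- raw[, -1L, drop = FALSE]
  }
  subject_ids <- colnames(raw)
  values <- matrix(NA_real_, nrow = length(gene_ids), ncol = length(subject_ids))
  for (j in seq_along(subject_ids)) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      abort(sprintf(
        "non-numeric or missing expression value for gene '%s', subject '%s'",
        gene_ids[bad[1]], subject_ids[j]
      ))
    }
    values[, j] <- v
  }
  em <- expression_matrix(values, gene_ids, subject_ids)
  inform(sprintf("read expression matrix: %d genes x %d subjects", nrow(em), ncol(em)))
  em
}

#' Write an expression matrix as TSV
#'
#' @param x An [expression_matrix()].
#' @param path Output path; first column `gene_id`, then one column per subject.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- tibble::as_tibble(as.data.frame(unclass(x)), rownames = "gene_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

# Check that every expression subject appears in the clinical table.
# Mismatches are a hard error, never a silent drop.
check_subject_alignment <- function(expr, clinical) {
  missing <- setdiff(colnames(expr), clinical$data$subject_id)
  if (length(missing)) {
    abort(sprintf(
      "subjects present in expression but absent from clinical table: %s",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  invisible(TRUE)
}
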
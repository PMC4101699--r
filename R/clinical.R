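#' Construct a typed clinical table
#'
#' Subjects by clinical characteristics, each declared `continuous`,
#' `binary` or `ordinal`. Continuous and ordinal characteristics are stored
#' as numeric (ordinal as integer level codes); binary characteristics keep
#' their two observed levels as a factor. Missing values are allowed and
#' are simply excluded from any group comparison that uses the trait.
#'
#' @param data A data frame with a `subject_id` column (unique) plus one
#'   column per characteristic.
#' @param kinds Named character vector mapping characteristic name to one of
#'   `"continuous"`, `"binary"`, `"ordinal"`. Columns of `data` not named
#'   here are dropped with a warning.
#'
#' @return An object of class `clinical_table`: a list with `data` (tibble)
#'   and `kinds` (named character vector).
#' @export
clinical_table <- function(data, kinds) {
  data <- tibble::as_tibble(data)
  if (!"subject_id" %in% names(data)) {
    abort("`data` must contain a `subject_id` column")
  }
  data$subject_id <- as.character(data$subject_id)
  if (anyDuplicated(data$subject_id)) abort("duplicate subject ids in clinical table")
  if (is.null(names(kinds)) || any(!nzchar(names(kinds)))) {
    abort("`kinds` must be a named vector")
  }
  bad_kind <- setdiff(unique(kinds), c("continuous", "binary", "ordinal"))
  if (length(bad_kind)) {
    abort(sprintf("unknown characteristic kind(s): %s", paste(bad_kind, collapse = ", ")))
  }
  absent <- setdiff(names(kinds), names(data))
  if (length(absent)) {
    abort(sprintf("declared characteristics missing from data: %s",
                  paste(absent, collapse = ", ")))
  }
  extra <- setdiff(names(data), c("subject_id", names(kinds)))
  if (length(extra)) {
    warn(sprintf("ignoring undeclared columns: %s", paste(extra, collapse = ", ")))
  }
  out <- data[c("subject_id", names(kinds))]
  for (nm in names(kinds)) {
    v <- out[[nm]]
    if (kinds[[nm]] == "binary") {
      f <- factor(v)
      lev <- levels(droplevels(f[!is.na(f)]))
      if (length(lev) > 2L) {
        abort(sprintf("binary characteristic '%s' has %d observed levels: %s",
                      nm, length(lev), paste(lev, collapse = ", ")))
      }
      out[[nm]] <- factor(v, levels = lev)
    } else if (kinds[[nm]] == "ordinal") {
      if (is.numeric(v)) {
        out[[nm]] <- as.numeric(v)
      } else {
        out[[nm]] <- as.numeric(factor(v, levels = sort(unique(v[!is.na(v)]))))
      }
    } else {
      vn <- suppressWarnings(as.numeric(v))
      if (any(is.na(vn) & !is.na(v))) {
        abort(sprintf("continuous characteristic '%s' has non-numeric values", nm))
      }
      out[[nm]] <- vn
    }
  }
  structure(list(data = out, kinds = kinds[names(kinds)]), class = "clinical_table")
}

#' @export
print.clinical_table <- function(x, ...) {
  cat(sprintf("<clinical_table> %d subjects, %d characteristics\n",
              nrow(x$data), length(x$kinds)))
  k <- table(factor(x$kinds, levels = c("continuous", "binary", "ordinal")))
  cat(sprintf("  continuous: %d  binary: %d  ordinal: %d\n", k[1], k[2], k[3]))
  invisible(x)
}

#' @export
#' @method tidy clinical_table
tidy.clinical_table <- function(x, ...) {
  tidyr::pivot_longer(
    dplyr::mutate(x$data, dplyr::across(-"subject_id", as.character)),
    -"subject_id", names_to = "trait", values_to = "value"
  ) |>
    dplyr::mutate(kind = unname(x$kinds[.data$trait]))
}

#' Read a clinical table from CSV with a schema
#'
#' @param path CSV path; must contain a subject id column.
#' @param schema Either a named character vector / named list of kinds
#'   (`continuous`, `binary`, `ordinal`) per column, or the path to a YAML
#'   file mapping column names to kinds.
#' @param id_col Name of the subject id column (default `"subject_id"`).
#'
#' @return A [clinical_table()].
#' @export
read_clinical <- function(path, schema, id_col = "subject_id") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (is.character(schema) && length(schema) == 1L && is.null(names(schema)) &&
      file.exists(schema)) {
    schema <- yaml::read_yaml(schema)
  }
  kinds <- vapply(schema, as.character, character(1))
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"), progress = FALSE)
  if (!id_col %in% names(df)) {
    abort(sprintf("clinical CSV lacks subject id column '%s'", id_col))
  }
  names(df)[names(df) == id_col] <- "subject_id"
  for (nm in names(kinds)) {
    if (!nm %in% names(df)) next
    if (kinds[[nm]] %in% c("continuous", "ordinal")) {
      v <- suppressWarnings(as.numeric(df[[nm]]))
      if (!any(is.na(v) & !is.na(df[[nm]]))) df[[nm]] <- v
    }
  }
  clinical_table(df, kinds)
}

#' Write a clinical table (CSV plus YAML schema sidecar)
#'
#' @param x A [clinical_table()].
#' @param path Output CSV path.
#' @param schema_path Output YAML schema path (default: `path` with
#'   `.schema.yaml` appended).
#' @return `path`, invisibly.
#' @export
write_clinical <- function(x, path, schema_path = paste0(path, ".schema.yaml")) {
  stopifnot(inherits(x, "clinical_table"))
  readr::write_csv(x$data, path, progress = FALSE, na = "")
  yaml::write_yaml(as.list(x$kinds), schema_path)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' One set per line: set name, description, then member gene ids, all
#' tab-separated. Duplicate genes within a line are deduplicated.
#'
#' @param path GMT file path.
#' @return An object of class `gene_set_collection`: list with `sets`
#'   (named list of character vectors) and `source_label`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("no gene sets: GMT file is empty")
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      abort(sprintf("GMT line %d has %d field(s); need name, description and >= 1 gene",
                    i, length(fields)))
    }
    nm <- fields[1]
    if (nm %in% names(sets)) abort(sprintf("duplicate gene set name '%s' (line %d)", nm, i))
    sets[[nm]] <- unique(fields[-c(1L, 2L)])
  }
  structure(list(sets = sets, source_label = basename(path)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat(sprintf("<gene_set_collection> %d sets from '%s' (sizes %d-%d)\n",
              length(x$sets), x$source_label, min(sizes), max(sizes)))
  invisible(x)
}
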
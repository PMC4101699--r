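# Partition of subjects into GROUP1 / GROUP2 / RESERVOIR, stored as a
# named integer vector (1, 2, 3). Sizes are fixed for the lifetime of a run.

GROUP1 <- 1L
GROUP2 <- 2L
RESERVOIR <- 3L

new_partition <- function(assignment) {
  stopifnot(is.integer(assignment), !is.null(names(assignment)),
            all(assignment %in% c(GROUP1, GROUP2, RESERVOIR)))
  structure(assignment, class = "partition")
}

#' Coerce labels to a partition
#'
#' @param x Named vector (names = subject ids) with values `"GROUP1"`,
#'   `"GROUP2"`, `"RESERVOIR"` or 1, 2, 3.
#' @return A partition usable with [test_division()], [propose_swap()] etc.
#' @export
#'
#' @examples
#' as_partition(c(a = "GROUP1", b = "GROUP1", c = "GROUP2", d = "GROUP2"))
as_partition <- function(x) {
  if (is.null(names(x))) abort("`x` must be named by subject id")
  if (is.character(x) || is.factor(x)) {
    code <- match(toupper(as.character(x)), c("GROUP1", "GROUP2", "RESERVOIR"))
  } else {
    code <- as.integer(x)
    code[!code %in% 1:3] <- NA_integer_
  }
  if (anyNA(code)) abort("labels must be GROUP1/GROUP2/RESERVOIR or 1/2/3")
  new_partition(setNames(code, names(x)))
}

#' Subjects assigned to one group of a partition
#'
#' @param partition A partition as produced by [initial_partition()].
#' @param group 1 (GROUP1), 2 (GROUP2) or 3 (RESERVOIR).
#' @return Character vector of subject ids.
#' @export
group_ids <- function(partition, group) {
  names(partition)[unclass(partition) == group]
}

#' Sizes of the three partition groups
#'
#' @param partition A partition.
#' @return Named integer vector `c(n1 = , n2 = , nr = )`.
#' @export
partition_sizes <- function(partition) {
  a <- unclass(partition)
  c(n1 = sum(a == GROUP1), n2 = sum(a == GROUP2), nr = sum(a == RESERVOIR))
}

#' @export
print.partition <- function(x, ...) {
  s <- partition_sizes(x)
  cat(sprintf("<partition> GROUP1: %d, GROUP2: %d, RESERVOIR: %d\n",
              s["n1"], s["n2"], s["nr"]))
  invisible(x)
}

#' @export
#' @method tidy partition
tidy.partition <- function(x, ...) {
  tibble(
    subject_id = names(x),
    group = c("GROUP1", "GROUP2", "RESERVOIR")[unclass(x)]
  )
}

#' Random initial partition
#'
#' Subjects are split into GROUP1, GROUP2 and a RESERVOIR of
#' `reservoir_size` subjects; the two comparison groups take
#' `floor((n - nr) / 2)` and the remainder. Draws from the current RNG
#' state (the optimizer seeds it per run).
#'
#' @param subject_ids Character vector of subject ids.
#' @param reservoir_size Number of reservoir subjects (0 for two-group mode).
#' @return A partition.
#' @export
initial_partition <- function(subject_ids, reservoir_size) {
  subject_ids <- as.character(subject_ids)
  n <- length(subject_ids)
  nr <- as.integer(reservoir_size)
  if (nr < 0L) abort("`reservoir_size` must be nonnegative")
  if (n < 4L + nr) {
    abort(sprintf("need at least %d subjects for reservoir_size = %d (got %d)",
                  4L + nr, nr, n))
  }
  n1 <- (n - nr) %/% 2L
  n2 <- n - nr - n1
  lab <- rep(c(GROUP1, GROUP2, RESERVOIR), times = c(n1, n2, nr))
  new_partition(setNames(sample(lab), subject_ids))
}

#' Propose a random swap
#'
#' With a reservoir: a uniformly chosen member of GROUP1 or GROUP2 trades
#' places with a uniformly chosen reservoir subject (the incomer takes the
#' outgoer's group). Without a reservoir (two-group mode), one member of
#' each comparison group exchange groups. Sizes are always preserved.
#'
#' @param partition A partition.
#' @return List with `candidate` (the new partition), `subject_out` and
#'   `subject_in`.
#' @export
propose_swap <- function(partition) {
  a <- unclass(partition)
  res <- names(a)[a == RESERVOIR]
  if (length(res)) {
    pool <- names(a)[a != RESERVOIR]
    out <- pool[sample.int(length(pool), 1L)]
    inc <- res[sample.int(length(res), 1L)]
    a[inc] <- a[out]
    a[out] <- RESERVOIR
  } else {
    g1 <- names(a)[a == GROUP1]
    g2 <- names(a)[a == GROUP2]
    if (!length(g1) || !length(g2)) {
      abort("empty reservoir and an empty comparison group; two-group mode needs both groups non-empty")
    }
    out <- g1[sample.int(length(g1), 1L)]
    inc <- g2[sample.int(length(g2), 1L)]
    a[out] <- GROUP2
    a[inc] <- GROUP1
  }
  list(candidate = new_partition(a), subject_out = out, subject_in = inc)
}

#' Best-matching overlap between a partition and reference class labels
#'
#' Restricted to subjects in GROUP1 and GROUP2, the fraction assigned
#' consistently with a two-class reference labeling, maximized over the two
#' possible label pairings. 1 means the comparison groups reproduce the
#' reference classes exactly; 0.5 is chance level for balanced classes.
#'
#' @param partition A partition.
#' @param classes Named vector (subject id -> class label) with two levels.
#' @return A number in \[0, 1\].
#' @export
partition_overlap <- function(partition, classes) {
  ids <- c(group_ids(partition, GROUP1), group_ids(partition, GROUP2))
  miss <- setdiff(ids, names(classes))
  if (length(miss)) abort("reference classes missing for some partitioned subjects")
  g <- unclass(partition)[ids]
  cl <- as.integer(factor(classes[ids]))
  if (length(unique(cl)) > 2L) abort("`classes` must have at most two levels")
  agree <- mean((g == GROUP1) == (cl == 1L))
  max(agree, 1 - agree)
}
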
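#' Optimizer parameters
#'
#' Settings for the divisive shuffling search. Defaults mirror the design
#' the method was introduced with: a reservoir of 40 subjects, 2,000
#' attempted swaps per run, 500 independent runs, and a permissive SAM FDR
#' cutoff of 0.1 as the objective.
#'
#' @param reservoir_size Reservoir size (0 enables two-group mode, where
#'   swaps exchange members between GROUP1 and GROUP2).
#' @param max_attempts Attempted swaps per run.
#' @param plateau_window If set, a run stops early once this many
#'   consecutive attempts yield no acceptance (default off: the plateau
#'   criterion is informal, a fixed budget is reproducible).
#' @param n_runs Number of independent restarts.
#' @param seed Master seed; per-run seeds are derived from it.
#' @param engine Objective engine: `"sam"`, `"ttest"`, or a function
#'   `function(expr, group1, group2)` returning a count (used for contract
#'   testing and custom objectives).
#' @param fdr_threshold FDR cutoff of the objective.
#' @param n_permutations SAM permutations inside the optimizer (default 100
#'   for speed; use more for final reported results).
#' @param accept_ties Accept swaps that leave the count unchanged
#'   (default `FALSE`: strict increase).
#'
#' @return A list of class `vista_params`.
#' @export
vista_params <- function(reservoir_size = 40L,
                         max_attempts = 2000L,
                         plateau_window = NULL,
                         n_runs = 500L,
                         seed = 1L,
                         engine = "sam",
                         fdr_threshold = 0.1,
                         n_permutations = 100L,
                         accept_ties = FALSE) {
  assert_scalar_number(reservoir_size, "reservoir_size", min = 0)
  assert_scalar_number(max_attempts, "max_attempts", min = 1)
  assert_scalar_number(n_runs, "n_runs", min = 1)
  if (!is.null(plateau_window)) assert_scalar_number(plateau_window, "plateau_window", min = 1)
  if (!is.function(engine) && !engine %in% c("sam", "ttest")) {
    abort("`engine` must be 'sam', 'ttest', or a function(expr, group1, group2)")
  }
  structure(list(
    reservoir_size = as.integer(reservoir_size),
    max_attempts = as.integer(max_attempts),
    plateau_window = if (is.null(plateau_window)) NULL else as.integer(plateau_window),
    n_runs = as.integer(n_runs),
    seed = as.integer(seed),
    engine = engine,
    fdr_threshold = fdr_threshold,
    n_permutations = as.integer(n_permutations),
    accept_ties = isTRUE(accept_ties)
  ), class = "vista_params")
}

# Build the objective closure: partition -> integer DE count.
# For the SAM engine the permutation assignment set is generated once per
# run and reused for every evaluation, so the objective is a deterministic
# function of the partition and accept/reject comparisons are coherent.
make_objective <- function(expr, params, run_seed, n1, n2) {
  if (is.function(params$engine)) {
    eng <- params$engine
    return(function(part) eng(expr, group_ids(part, GROUP1), group_ids(part, GROUP2)))
  }
  if (params$engine == "ttest") {
    return(function(part) {
      suppressMessages(
        ttest_count_de(expr, group_ids(part, GROUP1), group_ids(part, GROUP2),
                       fdr_threshold = params$fdr_threshold)$n_called
      )
    })
  }
  sp <- sam_params(n_permutations = params$n_permutations,
                   fdr_threshold = params$fdr_threshold,
                   seed = run_seed)
  frozen <- perm_assignments(n1 + n2, n1, params$n_permutations, run_seed)
  function(part) {
    suppressMessages(
      sam_count_de(expr, group_ids(part, GROUP1), group_ids(part, GROUP2),
                   params = sp, assignments = frozen, keep_genes = FALSE)$n_called
    )
  }
}

#' One divisive shuffling run
#'
#' Greedy stochastic hill-climb: starting from a random partition, repeated
#' single-subject swap proposals are accepted if and only if they increase
#' the number of differentially expressed genes between GROUP1 and GROUP2
#' (strictly, unless `accept_ties`). Bit-reproducible given `run_seed`.
#'
#' @param expr An [expression_matrix()].
#' @param params A [vista_params()] object.
#' @param run_seed Integer seed for this run.
#' @param run_id Identifier stored in the record.
#'
#' @return An object of class `vista_division`: final partition, final DE
#'   count, and the full attempt trajectory.
#' @export
vista_run <- function(expr, params = vista_params(), run_seed = params$seed,
                      run_id = 1L) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(params, "vista_params"))
  subject_ids <- colnames(expr)
  local_seed(run_seed, {
    part <- initial_partition(subject_ids, params$reservoir_size)
    sizes <- partition_sizes(part)
    objective <- make_objective(expr, params, run_seed, sizes[["n1"]], sizes[["n2"]])
    current <- objective(part)

    n_att <- params$max_attempts
    attempt <- integer(n_att); sub_out <- character(n_att); sub_in <- character(n_att)
    accepted <- logical(n_att); n_called <- integer(n_att)
    since_accept <- 0L
    k <- 0L
    for (i in seq_len(n_att)) {
      prop <- propose_swap(part)
      cand <- objective(prop$candidate)
      acc <- if (params$accept_ties) cand >= current else cand > current
      if (acc) {
        part <- prop$candidate
        current <- cand
        since_accept <- 0L
      } else {
        since_accept <- since_accept + 1L
      }
      k <- k + 1L
      attempt[k] <- i; sub_out[k] <- prop$subject_out; sub_in[k] <- prop$subject_in
      accepted[k] <- acc; n_called[k] <- current
      if (!is.null(params$plateau_window) && since_accept >= params$plateau_window) break
    }
    traj <- tibble(
      attempt = attempt[seq_len(k)],
      subject_out = sub_out[seq_len(k)],
      subject_in = sub_in[seq_len(k)],
      accepted = accepted[seq_len(k)],
      n_called = n_called[seq_len(k)]
    )
    structure(list(
      run_id = run_id,
      seed = run_seed,
      partition = part,
      n_called = current,
      trajectory = traj,
      trait_tests = NULL,
      significant_traits = NULL
    ), class = "vista_division")
  })
}

#' @export
print.vista_division <- function(x, ...) {
  s <- partition_sizes(x$partition)
  cat(sprintf(
    "<vista_division> run %s (seed %d): %d DE genes after %d attempts (%d accepted); sizes (%d, %d, %d)\n",
    x$run_id, x$seed, x$n_called, nrow(x$trajectory), sum(x$trajectory$accepted),
    s["n1"], s["n2"], s["nr"]
  ))
  invisible(x)
}

#' @export
#' @method tidy vista_division
tidy.vista_division <- function(x, ...) {
  dplyr::mutate(x$trajectory, run_id = x$run_id, .before = 1)
}

#' @export
#' @method glance vista_division
glance.vista_division <- function(x, ...) {
  tibble(
    run_id = x$run_id,
    seed = x$seed,
    n_called = x$n_called,
    n_attempts = nrow(x$trajectory),
    n_accepted = sum(x$trajectory$accepted),
    n_significant_traits = if (is.null(x$significant_traits)) NA_integer_
                           else length(x$significant_traits)
  )
}

#' Drive many independent shuffling runs
#'
#' Repeats [vista_run()] from independent random initial configurations.
#' Per-run seeds derive deterministically from the master seed, so the full
#' sweep is reproducible and runs share no mutable state.
#'
#' @inheritParams vista_run
#' @return An object of class `vista_fit`: list of `vista_division`
#'   records (in run order) plus the parameters.
#' @export
vista_drive <- function(expr, params = vista_params()) {
  stopifnot(inherits(params, "vista_params"))
  divisions <- purrr::map(seq_len(params$n_runs), function(i) {
    tryCatch(
      vista_run(expr, params, run_seed = derive_seed(params$seed, i), run_id = i),
      error = function(e) {
        warn(sprintf("run %d aborted: %s", i, conditionMessage(e)))
        NULL
      }
    )
  })
  divisions <- purrr::compact(divisions)
  if (!length(divisions)) abort("all runs failed")
  structure(list(divisions = divisions, params = params,
                 subject_ids = colnames(expr)),
            class = "vista_fit")
}

#' @export
print.vista_fit <- function(x, ...) {
  counts <- vapply(x$divisions, function(d) d$n_called, numeric(1))
  cat(sprintf("<vista_fit> %d runs; final DE counts: median %g (range %g-%g)\n",
              length(x$divisions), median(counts), min(counts), max(counts)))
  invisible(x)
}

#' @export
#' @method tidy vista_fit
tidy.vista_fit <- function(x, ...) {
  purrr::map_dfr(x$divisions, glance)
}

#' @export
#' @method glance vista_fit
glance.vista_fit <- function(x, ...) {
  counts <- vapply(x$divisions, function(d) d$n_called, numeric(1))
  tibble(
    n_runs = length(x$divisions),
    median_n_called = median(counts),
    max_n_called = max(counts),
    engine = if (is.function(x$params$engine)) "custom" else x$params$engine
  )
}

#' Plot shuffling trajectories
#'
#' The DE-gene count between GROUP1 and GROUP2 as a function of the number
#' of attempted swaps, one curve per run.
#'
#' @param object A `vista_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot vista_fit
autoplot.vista_fit <- function(object, ...) {
  traj <- purrr::map_dfr(object$divisions, tidy)
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$attempt, y = .data$n_called,
                                     group = .data$run_id)) +
    ggplot2::geom_step(alpha = 0.5) +
    ggplot2::labs(x = "attempted swaps", y = "differentially expressed genes") +
    ggplot2::theme_minimal()
}
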
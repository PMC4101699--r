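# The divisive shuffling optimizer: partitions, swap proposals, greedy
# acceptance, and the multi-run driver.

test_that("initial partition sizes follow the floor rule", {
  ids140 <- sprintf("p%03d", 1:140)
  part <- local({ set.seed(1); initial_partition(ids140, 40) })
  expect_identical(unname(partition_sizes(part)), c(50L, 50L, 40L))

  ids9 <- sprintf("p%d", 1:9)
  part9 <- local({ set.seed(1); initial_partition(ids9, 3) })
  expect_identical(unname(partition_sizes(part9)), c(3L, 3L, 3L))

  expect_error(local({ set.seed(1); initial_partition(ids9, 7) }), "at least 11")
})

test_that("initial partition is deterministic in the seed and varies across seeds", {
  ids <- sprintf("p%02d", 1:30)
  a <- local({ set.seed(5); initial_partition(ids, 6) })
  b <- local({ set.seed(5); initial_partition(ids, 6) })
  c <- local({ set.seed(6); initial_partition(ids, 6) })
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("swap proposals conserve sizes and exchange labels correctly", {
  ids <- sprintf("p%02d", 1:30)
  part <- local({ set.seed(2); initial_partition(ids, 6) })
  set.seed(3)
  for (i in 1:50) {
    prop <- propose_swap(part)
    expect_identical(partition_sizes(prop$candidate), partition_sizes(part))
    # incomer takes the outgoer's group; outgoer joins the reservoir
    out_group <- unname(unclass(part)[prop$subject_out])
    expect_identical(unname(unclass(prop$candidate)[prop$subject_in]), out_group)
    expect_identical(unname(unclass(prop$candidate)[prop$subject_out]), 3L)
  }
})

test_that("swap selection is uniform over the comparison groups", {
  ids <- sprintf("p%03d", 1:100)
  part <- local({ set.seed(4); initial_partition(ids, 20) })
  pool <- c(group_ids(part, 1), group_ids(part, 2))
  set.seed(9)
  picks <- replicate(10000, propose_swap(part)$subject_out)
  freq <- table(factor(picks, levels = pool)) / 10000
  se <- sqrt((1 / 80) * (1 - 1 / 80) / 10000)
  expect_true(all(abs(freq - 1 / 80) <= 3.9 * se + 1e-12))
})

test_that("two-group mode swaps between the comparison groups", {
  ids <- sprintf("p%02d", 1:10)
  part <- local({ set.seed(2); initial_partition(ids, 0) })
  expect_identical(unname(partition_sizes(part)), c(5L, 5L, 0L))
  set.seed(1)
  prop <- propose_swap(part)
  expect_identical(partition_sizes(prop$candidate), partition_sizes(part))
  expect_identical(unname(unclass(prop$candidate)[prop$subject_out]), 2L)
  expect_identical(unname(unclass(prop$candidate)[prop$subject_in]), 1L)
})

test_that("a constant-zero objective is a fixed point", {
  em <- make_expr(matrix(rnorm(20 * 12, mean = 8), 20, 12))
  params <- vista_params(reservoir_size = 2, max_attempts = 40, n_runs = 1,
                         engine = stub_engine(function(g1, g2) 0L), seed = 1)
  run <- vista_run(em, params, run_seed = 10)
  expect_identical(sum(run$trajectory$accepted), 0L)
  expect_identical(run$n_called, 0L)
  init <- local({ set.seed(10); initial_partition(colnames(em), 2) })
  expect_identical(run$partition, init)
})

test_that("trajectories are monotone, sizes conserved, and runs replayable with any stub", {
  em <- make_expr(matrix(rnorm(20 * 16, mean = 8), 20, 16))
  # arbitrary deterministic objective of the partition
  score <- function(g1, g2) {
    sum(utf8ToInt(paste(g1, collapse = ""))) %% 17L +
      as.integer(substr(g1[1], 2, 4))
  }
  params <- vista_params(reservoir_size = 4, max_attempts = 120, n_runs = 1,
                         engine = stub_engine(score), seed = 1)
  r1 <- vista_run(em, params, run_seed = 77)
  r2 <- vista_run(em, params, run_seed = 77)
  expect_identical(r1, r2)

  acc <- r1$trajectory$n_called[r1$trajectory$accepted]
  expect_true(all(diff(r1$trajectory$n_called) >= 0))
  expect_identical(r1$n_called, utils::tail(r1$trajectory$n_called, 1))
  expect_identical(partition_sizes(r1$partition), c(n1 = 6L, n2 = 6L, nr = 4L))
  if (length(acc) > 1) expect_true(all(diff(acc) > 0))
})

test_that("tie acceptance accepts equal counts only when enabled", {
  em <- make_expr(matrix(rnorm(10 * 12, mean = 8), 10, 12))
  params_strict <- vista_params(reservoir_size = 2, max_attempts = 30, n_runs = 1,
                                engine = stub_engine(function(g1, g2) 5L), seed = 1)
  params_ties <- vista_params(reservoir_size = 2, max_attempts = 30, n_runs = 1,
                              engine = stub_engine(function(g1, g2) 5L), seed = 1,
                              accept_ties = TRUE)
  expect_identical(sum(vista_run(em, params_strict, 3)$trajectory$accepted), 0L)
  expect_identical(sum(vista_run(em, params_ties, 3)$trajectory$accepted), 30L)
})

test_that("plateau window stops a stalled run early", {
  em <- make_expr(matrix(rnorm(10 * 12, mean = 8), 10, 12))
  params <- vista_params(reservoir_size = 2, max_attempts = 500, n_runs = 1,
                         plateau_window = 25,
                         engine = stub_engine(function(g1, g2) 0L), seed = 1)
  run <- vista_run(em, params, 3)
  expect_identical(nrow(run$trajectory), 25L)
})

test_that("the driver is reproducible and returns records in run order", {
  em <- make_expr(matrix(rnorm(15 * 14, mean = 8), 15, 14))
  score <- function(g1, g2) sum(utf8ToInt(paste(g1, collapse = ""))) %% 23L
  params <- vista_params(reservoir_size = 2, max_attempts = 30, n_runs = 3,
                         engine = stub_engine(score), seed = 42)
  f1 <- vista_drive(em, params)
  f2 <- vista_drive(em, params)
  expect_identical(f1$divisions, f2$divisions)
  expect_identical(vapply(f1$divisions, function(d) d$run_id, integer(1)), 1:3)
  expect_length(vista_drive(em, vista_params(
    reservoir_size = 2, max_attempts = 5, n_runs = 1,
    engine = stub_engine(score), seed = 1
  ))$divisions, 1L)
})

test_that("partitions can be built from labeled vectors", {
  p <- as_partition(c(a = "GROUP1", b = "GROUP2", c = "RESERVOIR", d = "GROUP1"))
  expect_identical(group_ids(p, 1), c("a", "d"))
  expect_identical(unname(partition_sizes(p)), c(2L, 1L, 1L))
  expect_identical(as_partition(c(a = 1, b = 2, c = 3, d = 1)), p)
  expect_error(as_partition(c(1, 2)), "named")
  expect_error(as_partition(c(a = "GROUPX", b = "GROUP2")), "labels")
})

test_that("overlap scoring is symmetric under label exchange and class relabel", {
  ids <- sprintf("p%02d", 1:20)
  part <- local({ set.seed(8); initial_partition(ids, 4) })
  classes <- setNames(rep(c("A", "B"), 10), ids)
  o1 <- partition_overlap(part, classes)
  swapped <- unclass(part)
  swapped[swapped == 1L] <- 99L; swapped[swapped == 2L] <- 1L; swapped[swapped == 99L] <- 2L
  o2 <- partition_overlap(vista:::new_partition(swapped), classes)
  flipped <- setNames(ifelse(classes == "A", "B", "A"), ids)
  o3 <- partition_overlap(part, flipped)
  expect_equal(o1, o2)
  expect_equal(o1, o3)
  expect_gte(o1, 0.5)
})
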
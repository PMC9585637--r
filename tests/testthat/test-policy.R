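test_that("pointwise initialisation draws 1% with a floor of one", {
  expect_equal(nrow(init_pointwise(c(100, 100), seed = 1)), 100)
  expect_equal(nrow(init_pointwise(c(5, 5), seed = 1)), 1)
  expect_identical(init_pointwise(c(20, 20), seed = 4),
                   init_pointwise(c(20, 20), seed = 4))
})

test_that("linewise initialisation hits 25/50/70% of the height", {
  rows_of <- function(L) sort(unique(init_linewise(line_schedule(n_rows = L), 4)$row))
  expect_equal(rows_of(101), c(26, 51, 71))  # positions 25, 50, 70 zero-based
  expect_equal(rows_of(79), c(21, 40, 56))   # round(p * 78) -> 20, 39, 55 zero-based
  expect_equal(rows_of(3), c(1, 2))          # degenerate: duplicates collapse
  expect_error(init_linewise(line_schedule(n_rows = 2), 4), "at least 3")
  init <- init_linewise(line_schedule(n_rows = 10), 7)
  expect_equal(nrow(init), 3 * 7)            # full rows
})

test_that("pointwise selection matches a brute-force argmax with tie-breaks", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(4:9, 1); m <- sample(4:9, 1)
    erd <- matrix(sample(0:5, n * m, replace = TRUE), n, m)  # many ties
    st <- new_measurement_state(c(n, m), "x")
    st <- measure(st, random_mask(c(n, m), 0.3, seed = s),
                  channel_stack(array(1, c(n, m, 1))))
    sel <- select_pointwise(erd, st)
    expect_equal(c(sel$row, sel$col), argmax_oracle(erd, st$measured))
  }
})

test_that("all-zero ERD falls back to the first unmeasured pixel", {
  st <- new_measurement_state(c(4, 4), "x")
  st <- measure(st, data.frame(row = 1, col = 1), matrix(1, 1, 1))
  sel <- select_pointwise(matrix(0, 4, 4), st)
  expect_equal(c(sel$row, sel$col), c(1, 2))  # (1,1) measured; next in (row, col) order
})

test_that("selection signals completion when nothing is unmeasured", {
  st <- new_measurement_state(c(2, 2), "x")
  st <- measure(st, expand.grid(row = 1:2, col = 1:2), matrix(1, 4, 1))
  expect_null(select_pointwise(matrix(1, 2, 2), st))
})

test_that("otsu_threshold separates a bimodal vector and flags constants", {
  thr <- otsu_threshold(c(0, 0, 0, 10, 10, 10))
  expect_gt(thr, 0)
  expect_lt(thr, 10)
  expect_true(is.na(otsu_threshold(c(3, 3, 3))))
  expect_error(otsu_threshold(5), "at least 2")
})

test_that("otsu_threshold matches the exhaustive variance oracle", {
  for (s in 1:40) {
    set.seed(100 + s)
    n <- sample(2:64, 1)
    values <- switch(1 + s %% 3,
      c(runif(ceiling(n / 2), 0, 2), runif(floor(n / 2), 5, 10))[1:n],
      runif(n, 0, 1),
      sample(0:8, n, replace = TRUE))
    if (length(unique(values)) < 2) next
    thr <- otsu_threshold(values)
    expect_equal(values > thr, otsu_oracle_partition(values))
  }
})

test_that("linewise segment selection follows max-sum row and Otsu subset", {
  st <- new_measurement_state(c(5, 5), "x")
  st <- measure(st, data.frame(row = 5, col = 1), matrix(1, 1, 1))
  erd <- matrix(0, 5, 5)
  erd[1, ] <- c(1, 1, 1, 1, 1)            # sum 5
  erd[3, ] <- c(0, 0, 8, 9, 0)            # sum 17 -> chosen
  seg <- select_linewise_segment(erd, st, line_schedule(n_rows = 5))
  expect_equal(seg$row, 3)
  expect_equal(sort(seg$pixels$col), c(3, 4))  # Otsu keeps the 8 and 9
})

test_that("degenerate zero ERD yields the lowest row in full", {
  st <- new_measurement_state(c(4, 6), "x")
  st <- measure(st, data.frame(row = 1, col = 2), matrix(1, 1, 1))
  seg <- select_linewise_segment(matrix(0, 4, 6), st, line_schedule(n_rows = 4))
  expect_equal(seg$row, 1)
  expect_equal(sort(seg$pixels$col), c(1, 3, 4, 5, 6))  # all unmeasured on row 1
})

test_that("visited lines are excluded when visits are single-shot", {
  st <- new_measurement_state(c(3, 4), "x")
  st <- measure(st, data.frame(row = 1, col = 1), matrix(1, 1, 1))
  sched <- line_schedule(n_rows = 3, visited_once_only = TRUE)
  erd <- matrix(1, 3, 4)
  erd[2, ] <- 5
  sched <- mark_visited(sched, 2)
  seg <- select_linewise_segment(erd, st, sched)
  # row 2 has the highest ERD but is spent; row 3 has the larger unmeasured sum
  expect_equal(seg$row, 3)
  sched <- mark_visited(mark_visited(sched, 1), 3)
  expect_null(select_linewise_segment(erd, st, sched))
})

test_that("check_stop handles density and iteration criteria", {
  tr <- tiny_phantom(c(10, 10), 1)
  st <- new_measurement_state(c(10, 10), tr$channel_labels)
  st <- measure(st, random_mask(c(10, 10), 0.40, seed = 1), tr, iteration = 3L)
  expect_true(check_stop(st, list(max_density = 0.40)))
  expect_false(check_stop(st, list(max_density = 0.41)))
  expect_false(check_stop(st, list(max_density = 0.41, max_iterations = 10)))
  expect_true(check_stop(st, list(max_iterations = 0)))
  expect_true(check_stop(st, list(max_iterations = 3)))
  expect_error(check_stop(st, list()), "criteria")
})
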
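test_that("eye combination averages, falls back and invalidates correctly", {
  stream <- data.frame(
    t_s = c(0, 0.1, 0.2),
    left_x = c(0.2, NA, NA), left_y = c(0.4, NA, NA),
    left_valid = c(TRUE, FALSE, FALSE),
    right_x = c(0.4, 0.9, NA), right_y = c(0.4, 0.1, NA),
    right_valid = c(TRUE, TRUE, FALSE)
  )
  mono <- combine_eyes(stream)
  expect_equal(mono$x, c(0.3, 0.9, NA))
  expect_equal(mono$y, c(0.4, 0.1, NA))
  expect_equal(mono$valid, c(TRUE, TRUE, FALSE))
})

test_that("ROI assignment is half-open with priority on shared edges", {
  layout <- roi_layout(data.frame(
    id = c("A", "B"),
    x_min = c(0, 0.5), y_min = c(0, 0),
    x_max = c(0.5, 1), y_max = c(1, 1)
  ))
  pts <- data.frame(x = c(0.25, 0.5, 0.75, 1.2), y = c(0.5, 0.5, 0.5, 0.5),
                    valid = TRUE)
  expect_equal(assign_roi(pts, layout), c("A", "B", "B", NA))
  # a region listed first wins where rectangles overlap
  overlap <- roi_layout(data.frame(
    id = c("top", "bottom"),
    x_min = c(0, 0), y_min = c(0, 0), x_max = c(1, 1), y_max = c(1, 1)
  ))
  expect_equal(assign_roi(data.frame(x = 0.5, y = 0.5, valid = TRUE), overlap),
               "top")
})

test_that("dwell collapsing emits transitions and honours the gap rule", {
  t <- (0:5) * 0.1
  ev <- collapse_to_transitions(t, c("A", "A", "A", "B", "B", "A"))
  expect_equal(ev$from, c("A", "B"))
  expect_equal(ev$to, c("B", "A"))

  # short invalid gap inside one dwell is bridged: no event
  ev2 <- collapse_to_transitions(c(0, 0.2, 0.4), c("A", NA, "A"), gap_max_s = 1)
  expect_equal(nrow(ev2), 0)

  # a 3-s invalid gap breaks the sequence without an A->B event
  ev3 <- collapse_to_transitions(c(0, 0.1, 3.2, 3.3), c("A", "A", "B", "B"),
                                 gap_max_s = 1)
  expect_equal(nrow(ev3), 0)
})

test_that("visual entropy matches closed forms", {
  expect_equal(visual_entropy(matrix(c(0, 2, 2, 0), 2, byrow = TRUE)), 0)
  m3 <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, byrow = TRUE)
  expect_equal(visual_entropy(m3), 1)
  for (n in 3:6) {
    mn <- matrix(1, n, n) - diag(n)
    expect_equal(visual_entropy(mn), log2(n - 1))
  }
  expect_true(is.na(visual_entropy(matrix(0, 3, 3))))
})

test_that("entropy agrees with the term-by-term oracle and is label-invariant", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    counts <- matrix(sample(0:20, n * n, replace = TRUE), n)
    diag(counts) <- 0
    if (sum(counts) == 0) counts[1, 2] <- 1
    expect_equal(visual_entropy(counts), entropy_oracle(counts),
                 tolerance = 1e-12)
    perm <- sample(n)
    expect_equal(visual_entropy(counts[perm, perm]), visual_entropy(counts),
                 tolerance = 1e-12)
  }
})

test_that("empirical entropy converges to the chain's analytic value", {
  n <- 9
  tau <- scan_temperature_for_entropy(n, 1.8)
  p <- scan_transition_matrix(n, tau)
  h_true <- scanpath_conditional_entropy(p)
  expect_equal(h_true, 1.8, tolerance = 1e-6)

  prof <- flat_profile(0.5, make_phase_schedule(c(60, 240, 240, 240, 60)))
  stream <- generate_gaze(prof, clean_gaze(
    temp_base = tau, dwell_mean_s = 0.2, fs = 30), seed = 3)
  mono <- combine_eyes(stream)
  roi <- assign_roi(mono, default_roi_layout())
  ev <- collapse_to_transitions(mono$t_s, roi)
  errs <- vapply(c(60, 240, 840), function(win) {
    m <- transition_matrix(ev[ev$t_s < win, ], default_roi_layout()$id)
    abs(visual_entropy(m) - h_true)
  }, numeric(1))
  expect_lt(errs[3], 0.1)
  expect_lt(errs[3], errs[1])
})

test_that("deterministic cyclic scans give zero windowed entropy", {
  prof <- flat_profile(0.9)
  stream <- generate_gaze(prof, clean_gaze(temp_base = 0), seed = 1)
  s <- entropy_series(stream, default_roi_layout())
  expect_true(all(s$value[!s$flagged] == 0))
})

test_that("windowed entropy rises with scan temperature", {
  prof <- flat_profile(0.5)
  mean_h <- function(temp, seed) {
    st <- generate_gaze(prof, clean_gaze(temp_base = temp), seed = seed)
    s <- entropy_series(st, default_roi_layout())
    mean(s$value[!s$flagged])
  }
  for (seed in 1:5) {
    expect_gt(mean_h(0.8, seed), mean_h(0.2, seed))
  }
})

test_that("short streams yield a single shrunk window", {
  prof <- flat_profile(0.5)
  stream <- generate_gaze(prof, clean_gaze(), seed = 2)
  stub <- stream[stream$t_s < 30, ]
  s <- entropy_series(stub, default_roi_layout(), window_s = 60)
  expect_length(s$t_s, 1)
})

test_that("empty ROI layouts are rejected", {
  expect_error(roi_layout(data.frame(id = character(0), x_min = numeric(0),
                                     y_min = numeric(0), x_max = numeric(0),
                                     y_max = numeric(0))), "non-empty")
})
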
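series_of <- function(values, step = 5, t0 = 0, ...) {
  index_series(t0 + (seq_along(values) - 1) * step, values, step, ...)
}

test_that("min-max normalization rescales to [0, 1] and is idempotent", {
  s <- series_of(c(2, 4, 6))
  expect_equal(minmax_normalize(s)$value, c(0, 0.5, 1))
  n1 <- minmax_normalize(s)
  expect_equal(minmax_normalize(n1)$value, n1$value)
  expect_error(minmax_normalize(series_of(rep(2, 5))), "constant")
})

test_that("flagged points are excluded from the min/max but kept flagged", {
  s <- index_series(0:3 * 5, c(1, 3, 100, 5), 5,
                    flagged = c(FALSE, FALSE, TRUE, FALSE))
  n <- minmax_normalize(s)
  expect_equal(n$value[c(1, 2, 4)], c(0, 0.5, 1))
  expect_true(n$flagged[3])
})

test_that("alignment pairs identical grids as identity", {
  a <- series_of(1:10)
  b <- series_of(11:20)
  al <- align_series(a, b)
  expect_equal(al$a$value, 1:10)
  expect_equal(al$b$value, 11:20)
  expect_equal(al$a$t_s, al$b$t_s)
})

test_that("step-valued series are carried forward onto the fine grid", {
  clicks <- series_of(c(7, 9), step = 120, resample = "locf")
  fine <- series_of(rnorm(48), step = 5)
  al <- align_series(fine, clicks, step_s = 5)
  expect_equal(sum(al$b$value == 7), 24)
  expect_equal(sum(al$b$value == 9), 24)
})

test_that("flagged gaps are dropped pairwise during alignment", {
  a <- index_series(0:9 * 5, 1:10, 5, flagged = c(rep(FALSE, 4), TRUE,
                                                  rep(FALSE, 5)))
  b <- series_of(101:110)
  al <- align_series(a, b)
  expect_false(20 %in% al$a$t_s)
  expect_false(20 %in% al$b$t_s)
  expect_length(al$a$t_s, 9)
})

test_that("series without overlap refuse to align", {
  a <- series_of(1:5, t0 = 0)
  b <- series_of(1:5, t0 = 1000)
  expect_error(align_series(a, b), "overlap")
})

test_that("fusion is the convex weighted sum", {
  a <- series_of(c(0, 1))
  b <- series_of(c(1, 0))
  expect_equal(fuse_series(a, b, fusion_weights(1, 0))$value, a$value)
  expect_equal(fuse_series(a, b, fusion_weights(0.5, 0.5))$value, c(0.5, 0.5))
  expect_equal(fuse_series(series_of(c(1, 0)), series_of(c(0, 1)),
                           fusion_weights(0.7, 0.3))$value, c(0.7, 0.3))
  expect_error(fuse_series(a, series_of(c(1, 0), t0 = 5)), "aligned")
  expect_error(fusion_weights(0.7, 0.7), "sum to 1")
})

test_that("fused values stay in [0, 1] for normalized inputs", {
  set.seed(1)
  for (w in list(fusion_weights(0.5), fusion_weights(0.7),
                 fusion_weights(0.3))) {
    a <- minmax_normalize(series_of(runif(50)))
    b <- minmax_normalize(series_of(runif(50)))
    f <- fuse_series(a, b, w)
    expect_true(all(f$value >= 0 & f$value <= 1))
  }
})

test_that("Pearson correlation matches the direct formula", {
  expect_equal(pearson_cc(1:10, 1:10), 1)
  expect_equal(pearson_cc(1:10, -(1:10)), -1)
  expect_equal(pearson_cc(c(1, 2, 3), c(1, 2, 4)), 0.9820, tolerance = 1e-4)
  expect_error(pearson_cc(c(1, 2, 3), c(2, 2, 2)), "constant")
  expect_error(pearson_cc(1:2, 1:2), "3 complete pairs")
})

test_that("Pearson correlation is affine-invariant and antisymmetric", {
  set.seed(5)
  x <- rnorm(30)
  y <- rnorm(30)
  r <- pearson_cc(x, y)
  expect_equal(pearson_cc(2.5 * x + 3, y), r, tolerance = 1e-12)
  expect_equal(pearson_cc(x, 0.1 * y - 7), r, tolerance = 1e-12)
  expect_equal(pearson_cc(-x, y), -r, tolerance = 1e-12)
})

test_that("phase means z-normalize across the included phases", {
  sched <- make_phase_schedule(c(10, 10, 10, 10, 10))
  vals <- c(rep(9, 2), rep(1, 2), rep(2, 2), rep(3, 2), rep(9, 2))
  s <- series_of(vals, step = 5)
  ps <- zscore_phase_means(s, sched, phases = mission_phases())
  expect_equal(ps$mean, c(1, 2, 3))
  expect_equal(ps$z, c(-1, 0, 1))

  full <- zscore_phase_means(s, sched)
  expect_equal(mean(full$z), 0, tolerance = 1e-12)
  expect_equal(sd(full$z), 1, tolerance = 1e-12)
})

test_that("degenerate phase means give all-zero z with a warning", {
  sched <- make_phase_schedule(c(10, 10, 10, 10, 10))
  s <- series_of(rep(4, 10), step = 5)
  expect_warning(ps <- zscore_phase_means(s, sched,
                                          phases = mission_phases()),
                 "constant")
  expect_equal(ps$z, c(0, 0, 0))
  empty <- index_series(c(0, 5), c(1, 2), 5)
  expect_error(zscore_phase_means(empty, sched, phases = "Phase3"),
               "no valid samples")
})

test_that("one-way ANOVA matches the hand sum-of-squares decomposition", {
  groups <- list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)) # SSB = 6, SSW = 6
  an <- oneway_anova(groups)
  expect_equal(an$F, 3)
  expect_equal(c(an$df_between, an$df_within), c(2, 6))
  or <- anova_oracle(groups)
  expect_equal(an$F, or$F, tolerance = 1e-12)
  expect_equal(an$p, or$p, tolerance = 1e-12)

  flat <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3))
  expect_equal(oneway_anova(flat)$F, 0)

  shifted <- lapply(groups, function(g) g + 100)
  expect_equal(oneway_anova(shifted)$F, an$F, tolerance = 1e-10)

  expect_error(oneway_anova(list(c(1, 1), c(2, 2))), "zero within-group")
  expect_error(oneway_anova(list(c(1, 2))), "two groups")
})

test_that("Tukey HSD separates what the studentized range separates", {
  set.seed(9)
  tight <- list(rnorm(5, 0, 0.1), rnorm(5, 10, 0.1), rnorm(5, 20, 0.1))
  tk <- tukey_hsd(tight)
  expect_true(all(tk$significant))
  expect_equal(tk$significant, tukey_oracle(tight))

  same <- list(rnorm(5), rnorm(5), rnorm(5))
  expect_equal(tukey_hsd(same)$significant, tukey_oracle(same))

  weak <- list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  expect_false(any(tukey_hsd(weak)$significant))
})

test_that("correlation summaries use the sample-SD convention", {
  # construct features with exactly known correlations via orthogonal bases
  x <- rep(c(1, -1), 8)
  z <- rep(c(1, 1, -1, -1), 4)
  mk <- function(r) list(a = x, b = r * x + sqrt(1 - r^2) * z)
  ct <- correlation_table(list(P1 = mk(0.6), P2 = mk(0.8)))
  expect_equal(ct$summary$mean_cc, 0.7, tolerance = 1e-12)
  expect_equal(ct$summary$sd_cc, sd(c(0.6, 0.8)), tolerance = 1e-12)
  expect_equal(ct$summary$sd_cc, 0.1414, tolerance = 1e-3)

  one <- correlation_table(list(P1 = mk(0.3)))
  expect_true(is.na(one$summary$sd_cc))

  dup <- correlation_table(list(P1 = list(a = x, b = x)))
  expect_equal(dup$summary$mean_cc, 1)
})

test_that("participants lacking a feature pair are omitted with a warning", {
  x <- rnorm(20)
  y <- rnorm(20)
  feats <- list(P1 = list(a = x, b = y), P2 = list(a = x, b = rep(1, 20)))
  expect_warning(ct <- correlation_table(feats), "degenerate")
  expect_equal(ct$summary$n_participants, 1)
})
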
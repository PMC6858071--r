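test_that("cumulative/density transforms match the differencing rule", {
  expect_equal(cumulative_to_density(c(100, 60, 10, 0), 0:3),
               c(40, 50, 10, 0))
  # flat cumulative: all mass at the top level
  expect_equal(cumulative_to_density(c(5, 5, 5), 0:2), c(0, 0, 5))
  expect_error(cumulative_to_density(c(100, 110, 0), 0:2), "increase")
  expect_equal(density_to_cumulative(c(40, 50, 10, 0)), c(100, 60, 10, 0))
  expect_equal(density_to_cumulative(rep(0, 4)), rep(0, 4))
  expect_error(density_to_cumulative(c(1, -2, 3)), "negative")
})

test_that("transforms are exact mutual inverses on random monotone input", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    cum <- random_cumulative(n)
    expect_equal(density_to_cumulative(cumulative_to_density(cum, seq_len(n))),
                 cum)
    den <- stats::runif(n, 0, 1e4)
    expect_equal(cumulative_to_density(density_to_cumulative(den), seq_len(n)),
                 den)
    # conservation: density sums to the level-0 cumulative count
    expect_equal(sum(cumulative_to_density(cum, seq_len(n))), cum[1])
  }
})

test_that("detection-limit extension follows the adjacency rules", {
  levels <- seq(0, 10, by = 2)
  # rule (a): zeros at 6 mM with colonies observed at 8 mM
  counts <- rbind(c(1e5, 1e3, 500, 0, 200, 0),
                  c(1e5, 1e3, 500, 0, 150, 0),
                  c(1e5, 1e3, 500, 0, 100, 0))
  df <- make_series(list(`2` = counts), levels)
  ext <- extend_detection_limit(df)
  at6 <- ext$cfu_per_ml[ext$tolerance_mM == 6]
  expect_equal(sort(at6), c(0, 0, 90.9))
  # rule (b): 10 mM is the first level beyond the last observation (8 mM)
  at10 <- ext$cfu_per_ml[ext$tolerance_mM == 10]
  expect_equal(sort(at10), c(0, 0, 90.9))
})

test_that("extension rule (b) fills only the first level beyond the data", {
  levels <- seq(0, 10, by = 2)
  counts <- rbind(c(1e5, 1e3, 500, 100, 0, 0),
                  c(1e5, 1e3, 500, 120, 0, 0),
                  c(1e5, 1e3, 500, 80, 0, 0))
  df <- make_series(list(`2` = counts), levels)
  ext <- extend_detection_limit(df)
  expect_equal(sort(ext$cfu_per_ml[ext$tolerance_mM == 8]), c(0, 0, 90.9))
  expect_equal(ext$cfu_per_ml[ext$tolerance_mM == 10], c(0, 0, 0))
})

test_that("extension is idempotent, minimal, and a no-op on nonzero data", {
  levels <- seq(0, 10, by = 2)
  counts <- rbind(c(1e5, 1e3, 500, 100, 0, 0),
                  c(1e5, 1e3, 500, 120, 0, 0),
                  c(1e5, 1e3, 500, 80, 0, 0))
  df <- make_series(list(`2` = counts, `6` = counts), levels)
  df <- df[order(df$replicate, df$time_h, df$tolerance_mM), ]
  once <- extend_detection_limit(df)
  twice <- extend_detection_limit(once)
  expect_equal(twice$cfu_per_ml, once$cfu_per_ml)
  # at most one replicate changed per (time, level)
  for (tm in unique(df$time_h)) {
    for (l in levels) {
      sel <- df$time_h == tm & df$tolerance_mM == l
      expect_lte(sum(once$cfu_per_ml[sel] != df$cfu_per_ml[sel]), 1)
    }
  }
  all_nz <- make_series(list(`2` = counts[, 1:4] + 1), levels[1:4])
  expect_equal(extend_detection_limit(all_nz)$cfu_per_ml, all_nz$cfu_per_ml)
})

test_that("replicate averaging is the arithmetic mean per (time, level)", {
  levels <- c(0, 2)
  counts <- rbind(c(10, 0), c(20, 0), c(30, 90.9))
  df <- make_series(list(`2` = counts), levels)
  avg <- average_replicates(df)
  expect_equal(avg$cfu_per_ml[avg$tolerance_mM == 0], 20)
  # one colony credited to a single replicate averages to 30.3 CFU/mL
  expect_equal(avg$cfu_per_ml[avg$tolerance_mM == 2], 30.3)
  expect_equal(unique(avg$replicate), "mean")
  # identical replicates are unchanged
  same <- make_series(list(`2` = rbind(c(5, 1), c(5, 1))), levels)
  expect_equal(average_replicates(same)$cfu_per_ml, c(5, 1))
  # mismatched level sets across replicates are an error
  bad <- df[-1, ]
  expect_error(average_replicates(bad), "replicates")
})

test_that("spline initial condition reproduces knots, stays monotone, conserves mass", {
  levels <- 0:10
  counts <- cummin(c(2e6, 3e5, 1e4, 2e3, 300, 100, 30, 0, 0, 0, 0))
  g <- tolerance_grid(12, 0.01)
  den <- interpolate_initial_condition(counts, levels, g)
  expect_true(all(den >= 0))
  # total mass telescopes to the level-0 cumulative count
  expect_equal(sum(den), counts[1])
  # knot values reproduced exactly by the fine cumulative curve
  fine_cum <- density_to_cumulative(den)
  at_knots <- fine_cum[match(levels, round(g$x, 10))]
  expect_equal(at_knots, counts, tolerance = 1e-10)
  # fine cumulative non-increasing everywhere
  expect_true(all(diff(fine_cum) <= 1e-9))
  expect_error(interpolate_initial_condition(c(1, 2, 1), 0:2, g),
               "non-increasing")
  expect_error(interpolate_initial_condition(counts, levels,
                                             tolerance_grid(8, 0.01)),
               "below the highest")
})

test_that("binning conserves mass and inverts the interpolation", {
  g <- tolerance_grid(12, 0.01)
  # uniform fine density over [0, 2) totalling 100
  den <- numeric(g$n)
  den[g$x < 2] <- 100 / sum(g$x < 2)
  coarse <- bin_to_data_resolution(den, g, c(0, 1, 2), cumulative = FALSE)
  expect_equal(coarse, c(50, 50, 0))
  expect_equal(bin_to_data_resolution(den, g, c(0, 1, 2)), c(100, 50, 0))
  expect_error(bin_to_data_resolution(den, g, c(0, 0.505)), "align")
  # round trip: interpolate then re-bin at the original levels
  levels <- 0:10
  counts <- cummin(c(2e6, 3e5, 1e4, 2e3, 300, 100, 30, 10, 0, 0, 0))
  den2 <- interpolate_initial_condition(counts, levels, g)
  back <- bin_to_data_resolution(den2, g, levels)
  expect_equal(sum(den2), counts[1])
  nz <- counts > 0
  expect_lt(max(abs(back[nz] - counts[nz]) / counts[nz]), 0.01)
})

test_that("prepare_series chains extension, averaging and monotonization", {
  levels <- seq(0, 6, by = 2)
  counts <- rbind(c(1e5, 900, 0, 0),
                  c(9e4, 1100, 0, 0),
                  c(1.1e5, 1000, 0, 0))
  df <- make_series(list(`2` = counts), levels)
  prep <- prepare_series(df)
  expect_equal(unique(prep$replicate), "mean")
  ordered <- prep$cfu_per_ml[order(prep$tolerance_mM)]
  expect_true(all(diff(ordered) <= 0))
  # 4 mM got the single-colony credit in one of three replicates
  expect_equal(ordered[3], 90.9 / 3, tolerance = 1e-9)
})

test_that("the CSV reader validates and round-trips the canonical schema", {
  df <- make_series(list(`2` = rbind(c(100, 10), c(90, 0))), c(0, 2))
  df$extra <- "kept"
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  back <- read_tolerance_csv(path)
  expect_true("extra" %in% names(back))
  expect_equal(sort(back$cfu_per_ml), sort(df$cfu_per_ml))
  bad <- df[, setdiff(names(df), "cfu_per_ml")]
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_tolerance_csv(path), "cfu_per_ml")
})
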
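mk_series <- function(times, offsets) {
  clock_offset_series("receiver", "eeg", times, offsets)
}

test_that("identical offset records compare as equal", {
  a <- mk_series(seq(0, 100, by = 5), rnorm(21, 0, 1e-4))
  cmp <- align_offset_records(a, a)
  expect_equal(cmp$paired_differences, rep(0, 21))
  expect_equal(cmp$mean_difference, 0)
  expect_equal(cmp$outlier_count, 0)
})

test_that("a constant shift between recorders appears as the mean difference", {
  t <- seq(0, 500, by = 5)
  base <- -0.1 + 2e-6 * t
  a <- mk_series(t, base)
  b <- mk_series(t + 0.7, base + 5e-5)  # measured slightly later, shifted
  cmp <- align_offset_records(a, b)
  expect_equal(cmp$n_pairs, length(t))
  expect_equal(cmp$mean_difference, -5e-5, tolerance = 1e-12)
  expect_equal(cmp$mean_abs_difference, 5e-5, tolerance = 1e-12)
})

test_that("perturbed measurements are counted as outliers", {
  t <- seq(0, 1000, by = 5)
  a_off <- rnorm(length(t), 0, 1e-4)
  hit <- seq(10, length(t), by = 100)
  a_off[hit] <- a_off[hit] + 0.150
  cmp <- align_offset_records(mk_series(t, a_off), mk_series(t, rep(0, length(t))))
  expect_equal(cmp$outlier_count, length(hit))
  expect_lte(cmp$outlier_count, cmp$n_pairs)
})

test_that("comparison antisymmetry: swapping recorders negates the mean", {
  set.seed(3)
  t <- seq(0, 300, by = 5)
  a <- mk_series(t, rnorm(length(t), 0, 1e-3))
  b <- mk_series(t + 0.4, rnorm(length(t), 1e-4, 1e-3))
  ab <- align_offset_records(a, b)
  ba <- align_offset_records(b, a)
  expect_equal(ab$mean_difference, -ba$mean_difference)
  expect_equal(sort(ab$paired_differences), sort(-ba$paired_differences))
})

test_that("mismatched clock pairs and unpairable series are errors", {
  a <- mk_series(1:3, rep(0, 3))
  b <- clock_offset_series("receiver", "other", 1:3, rep(0, 3))
  expect_error(align_offset_records(a, b), "same clock pair")
  far <- mk_series(1000:1002, rep(0, 3))
  expect_error(align_offset_records(a, far), "paired")
})

test_that("the clipped histogram conserves counts and clips to the outer bins", {
  # all-zero differences fall in the bin containing 0
  h0 <- clipped_histogram(rep(0, 10))
  expect_equal(sum(h0$counts), 10)
  zero_bin <- findInterval(0, h0$edges)
  expect_equal(h0$counts[zero_bin], 10)

  # +150 ms lands in the top bin, -150 ms in the bottom one
  h <- clipped_histogram(c(0.150, -0.150, 1e-4))
  expect_equal(sum(h$counts), 3)
  expect_equal(h$counts[length(h$counts)], 1)
  expect_equal(h$counts[1], 1)

  # random vectors match the per-value oracle for several settings
  set.seed(14)
  x <- rnorm(2000, 0, 0.004)
  x[1:20] <- x[1:20] + sample(c(-1, 1), 20, TRUE) * 0.15
  for (bw in c(5e-4, 1e-3, 2e-3)) {
    for (clip in c(0.01, 0.02)) {
      h <- clipped_histogram(x, bin_width = bw, clip_limit = clip)
      expect_equal(sum(h$counts), length(x))
      expect_equal(h$counts, oracle_hist_counts(x, bw, clip))
    }
  }
  expect_error(clipped_histogram(1, bin_width = 0), "bin_width")
  expect_error(clipped_histogram(1, bin_width = 3e-3, clip_limit = 0.01),
               "whole number")
})
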
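# build a smooth_signal directly on a uniform grid
grid_signal <- function(t0, t1, rate, values, masked = NULL) {
  tt <- seq(t0, t1, by = 1 / rate)
  v <- rep_len(values, length(tt))
  m <- rep(FALSE, length(tt))
  if (!is.null(masked)) m <- masked(tt)
  v[m] <- NA_real_
  structure(list(timestamp_s = tt, diameter_mm = v,
                 interpolated_over_gap = m, rate_hz = rate,
                 source = "mean"),
            class = "smooth_signal")
}

test_that("segment metrics on a constant signal are degenerate and exact", {
  sig <- grid_signal(0, 10, 100, 4)
  seg <- segment_table(1, "trial", 2, 3)
  m <- summarize_segments(sig, seg, max_missing_pct = 50)
  expect_equal(m$mean_mm, 4)
  expect_equal(m$max_mm, 4)
  expect_equal(m$min_mm, 4)
  expect_equal(m$sd_mm, 0)
  expect_equal(m$missing_pct, 0)
  expect_false(m$rejected)
})

test_that("windows are half-open on the grid and partition contiguous segments", {
  sig <- grid_signal(0, 1, 10, 1:100)
  segs <- segment_table(1:2, c("a", "b"), c(0, 0.5), c(0.5, 1.001))
  m <- summarize_segments(sig, segs, max_missing_pct = 100)
  expect_equal(sum(m$n_grid_points), length(sig$timestamp_s))
  expect_equal(m$n_grid_points, c(5, 6))  # grid point at 0.5 goes to b
})

test_that("missing percentage counts masked grid points exactly", {
  sig <- grid_signal(0, 10, 100, 4, masked = function(tt) tt >= 2.5 & tt < 3)
  seg <- segment_table(1, "trial", 2, 3)
  m <- summarize_segments(sig, seg, max_missing_pct = 30)
  expect_equal(m$missing_pct, 50)
  expect_true(m$rejected)                      # 50% > 30%
  m2 <- summarize_segments(sig, seg, max_missing_pct = 60)
  expect_false(m2$rejected)
  # a segment entirely outside the signal span is 100% missing and flagged
  far <- summarize_segments(sig, segment_table(2, "x", 100, 101), 99)
  expect_equal(far$missing_pct, 100)
  expect_true(far$rejected)
  expect_true(is.na(far$mean_mm))
})

test_that("sd uses the n-1 denominator and is NA below two points", {
  sig <- grid_signal(0, 10, 100, c(3, 5))
  seg <- segment_table(1, "trial", 0, 0.05)   # 5 points: 3,5,3,5,3
  m <- summarize_segments(sig, seg, 100)
  expect_equal(m$sd_mm, stats::sd(c(3, 5, 3, 5, 3)))
  lone <- summarize_segments(sig, segment_table(2, "x", 0, 0.011), 100)
  expect_equal(lone$n_grid_points, 2)
  sig1 <- grid_signal(0, 10, 100, 4,
                      masked = function(tt) tt > 0.001 & tt < 0.02)
  one <- summarize_segments(sig1, segment_table(3, "x", 0, 0.02), 100)
  expect_true(is.na(one$sd_mm))
})

test_that("metrics are independent of segment ordering", {
  sig <- grid_signal(0, 10, 100, sin(1:50))
  segs <- segment_table(1:3, c("a", "b", "c"), c(1, 4, 7), c(2, 5, 8))
  fwd <- summarize_segments(sig, segs, 100)
  rev_ <- summarize_segments(sig, segs[3:1, ], 100)
  expect_equal(fwd[order(fwd$segment_id), ], rev_[order(rev_$segment_id), ],
               ignore_attr = TRUE)
})

test_that("time-course binning yields the expected bin count and centers", {
  sig <- grid_signal(0, 5, 1000, 4)
  seg <- segment_table(1, "trial", 1, 2)
  b <- bin_timecourse(sig, seg[1, ], 100)
  expect_equal(nrow(b), 10)
  expect_equal(b$bin_t_center_s, seq(1.05, 1.95, by = 0.1))
  expect_false(any(b$partial))
  # trailing partial bin is kept and flagged
  b2 <- bin_timecourse(sig, segment_table(2, "x", 1, 1.25)[1, ], 100)
  expect_equal(nrow(b2), 3)
  expect_true(b2$partial[3] && !any(b2$partial[1:2]))
})

test_that("bin means of a linear ramp sit at the bin centers", {
  tt <- seq(0, 5, by = 0.001)
  sig <- structure(list(timestamp_s = tt, diameter_mm = 3 + 0.5 * tt,
                        interpolated_over_gap = rep(FALSE, length(tt)),
                        rate_hz = 1000, source = "mean"),
                   class = "smooth_signal")
  b <- bin_timecourse(sig, segment_table(1, "trial", 1, 3)[1, ], 100)
  expect_equal(b$mean_mm, 3 + 0.5 * (b$bin_t_center_s - 0.0005),
               tolerance = 1e-6)
})

test_that("binning conserves the segment sum and handles full masking", {
  sig <- grid_signal(0, 10, 250, smooth_trace(seq(0, 10, by = 0.004)),
                     masked = function(tt) tt > 2.2 & tt < 2.5)
  seg <- segment_table(1, "trial", 1.95, 3.05)
  b <- bin_timecourse(sig, seg[1, ], 100)
  inwin <- sig$timestamp_s >= 1.95 & sig$timestamp_s < 3.05
  expect_equal(sum(b$n_points * b$mean_mm, na.rm = TRUE),
               sum(sig$diameter_mm[inwin], na.rm = TRUE))
  expect_equal(sum(b$n_points), sum(inwin & !is.na(sig$diameter_mm)))
  # bins fully inside the masked stretch are NA
  dead <- b$bin_t_center_s > 2.25 & b$bin_t_center_s < 2.45
  expect_true(all(is.na(b$mean_mm[dead])))
  allmask <- grid_signal(0, 10, 250, 4, masked = function(tt) rep(TRUE, length(tt)))
  b2 <- bin_timecourse(allmask, seg[1, ], 100)
  expect_true(all(is.na(b2$mean_mm)))
})

test_that("baseline pairing matches by trial and flags orphans", {
  metrics <- data.frame(
    segment_id = 1:6,
    label = rep(c("baseline", "trial"), 3),
    mean_mm = c(4.0, 4.4, 4.1, 4.5, NA, 4.6),
    trial_id = rep(1:3, each = 2))
  metrics$mean_mm[5] <- 4.2
  p <- pair_baselines(metrics)
  expect_equal(nrow(p), 3)
  expect_equal(p$baseline_mean_mm, c(4.0, 4.1, 4.2))
  expect_equal(p$mean_mm, c(4.4, 4.5, 4.6))     # no correction applied
  expect_false(any(p$baseline_missing))
  # orphan response: trial without a baseline in its trial_id
  orphan <- rbind(metrics, data.frame(segment_id = 7, label = "trial",
                                      mean_mm = 5, trial_id = 4))
  p2 <- pair_baselines(orphan)
  expect_true(p2$baseline_missing[p2$segment_id == 7])
  # duplicated baseline within a trial is an error
  dup <- rbind(metrics, data.frame(segment_id = 8, label = "baseline",
                                   mean_mm = 4, trial_id = 1))
  expect_error(pair_baselines(dup), "unique")
})

test_that("without trial ids pairing falls back to the preceding baseline", {
  metrics <- data.frame(
    segment_id = c(10, 11, 20, 21),
    label = c("baseline", "trial", "baseline", "trial"),
    mean_mm = c(4.0, 4.4, 4.1, 4.5))
  p <- pair_baselines(metrics)
  expect_equal(p$baseline_segment_id, c(10, 20))
  # a leading response with no preceding baseline is flagged
  lead <- metrics[c(2, 1, 3, 4), ]
  p2 <- pair_baselines(lead)
  expect_true(p2$baseline_missing[p2$segment_id == 11])
})
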
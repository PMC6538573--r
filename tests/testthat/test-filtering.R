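test_that("dilation speed matches hand-computed values", {
  expect_equal(compute_dilation_speed(c(0, 0.1, 0.2), c(4, 4.1, 3)),
               c(1, 11, 11))
  expect_equal(compute_dilation_speed(c(0, 1, 3), c(0, 2, 2)), c(2, 2, 0))
  expect_equal(compute_dilation_speed(c(0, 0.5, 1), rep(4.2, 3)),
               c(0, 0, 0))
  expect_error(compute_dilation_speed(0, 4), "insufficient")
})

test_that("dilation speed equals a per-sample loop oracle on random series", {
  set.seed(42)
  for (case in 1:50) {
    n <- sample(2:40, 1)
    t <- sort(runif(n, 0, 10))
    while (any(diff(t) == 0)) t <- sort(runif(n, 0, 10))
    d <- runif(n, 2, 6)
    expect_equal(compute_dilation_speed(t, d), oracle_dilation_speed(t, d))
  }
})

test_that("dilation speed has the expected invariances", {
  set.seed(7)
  t <- sort(runif(30, 0, 5))
  d <- runif(30, 3, 5)
  base <- compute_dilation_speed(t, d)
  expect_equal(compute_dilation_speed(t, d + 1.23), base)       # shift
  expect_equal(compute_dilation_speed(t, 2.5 * d), 2.5 * base)  # scale
  expect_equal(compute_dilation_speed(3 * t, d), base / 3)      # time rescale
  expect_true(all(base >= 0) && length(base) == length(d))
})

test_that("MAD threshold matches hand values and the brute-force oracle", {
  expect_identical(mad_threshold(c(1, 1, 1, 10), 5), 1)   # degenerate MAD 0
  expect_identical(mad_threshold(c(1, 2, 3, 4, 100), 2), 5)
  expect_identical(mad_threshold(rep(3.7, 9), 16), 3.7)   # constant series
  expect_error(mad_threshold(numeric(0), 2), "empty")
  set.seed(99)
  for (case in 1:1000) {
    x <- abs(rnorm(sample(1:50, 1), sd = runif(1, 0.1, 10)))
    n_mult <- runif(1, 1, 30)
    expect_identical(mad_threshold(x, n_mult),
                     oracle_mad_threshold(x, n_mult))
  }
})

test_that("range gate uses inclusive feasible bounds and is idempotent", {
  s <- filter_settings()
  expect_equal(filter_range(c(1.0, 2.0, 9.5), s), c(FALSE, TRUE, FALSE))
  expect_equal(filter_range(c(1.5, 9.0), s), c(TRUE, TRUE))
  expect_true(all(filter_range(seq(2, 8, by = 0.5), s)))
  expect_true(is.na(c(NA, 4))[1])  # NA diameters are not in range
  expect_equal(filter_range(c(NA, 4), s), c(FALSE, TRUE))
  # idempotence: filtering the survivors changes nothing
  d <- c(1, 2, 5, 10, NA, 8)
  m <- filter_range(d, s)
  expect_equal(filter_range(replace(d, !m, NA), s), m)
})

test_that("a lone spike is caught by the speed filter, with only adjacent collateral", {
  t <- seq(0, 0.99, by = 0.01)
  set.seed(3)
  d <- smooth_trace(t) + rnorm(100, 0, 0.02)
  d[50] <- d[50] + 3
  res <- filter_speed_outliers(t, d, settings = filter_settings())
  expect_false(res$mask[50])
  rejected <- which(!res$mask)
  expect_true(all(rejected %in% 49:51))
})

test_that("consecutive spike samples are both rejected (hand fixture)", {
  t <- seq(0, 0.09, by = 0.01)
  d <- c(4, 4, 4, 4, 5.5, 5.6, 4, 4, 4, 4)
  # hand evaluation: steps/0.01 -> d' = (0,0,0,150,150,160,160,0,0,0);
  # median 0, MAD 0, threshold 0; strictly-positive speeds rejected
  res <- filter_speed_outliers(t, d, settings = filter_settings())
  expect_equal(which(!res$mask), 4:7)
  expect_identical(res$threshold, 0)
})

test_that("constant series rejects nothing under the strict comparison", {
  t <- seq(0, 1, by = 0.01)
  res <- filter_speed_outliers(t, rep(4, length(t)),
                               settings = filter_settings())
  expect_true(all(res$mask))
})

test_that("gap-edge rejection honors the 50 ms margin and 75 ms qualification", {
  t <- seq(0, 1.999, by = 0.001)
  s <- filter_settings()
  # 100 ms gap: qualifies (> 75 ms); reject within 50 ms of either edge
  present <- !(t > 1.0 & t < 1.1)
  m <- reject_gap_edges(t, present, s)
  at <- function(tt) which.min(abs(t - tt))
  rejected <- present & !m
  expect_true(all(t[rejected] >= 0.95 - 1e-6 & t[rejected] <= 1.15 + 1e-6))
  expect_false(m[at(0.950)])           # exactly 50 ms: inclusive margin
  expect_true(m[at(0.949)])            # 51 ms away: retained
  expect_false(m[at(1.0)] || m[at(1.1)])  # gap-bordering samples go
  expect_true(m[at(1.151)])
  # 60 ms gap does not qualify
  present2 <- !(t > 1.0 & t < 1.06)
  expect_equal(reject_gap_edges(t, present2, s), present2)
  # applying twice with the same present mask equals once
  expect_equal(reject_gap_edges(t, present, s), m)
})

test_that("a gap at the recording start rejects only at its trailing edge", {
  t <- seq(0, 0.999, by = 0.001)
  present <- t >= 0.1    # eye data begin 100 ms into the recording
  m <- reject_gap_edges(t, present, filter_settings())
  rejected <- present & !m
  expect_true(all(t[rejected] <= 0.15 + 1e-12))
  expect_true(any(rejected))
  expect_true(m[t == 0.151])
})

test_that("trend line reproduces straight-line and constant signals", {
  t <- seq(0, 2, by = 0.01)
  d <- 4 + 0.2 * t
  tl <- build_trendline(t, d, filter_settings())
  ctr <- tl$grid >= 0.2 & tl$grid <= 1.8
  expect_lt(max(abs(tl$trend[ctr] - (4 + 0.2 * tl$grid[ctr]))), 0.005)
  tl2 <- build_trendline(t, rep(4.4, length(t)), filter_settings())
  expect_lt(max(abs(tl2$trend - 4.4)), 1e-6)
  expect_error(build_trendline(1, 4, filter_settings()), "insufficient")
})

test_that("trend line stays near dense on-trend samples despite a far cluster", {
  t <- seq(0, 5, by = 0.01)
  set.seed(5)
  d <- smooth_trace(t) + rnorm(length(t), 0, 0.02)
  cl <- 250:254
  d[cl] <- d[cl] + 1.0
  tl <- build_trendline(t, d, filter_settings())
  truth <- smooth_trace(tl$grid)
  ctr <- tl$grid >= 0.5 & tl$grid <= 4.5
  rmse <- sqrt(mean((tl$trend[ctr] - truth[ctr])^2))
  expect_lt(rmse, 1.0 / 10)   # well below the cluster offset
})

test_that("a deviant cluster is fully rejected by the deviation filter", {
  t <- seq(0, 9.99, by = 0.01)
  set.seed(8)
  d <- smooth_trace(t) + rnorm(length(t), 0, 0.03)
  cl <- 500:504
  d[cl] <- d[cl] + 0.5   # 10x noise SD, resistant to the speed filter inside
  res <- filter_trendline_deviation(t, d, settings = filter_settings())
  expect_true(all(!res$mask[cl]))
  expect_equal(res$passes, 2)
})

test_that("a clean smooth trace loses at most a small MAD-tail fraction", {
  t <- seq(0, 9.99, by = 0.01)
  set.seed(12)
  d <- smooth_trace(t) + rnorm(length(t), 0, 0.03)
  res <- filter_trendline_deviation(t, d, settings = filter_settings())
  expect_lte(mean(!res$mask), 0.05)
})

test_that("a later pass reinstates clean samples dragged out by a cluster", {
  t <- seq(0, 9.99, by = 0.01)
  set.seed(21)
  d <- smooth_trace(t) + rnorm(length(t), 0, 0.01)
  cl <- 500:514                     # long cluster pulls the trend line
  d[cl] <- d[cl] + 0.6
  one <- filter_trendline_deviation(t, d,
           settings = filter_settings(deviation_passes = 1))
  two <- filter_trendline_deviation(t, d,
           settings = filter_settings(deviation_passes = 2))
  reinstated <- which(!one$mask & two$mask)
  expect_gt(length(reinstated), 0)
  expect_true(all(!reinstated %in% cl))   # only clean neighbors come back
  expect_true(all(!two$mask[cl]))         # the cluster itself stays out
})

test_that("sparsity filter applies the 40 ms split and 50 ms section criteria", {
  t <- seq(0, 1.999, by = 0.001)
  s <- filter_settings()
  # 45 ms island flanked by 60 ms gaps: split (60 > 40), span 45 < 50 -> out
  valid <- t <= 0.5 | (t >= 0.56 & t <= 0.605) | t >= 0.665
  m <- filter_sparsity(t, valid, s)
  island <- t >= 0.56 & t <= 0.605
  expect_true(all(!m[island]))
  expect_equal(m[!island], valid[!island])
  # a 200 ms run flanked by large gaps is retained
  valid2 <- t <= 0.5 | (t >= 0.8 & t <= 1.0) | t >= 1.5
  expect_equal(filter_sparsity(t, valid2, s), valid2)
  # a single isolated sample spans 0 ms and is rejected
  lone <- which.min(abs(t - 1.0))
  valid3 <- t <= 0.5 | seq_along(t) == lone | t >= 1.5
  m3 <- filter_sparsity(t, valid3, s)
  expect_false(m3[lone])
  # idempotence
  expect_equal(filter_sparsity(t, m, s), m)
})

test_that("stage masks only switch samples off, except deviation reinstatement", {
  sr <- generate_recording(synthetic_scenario(seed = 4, duration_s = 15))
  rec <- sr$recording
  fr <- run_filter_pipeline(rec)
  for (eye in c("left", "right")) {
    vm <- fr[[eye]]
    present <- !is.na(rec[[paste0(eye, "_mm")]])
    expect_true(all(vm$range <= present))
    expect_true(all(vm$speed <= vm$range))
    expect_true(all(vm$gap_edge <= vm$speed))
    expect_true(all(vm$deviation <= vm$gap_edge))  # scope bound
    expect_true(all(vm$sparsity <= vm$deviation))
    expect_equal(vm$combined,
                 vm$range & vm$speed & vm$gap_edge & vm$deviation &
                   vm$sparsity)
  }
})

test_that("full filter catches ledgered artifacts and spares clean samples", {
  sr <- generate_recording(synthetic_scenario(
    seed = 17, duration_s = 30, n_blinks = 3, n_spikes = 5, n_islands = 1))
  rec <- sr$recording
  fr <- run_filter_pipeline(rec)
  for (eye in c("left", "right")) {
    d <- rec[[paste0(eye, "_mm")]]
    cls <- sr$ledger[[paste0("class_", eye)]]
    present <- !is.na(d)
    vm <- fr[[eye]]$combined
    art <- present & cls %in% c("blink_dip", "spike", "cluster", "island")
    expect_gte(sum(art & !vm) / sum(art), 0.95)
    clean <- present & cls == "clean"
    expect_lte(sum(clean & !vm) / sum(clean), 0.05)
  }
})

test_that("an artifact-free trace keeps at least 95% of its samples", {
  sr <- generate_recording(synthetic_scenario(
    seed = 31, duration_s = 20, n_blinks = 0, n_spikes = 0,
    n_clusters = 0, n_islands = 0))
  fr <- run_filter_pipeline(sr$recording)
  expect_gte(fr$left$report$pct_valid, 95)
  expect_gte(fr$right$report$pct_valid, 95)
})

test_that("range and sparsity stages are stable on their own survivors", {
  sr <- generate_recording(synthetic_scenario(seed = 9, duration_s = 15))
  rec <- sr$recording
  fr <- run_filter_pipeline(rec)
  vm <- fr$left$combined
  d2 <- replace(rec$left_mm, !vm, NA)
  expect_equal(filter_range(d2, fr$settings), vm)
  expect_equal(filter_sparsity(rec$timestamps, vm, fr$settings), vm)
})

test_that("the filter report accounts for every present sample", {
  sr <- generate_recording(synthetic_scenario(seed = 2, duration_s = 15))
  fr <- run_filter_pipeline(sr$recording)
  rep <- fr$left$report
  expect_equal(Reduce(`+`, rep$rejected) + rep$n_valid, rep$n_present)
  expect_true(is.finite(fr$left$thresholds$speed_mm_per_s))
  expect_length(fr$left$thresholds$deviation_mm, 2)
})
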
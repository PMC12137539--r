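# Target signals: primitives, synthetic muscle targets, assembly protocol.

test_that("primitive bumps are ordered and bounded", {
  p <- primitive_patterns(1.2)
  expect_s3_class(p, "stride_pattern")
  expect_equal(nrow(p$channels), 5L)
  peaks <- apply(p$channels, 1, which.max)
  expect_true(all(diff(peaks) > 0))
  expect_true(all(p$channels >= 0 & p$channels <= 0.8))
  expect_equal(max(p$channels), 0.8, tolerance = 1e-3)
})

test_that("primitive period follows the speed map and bounds are enforced", {
  p_slow <- primitive_patterns(0.3)
  p_fast <- primitive_patterns(2.0)
  expect_equal(p_slow$period, 1 / (0.6 + 0.25 * 0.3))
  expect_gt(p_slow$period, p_fast$period)
  expect_error(primitive_patterns(0.2), "0.3")
  expect_error(primitive_patterns(2.5), "0.3")
})

test_that("bump integral scales linearly with the period at fixed shape", {
  p1 <- primitive_patterns(0.5)
  p2 <- primitive_patterns(1.8)
  int1 <- sum(p1$channels[1, ]) / p1$sample_rate
  int2 <- sum(p2$channels[1, ]) / p2$sample_rate
  expect_equal(int1 / p1$period, int2 / p2$period, tolerance = 0.01)
})

test_that("synthetic targets are bounded, deterministic and distinguishable", {
  tg <- synthetic_muscle_targets(seed = 1)
  expect_named(tg, c("slow_walk", "fast_walk", "run"))
  expect_equal(vapply(tg, function(p) p$period, numeric(1)),
               c(slow_walk = 1.30, fast_walk = 1.00, run = 0.72))
  for (p in tg) {
    expect_equal(nrow(p$channels), 17L)
    expect_true(all(p$channels >= 0 & p$channels <= 1))
  }
  tg2 <- synthetic_muscle_targets(seed = 1)
  expect_identical(tg$run$channels, tg2$run$channels)
  tg3 <- synthetic_muscle_targets(seed = 2)
  expect_false(identical(tg$run$channels, tg3$run$channels))
  # pairwise RMS difference > 0.05 on at least half the channels
  common <- seq(0, 1, length.out = 101)[-101]
  resamp <- lapply(tg, function(p) {
    n <- ncol(p$channels)
    t(apply(p$channels, 1, function(ch)
      approx((seq_len(n) - 1) / n, ch, xout = common)$y))
  })
  pairs <- combn(3, 2)
  for (k in seq_len(ncol(pairs))) {
    d <- sqrt(rowMeans((resamp[[pairs[1, k]]] - resamp[[pairs[2, k]]])^2))
    expect_gte(mean(d > 0.05), 0.5)
  }
})

test_that("synthetic target set has at most 8 principal components", {
  tg <- synthetic_muscle_targets(seed = 1)
  stacked <- do.call(cbind, lapply(tg, `[[`, "channels"))
  expect_lte(effective_dimensionality(stacked), 8L)
})

test_that("assembly produces the right stride counts and balanced tests", {
  tg <- synthetic_muscle_targets(seed = 1)
  tr <- assemble_signal(tg, "train")
  expect_equal(nrow(tr$stride_spans), 15L)
  expect_equal(tr$stride_spans$activity,
               rep(c("slow_walk", "fast_walk", "run"), each = 5))
  te <- assemble_signal(tg, "test", seed = 4)
  expect_equal(nrow(te$stride_spans), 21L)
  expect_equal(as.integer(table(te$stride_spans$activity)), c(7L, 7L, 7L))
  te2 <- assemble_signal(tg, "test", seed = 4)
  expect_identical(te$signal, te2$signal)
  te3 <- assemble_signal(tg, "test", seed = 5)
  expect_false(identical(te$stride_spans$activity, te3$stride_spans$activity))
})

test_that("strides are joined by the interpolated midpoint sample", {
  tg <- synthetic_muscle_targets(seed = 1)
  raw <- assemble_signal(tg[c(1, 2)], "train", filter_cutoff = NA, trim = 0,
                         strides_per_activity = 1L)
  n1 <- ncol(tg[[1]]$channels)
  a <- tg[[1]]$channels[, n1]
  b <- tg[[2]]$channels[, 1]
  expect_equal(raw$signal[, n1 + 1], (a + b) / 2)
  # U(t) resets phase: every stride starts at U = 1
  expect_equal(raw$input_wave[1], 1)
  expect_equal(raw$input_wave[n1 + 2], 1)
})

test_that("signal length accounting: sum of strides + gaps - 100", {
  tg <- synthetic_muscle_targets(seed = 1)
  tr <- assemble_signal(tg, "train")
  lens <- vapply(tg, function(p) ncol(p$channels), integer(1))
  expect_equal(ncol(tr$signal), sum(lens * 5) + 14L - 100L)
  expect_equal(length(tr$input_wave), ncol(tr$signal))
})

test_that("the 20 Hz Butterworth filter is passband-flat and zero-phase", {
  fs <- 200
  t <- (0:2999) / fs
  x <- sin(2 * pi * 1 * t)
  bf <- signal::butter(2, 20 / (fs / 2), type = "low")
  y <- signal::filtfilt(bf, x)
  mid <- 500:2500
  expect_lt(max(abs(y[mid] - x[mid])), 0.01)           # < 1% in passband
  cc <- ccf(y[mid], x[mid], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)           # zero-phase
})

test_that("stride patterns round-trip bit-identically through CSV", {
  tg <- synthetic_muscle_targets(seed = 3)
  dir <- withr::local_tempdir()
  write_stride_patterns(tg, dir)
  back <- load_external_targets(dir)
  expect_setequal(names(back), names(tg))
  for (nm in names(tg)) {
    expect_identical(back[[nm]]$channels, unname(tg[[nm]]$channels))
    expect_identical(back[[nm]]$period, tg[[nm]]$period)
  }
  expect_error(load_external_targets(file.path(dir, "nope.csv")), "not found")
})

test_that("loader clips out-of-range values with a warning", {
  dir <- withr::local_tempdir()
  writeLines(c("# activity: bad", "# period: 1", "# sample_rate: 200",
               "ch01,ch02", "0.5,1.2", "-0.1,0.3"),
             file.path(dir, "bad.csv"))
  expect_warning(out <- load_external_targets(file.path(dir, "bad.csv")),
                 "clipping")
  expect_true(all(out$bad$channels >= 0 & out$bad$channels <= 1))
})
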
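test_that("frequency plans derive the stimuli from the pulse cycles", {
  plan <- frequency_plan()
  expect_equal(plan$stimulus_freqs, c(33.33, 25, 16.67, 12.5, 8.33, 6.25))
  expect_equal(unname(plan$second_harmonic),
               c(33.34, 25, 16.66, 12.5))
  expect_equal(plan$high_freqs, c(33.33, 25))
  # every in-band harmonic coincides with another stimulus
  expect_true(all(vapply(plan$second_harmonic, function(h)
    any(abs(plan$stimulus_freqs - h) <= plan$match_tol), TRUE)))
})

test_that("epoch segmentation floors to whole segments and partitions", {
  rec <- noise_recording(3, duration = 100, seed = 31)
  segs <- segment_epoch(rec, 2)
  expect_length(segs, 50)
  expect_true(all(vapply(segs, function(s) ncol(s$data) == 500, TRUE)))
  rec5 <- noise_recording(3, duration = 5, seed = 32)
  segs5 <- segment_epoch(rec5, 2)
  expect_length(segs5, 2)
  # concatenating reproduces the leading samples
  expect_equal(do.call(cbind, lapply(segs5, function(s) s$data)),
               rec5$data[, 1:1000])
  expect_error(segment_epoch(rec5, 0), "positive")
  expect_error(segment_epoch(rec5, 6), "shorter")
})

test_that("the specificity threshold is the order-statistic midpoint", {
  expect_equal(specificity_threshold(sample(1:50), 0.9), 45.5)
  expect_equal(specificity_threshold(sample(1:50), 1), 50 * (1 + 1e-6))
  # all-equal degenerate input still produces a usable cut
  expect_equal(specificity_threshold(rep(3, 20), 0.9), 3)
})

test_that("calibrated thresholds hit the target specificity exactly", {
  rec <- noise_recording(6, duration = 60, rate = 250, seed = 33)
  segs <- segment_epoch(rec, 2)
  plan <- frequency_plan()
  ts <- calibrate_thresholds(segs, plan, ref_single(6))
  expect_s3_class(ts, "threshold_set")
  expect_equal(attr(ts, "n_segments_used"), 30L)
  expect_equal(ts$n_below, rep(round(0.9 * 30), nrow(ts)))
  expect_true(all(ts$threshold > 0))
  # recount independently via the public per-segment statistic
  f <- 12.5
  vals <- vapply(segs, function(s) {
    spec <- power_spectrum(rereference(s, ref_single(6)), 4)
    sum_relative_power(spec, f, exclude = 6)
  }, 0)
  expect_equal(sum(vals < threshold_for(ts, f)), 27L)
  expect_error(calibrate_thresholds(segs[1:5], plan, ref_single(6)),
               "at least 10")
  expect_error(calibrate_thresholds(segs, plan, ref_single(6),
                                    specificity = 1.5), "0, 1")
})

# build a segment whose sum relative-power is strong at chosen frequencies
composite_segment <- function(freqs, amps, n_channels = 6, seed = 1,
                              noise_sd = 1) {
  set.seed(seed)
  n <- 500
  t <- (0:(n - 1)) / 250
  d <- matrix(stats::rnorm(n_channels * n, sd = noise_sd), n_channels)
  for (j in seq_along(freqs)) {
    a <- runif(n_channels, 0.8, 1.2) * amps[j]
    ph <- runif(n_channels, 0, 2 * pi)
    d <- d + a * sin(outer(ph, 2 * pi * freqs[j] * t, `+`))
  }
  eeg_recording(d, 250, synthetic_montage(n_channels),
                epoch_kind = "evoked")
}

test_that("the two checking standards implement the competitor logic", {
  plan <- frequency_plan()
  # thresholds forged directly: moderate everywhere (the statistic
  # saturates near band_bins per channel, so sums top out around 25 here)
  targets <- plan$stimulus_freqs
  ts <- structure(data.frame(freq = targets, threshold = 10,
                             n_below = NA_integer_),
                  class = c("threshold_set", "data.frame"),
                  specificity = 0.9, n_segments_used = 50L,
                  scheme = ref_single(6), pad_to = 4, halfwidth = 1)

  clean <- composite_segment(12.5, 6, seed = 41)
  for (rule in c("h1", "h1h2")) {
    out <- detect_segment(clean, 12.5, ts, plan, rule, ref_single(6))
    expect_true(out$detected)
    expect_true(any(abs(out$exceeded - 12.5) < 0.05))
  }

  # a non-harmonic competitor above threshold defeats the detection
  comp <- composite_segment(c(12.5, 8.33), c(6, 6), seed = 42)
  expect_false(detect_segment(comp, 12.5, ts, plan, "h1",
                              ref_single(6))$detected)
  expect_false(detect_segment(comp, 12.5, ts, plan, "h1h2",
                              ref_single(6))$detected)

  # second harmonic strong, fundamental weak: only h1h2 detects
  h2only <- composite_segment(25, 6, seed = 43)
  expect_false(detect_segment(h2only, 12.5, ts, plan, "h1",
                              ref_single(6))$detected)
  expect_true(detect_segment(h2only, 12.5, ts, plan, "h1h2",
                             ref_single(6))$detected)
  # ... and the strong 25 Hz component does not count against 12.5 Hz
  # under h1 because the second harmonic is excluded from competitors,
  # yet it is also not enough to detect without the fundamental
  out <- detect_segment(h2only, 12.5, ts, plan, "h1", ref_single(6))
  expect_true(any(abs(out$exceeded - 25) < 0.05))

  # a high-frequency stimulus degenerates h1h2 to h1
  hf <- composite_segment(33.33, 6, seed = 44)
  expect_equal(detect_segment(hf, 33.33, ts, plan, "h1h2",
                              ref_single(6))$detected,
               detect_segment(hf, 33.33, ts, plan, "h1",
                              ref_single(6))$detected)
  expect_error(detect_segment(clean, 40, ts, plan, "h1", ref_single(6)),
               "stimulus")
})

test_that("detection is monotone in the thresholds", {
  plan <- frequency_plan()
  targets <- plan$stimulus_freqs
  seg <- composite_segment(c(12.5, 8.33), c(6, 3), seed = 45)
  mk_ts <- function(thr) structure(
    data.frame(freq = targets, threshold = thr, n_below = NA_integer_),
    class = c("threshold_set", "data.frame"), specificity = 0.9,
    n_segments_used = 50L, scheme = ref_single(6), pad_to = 4,
    halfwidth = 1)
  lo <- detect_segment(seg, 12.5, mk_ts(10), plan, "h1", ref_single(6))
  hi <- detect_segment(seg, 12.5, mk_ts(1e6), plan, "h1", ref_single(6))
  # raising all thresholds can only shrink the exceedance set
  expect_true(all(hi$exceeded %in% lo$exceeded))
  expect_false(hi$detected) # nothing exceeds an absurd threshold
})

test_that("detection accuracy matches a per-segment recount", {
  plan <- frequency_plan()
  rec <- noise_recording(6, duration = 60, seed = 46)
  segs <- segment_epoch(rec, 2)
  ts <- calibrate_thresholds(segs, plan, ref_single(6))
  ev_segs <- lapply(1:10, function(k)
    composite_segment(12.5, 5, seed = 400 + k))
  acc <- detection_accuracy(ev_segs, 12.5, ts, plan, "h1h2", ref_single(6))
  recount <- vapply(ev_segs, function(s)
    detect_segment(s, 12.5, ts, plan, "h1h2", ref_single(6))$detected,
    TRUE)
  expect_equal(acc$overall, mean(recount))
  expect_equal(acc$detected, unname(recount))
  expect_equal(acc$per_freq$n, 10)
  # separable limit: strong targets whose sum sits at the statistic's
  # ceiling are all detected against thresholds no noise band reaches
  strong <- lapply(1:5, function(k)
    composite_segment(12.5, 6, seed = 500 + k))
  ts15 <- structure(data.frame(freq = plan$stimulus_freqs, threshold = 15,
                               n_below = NA_integer_),
                    class = c("threshold_set", "data.frame"),
                    specificity = 0.9, n_segments_used = 50L,
                    scheme = ref_single(6), pad_to = 4, halfwidth = 1)
  acc2 <- detection_accuracy(strong, 12.5, ts15, plan, "h1h2",
                             ref_single(6))
  expect_equal(acc2$overall, 1)
  expect_error(detection_accuracy(list(), 12.5, ts, plan, "h1",
                                  ref_single(6)), "no segments")
})
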
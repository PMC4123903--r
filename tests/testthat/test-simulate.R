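test_that("sinusoid fields validate the source-maximal amplitude", {
  expect_error(sinusoid_field(c(1, 2), c(0, 0), 10, 1), "maximal")
  f <- sinusoid_field(c(2, 1), c(0, 7), 10, 1)
  expect_true(all(f$phases >= 0 & f$phases < 2 * pi))
  expect_equal(f$cycle, 0.1)
})

test_that("closed-form sum power matches hand values and the integral", {
  # identical signals cancel under either reference
  f0 <- sinusoid_field(c(1, 1, 1), c(2, 2, 2), 10, 1)
  expect_equal(sum_power_under_reference(f0, 2), 0)
  # two channels, A = (2, 1), phase difference pi -> (4 + 1 + 4)/2 = 4.5
  f1 <- sinusoid_field(c(2, 1), c(0, pi), 5, 1)
  expect_equal(sum_power_under_reference(f1, 1), 4.5)
  expect_equal(sum_power_under_reference(f1, 2), 4.5)
  # random fields against trapezoid integration of the defining integral
  set.seed(51)
  for (k in 1:100) {
    n <- sample(3:8, 1)
    A <- runif(n)
    A[1] <- max(A) + 0.01
    ph <- runif(n, 0, 2 * pi)
    fld <- sinusoid_field(A, ph, freq = runif(1, 4, 30), source = 1)
    ref <- sample(n, 1)
    expect_equal(sum_power_under_reference(fld, ref),
                 trapz_sum_power(A, ph %% (2 * pi), fld$freq, ref),
                 tolerance = 1e-6)
  }
})

test_that("the forward model builds a decaying traveling-wave field", {
  model <- forward_model(12.5, montage = synthetic_montage(12), source = 3,
                         amplitude = 4, topography_decay = 0.5)
  fld <- model_field(model)
  expect_equal(fld$amplitudes[3], 4)
  expect_equal(which.max(fld$amplitudes), 3L)
  d <- montage_distances(model$montage, 3)
  expect_equal(fld$amplitudes, 4 * exp(-d / 0.5))
  expect_error(forward_model(12.5, rate = 80), "twice")
})

test_that("noise-free synthesis follows the closed-form field difference", {
  m <- synthetic_montage(5)
  model <- forward_model(10, montage = m, source = 2, amplitude = 3,
                         harmonic2_scale = 0, phase_gradient = 0,
                         noise_scale = 0, topography_decay = Inf)
  rec <- synthesize_evoked(model, duration = 1)
  # equal amplitudes (infinite decay length) and equal phases: referencing
  # at the last channel cancels everything
  expect_lt(max(abs(rec$data)), 1e-12)
  model2 <- forward_model(10, montage = m, source = 2, amplitude = 3,
                          harmonic2_scale = 0, phase_gradient = 0,
                          noise_scale = 0, topography_decay = 0.7)
  rec2 <- synthesize_evoked(model2, duration = 1)
  fld <- model_field(model2)
  t <- (0:249) / 250
  for (i in 1:5) {
    expected <- (fld$amplitudes[i] - fld$amplitudes[5]) *
      sin(2 * pi * 10 * t)
    expect_equal(rec2$data[i, 1:250], expected, tolerance = 1e-9)
  }
  expect_equal(rec2$reference$index, 5L)
  expect_equal(rec2$stimulus_freq, 10)
})

test_that("synthesis is reproducible under a fixed seed", {
  model <- forward_model(12.5, montage = synthetic_montage(8))
  a <- synthesize_evoked(model, 2, seed = 61)
  b <- synthesize_evoked(model, 2, seed = 61)
  expect_identical(a$data, b$data)
  c <- synthesize_evoked(model, 2, seed = 62)
  expect_false(identical(a$data, c$data))
  s1 <- synthesize_spontaneous(model, 2, seed = 61)
  expect_equal(s1$epoch_kind, "spontaneous")
  expect_true(is.na(s1$stimulus_freq))
})

test_that("the evoked spectrum peaks at the stimulus bin in every channel", {
  # noise-free fundamental-only field: every channel whose vertex-referenced
  # amplitude is non-negligible peaks exactly at the stimulus bin
  m <- synthetic_montage(16)
  model <- forward_model(12.5, montage = m, noise_scale = 0,
                         harmonic2_scale = 0)
  rec <- synthesize_evoked(model, 20, seed = 63)
  spec <- power_spectrum(rec)
  amp <- apply(rec$data, 1, function(x) max(abs(x)))
  for (i in which(amp > 1e-6)) {
    expect_equal(spec$freqs[which.max(spec$power[i, ])], 12.5)
  }
  # with default background noise the channels nearest the source still
  # peak at the stimulus inside the analysis band
  rec2 <- synthesize_evoked(forward_model(12.5, montage = m), 20, seed = 65)
  spec2 <- power_spectrum(rec2)
  inband <- spec2$freqs >= 10 & spec2$freqs <= 15
  for (i in c(model$source, nearest_channels(m, model$source, 2))) {
    expect_equal(spec2$freqs[inband][which.max(spec2$power[i, inband])],
                 12.5)
  }
})

test_that("an out-of-band second harmonic is dropped with a notice", {
  model <- forward_model(33.33, montage = synthetic_montage(6),
                         noise_scale = 0)
  expect_message(synthesize_evoked(model, 1), "cutoff")
  model2 <- forward_model(12.5, montage = synthetic_montage(6),
                          noise_scale = 0)
  expect_silent(synthesize_evoked(model2, 1))
})

test_that("spontaneous epochs behave like stationary background noise", {
  model <- forward_model(12.5, montage = synthetic_montage(26))
  sp <- synthesize_spontaneous(model, 50, seed = 64)
  # noise RMS is calibrated per channel (vertex reference doubles power)
  rms <- apply(sp$data[1:25, ], 1, stats::sd)
  expect_equal(mean(rms), sqrt(2) * model$noise_scale, tolerance = 0.1)
  # sum relative-power at stimulus frequencies is about one per channel
  spec <- power_spectrum(sp)
  rel <- vapply(c(8.33, 12.5, 25), function(f)
    sum_relative_power(spec, f, exclude = 26) / 25, 0)
  expect_equal(mean(rel), 1, tolerance = 0.15)
  # zero noise scale gives the all-zero recording
  model0 <- forward_model(12.5, montage = synthetic_montage(4),
                          amplitude = 0, noise_scale = 0)
  expect_equal(max(abs(synthesize_spontaneous(model0, 1)$data)), 0)
})

test_that("the Monte-Carlo closed form matches trial-by-trial integration", {
  n <- 3; trials <- 60
  law_a <- function(k) stats::runif(k)
  law_p <- function(k) stats::runif(k, 0, 2 * pi)
  res <- monte_carlo_reference_advantage(n, trials, seed = 71,
                                         amplitude_law = law_a,
                                         phase_law = law_p)
  # oracle: replay the documented draw order (all amplitude rows, then all
  # phase rows), then integrate numerically instead of using closed form
  set.seed(71)
  A <- t(vapply(seq_len(trials), function(i) law_a(n), numeric(n)))
  PH <- t(vapply(seq_len(trials), function(i) law_p(n), numeric(n)))
  per_trial <- numeric(trials)
  for (tr in seq_len(trials)) {
    a <- A[tr, ]; p <- PH[tr, ]
    mx <- which.max(a)
    a[c(1, mx)] <- a[c(mx, 1)]
    P <- vapply(seq_len(n), function(r)
      trapz_sum_power(a, p, freq = 10, ref = r, n_grid = 3000), 0)
    per_trial[tr] <- mean(P[1] - P[-1] > 0)
  }
  expect_equal(res$probability, mean(per_trial), tolerance = 1e-9)
})

test_that("degenerate equal fields never show a strict advantage", {
  res <- monte_carlo_reference_advantage(5, 40, seed = 72,
    amplitude_law = function(n) rep(1, n),
    phase_law = function(n) rep(0.5, n))
  expect_equal(res$probability, 0)
})

test_that("seeded Monte-Carlo runs are reproducible and stable", {
  a <- monte_carlo_reference_advantage(20, 2000, seed = 73)
  b <- monte_carlo_reference_advantage(20, 2000, seed = 73)
  expect_identical(a$probability, b$probability)
  c <- monte_carlo_reference_advantage(20, 2000, seed = 74)
  expect_lt(abs(a$probability - c$probability),
            3 * sqrt(a$se^2 + c$se^2) + 1e-3)
  one <- monte_carlo_reference_advantage(20, 500, seed = 75,
                                         comparison = "one_random_m")
  expect_true(one$probability >= 0 && one$probability <= 1)
})
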
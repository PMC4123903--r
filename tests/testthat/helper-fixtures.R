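# Fixtures are generated in code; sizes are kept small for unit tests
# (a handful of channels, seconds of data) while the acceptance checks
# run the full default conditions.

# white-noise recording on a small synthetic montage
noise_recording <- function(n_channels = 4, duration = 2, rate = 250,
                            seed = 1, sd = 1) {
  set.seed(seed)
  m <- synthetic_montage(n_channels)
  eeg_recording(matrix(stats::rnorm(n_channels * duration * rate, sd = sd),
                       n_channels), rate, m)
}

# multichannel sinusoid + white noise with explicit amplitudes/phases
sine_recording <- function(amps, phases, freq, duration = 2, rate = 250,
                           noise_sd = 0, seed = 1) {
  set.seed(seed)
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  d <- t(vapply(seq_along(amps), function(i)
    amps[i] * sin(2 * pi * freq * t + phases[i]), numeric(n)))
  if (noise_sd > 0) d <- d + matrix(stats::rnorm(length(d), sd = noise_sd),
                                    nrow(d))
  eeg_recording(d, rate, synthetic_montage(length(amps)))
}

# hand-built spectrum object for band-arithmetic tests
toy_spectrum <- function(power, resolution) {
  power <- rbind(power)
  structure(
    list(power = power, resolution = resolution,
         freqs = (seq_len(ncol(power)) - 1) * resolution,
         n_channels = nrow(power),
         labels = sprintf("E%d", seq_len(nrow(power))),
         reference = ref_as_recorded()),
    class = "eeg_spectrum"
  )
}

# single-frequency DFT at one bin (Goertzel-style reference for the FFT)
direct_dft_power <- function(x, bin, n_total) {
  t <- seq_along(x) - 1
  Mod(sum(x * exp(-2i * pi * bin * t / n_total)))^2
}

# numerical-integration reference for the per-cycle mean sum power
trapz_sum_power <- function(A, ph, freq, ref, n_grid = 2000) {
  T <- 1 / freq
  t <- seq(0, T, length.out = n_grid)
  total <- 0
  for (i in seq_along(A)) {
    if (i == ref) next
    s <- A[i] * sin(2 * pi * freq * t + ph[i]) -
      A[ref] * sin(2 * pi * freq * t + ph[ref])
    y <- s^2
    total <- total + sum((y[-1] + y[-n_grid]) / 2 * diff(t)) / T
  }
  total
}

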
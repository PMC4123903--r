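#' Zero-padded FFT power spectrum
#'
#' Transforms every channel with a plain (rectangular-window) FFT after
#' appending zeros up to `pad_to_seconds`, and returns the one-sided
#' squared-magnitude spectrum on the uniform grid `k / pad_to_seconds` Hz.
#' No detrending or scaling is applied: power is the raw `|X(k)|^2`, which
#' cancels in every ratio the package computes. With no padding the bin
#' width is the reciprocal of the epoch duration (a 100 s epoch gives
#' 0.01 Hz bins); padding a 2 s segment to 4 s gives 0.25 Hz bins.
#'
#' @param rec An [eeg_recording()].
#' @param pad_to_seconds Total duration (s) after zero padding, or `NULL`
#'   for no padding. Must be at least the recording duration.
#' @return An object of class `eeg_spectrum` with elements `power`
#'   (channels x bins, bin 0 = DC), `resolution` (Hz), `freqs`,
#'   `n_channels`, `labels` and the recording's `reference`.
#' @export
power_spectrum <- function(rec, pad_to_seconds = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- ncol(rec$data)
  n_pad <- pad_length(n, rec$rate, pad_to_seconds)
  X <- stats::mvfft(pad_columns(t(rec$data), n_pad))
  nb <- floor(n_pad / 2) + 1L
  power <- t(Mod(X[seq_len(nb), , drop = FALSE])^2)
  res <- rec$rate / n_pad
  structure(
    list(power = power, resolution = res,
         freqs = (seq_len(nb) - 1) * res,
         n_channels = nrow(power), labels = rec$montage$labels,
         reference = rec$reference),
    class = "eeg_spectrum"
  )
}

#' @export
print.eeg_spectrum <- function(x, ...) {
  cat(sprintf("EEG power spectrum: %d channels, %d bins @ %g Hz resolution\n",
              x$n_channels, length(x$freqs), x$resolution))
  cat("  reference:", format_scheme(x$reference), "\n")
  invisible(x)
}

pad_length <- function(n, rate, pad_to_seconds) {
  if (is.null(pad_to_seconds)) return(n)
  n_pad <- round(pad_to_seconds * rate)
  if (n_pad < n)
    stop(sprintf("pad_to_seconds (%g s) is shorter than the signal (%g s)",
                 pad_to_seconds, n / rate))
  n_pad
}

pad_columns <- function(m, n_pad) {
  if (n_pad == nrow(m)) return(m)
  rbind(m, matrix(0, n_pad - nrow(m), ncol(m)))
}

# indices of the target bin and the surrounding band on a spectrum grid
band_indices <- function(freqs, resolution, f, halfwidth) {
  if (f - halfwidth < resolution - 1e-9)
    stop(sprintf(
      "band [%g, %g] Hz reaches below the first non-DC bin (%g Hz)",
      f - halfwidth, f + halfwidth, resolution))
  target <- which.min(abs(freqs - f))
  band <- which(freqs >= f - halfwidth - 1e-9 &
                  freqs <= f + halfwidth + 1e-9)
  if (length(band) == 0L) stop("empty frequency band")
  list(target = target, band = band)
}

#' Narrowband relative power
#'
#' The power at the bin nearest `f` divided by the mean power over all
#' bins whose centre lies in the closed interval `[f - halfwidth,
#' f + halfwidth]` (the target bin included). This is the narrowband SNR
#' used as the SSVEP indicator; it is invariant to rescaling the signal.
#' A channel whose band power is identically zero (e.g. the reference
#' electrode itself) returns 0.
#'
#' @param spec An `eeg_spectrum` from [power_spectrum()].
#' @param f Target frequency in Hz; `f - halfwidth` must not reach below
#'   the first non-DC bin.
#' @param channel 1-based channel index.
#' @param halfwidth Band half-width in Hz (default 1).
#' @return A non-negative scalar.
#' @export
relative_power <- function(spec, f, channel, halfwidth = 1) {
  stopifnot(inherits(spec, "eeg_spectrum"))
  channel <- check_channel(channel, spec$n_channels)
  idx <- band_indices(spec$freqs, spec$resolution, f, halfwidth)
  denom <- mean(spec$power[channel, idx$band])
  if (denom == 0) return(0)
  unname(spec$power[channel, idx$target] / denom)
}

#' Sum relative-power over electrodes
#'
#' Sums [relative_power()] at `f` over all channels, optionally excluding
#' one channel — by convention the current reference electrode, whose
#' re-referenced signal is identically zero (its relative power is the
#' indeterminate 0/0 and is defined to contribute nothing).
#'
#' @inheritParams relative_power
#' @param exclude Channel index to exclude, or `NULL`.
#' @return A non-negative scalar.
#' @export
sum_relative_power <- function(spec, f, exclude = NULL, halfwidth = 1) {
  stopifnot(inherits(spec, "eeg_spectrum"))
  idx <- band_indices(spec$freqs, spec$resolution, f, halfwidth)
  chans <- seq_len(spec$n_channels)
  if (!is.null(exclude))
    chans <- setdiff(chans, check_channel(exclude, spec$n_channels))
  band <- spec$power[chans, idx$band, drop = FALSE]
  denom <- rowMeans(band)
  num <- spec$power[chans, idx$target]
  sum(ifelse(denom == 0, 0, num / denom))
}

#' SSVEP gain
#'
#' Ratio of the evoked-epoch sum relative-power to the spontaneous-epoch
#' baseline at the same frequency and reference. Values near 1 at
#' non-stimulus frequencies indicate that the noise level is unchanged;
#' values well above 1 at the stimulus frequency quantify the evoked
#' response.
#'
#' @param evoked_sum Sum relative-power from the evoked epoch.
#' @param spontaneous_sum Baseline sum relative-power from the spontaneous
#'   epoch (must be positive).
#' @return `evoked_sum / spontaneous_sum`.
#' @export
ssvep_gain <- function(evoked_sum, spontaneous_sum) {
  if (!all(spontaneous_sum > 0))
    stop("spontaneous baseline must be positive")
  evoked_sum / spontaneous_sum
}

#' Export a spectrum as delimited text
#'
#' Writes a tab-separated table with the bin frequency in the first
#' column and one column of absolute power per channel.
#'
#' @param spec An `eeg_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_txt <- function(spec, path) {
  stopifnot(inherits(spec, "eeg_spectrum"))
  tab <- cbind(freq = spec$freqs, t(spec$power))
  colnames(tab) <- c("freq", spec$labels)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
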
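## Internal fast path.
##
## The FFT is linear, so re-referencing commutes with it: the spectrum of
## channel i under single-electrode reference r is X_i - X_r, under the
## common average X_i - mean_j(X_j), and under a pair average
## X_i - (X_a + X_b)/2, where X_i is the transform of the channel as
## stored. The exhaustive scan and the segment-wise detection pipeline
## therefore compute the complex transform of each channel once and derive
## every candidate reference algebraically. Equivalence with the direct
## route (rereference() then power_spectrum()) is part of the test suite.

# complex one-sided FFT of all channels restricted to the band around f
band_fft <- function(data, rate, pad_to_seconds, f, halfwidth = 1) {
  n_pad <- pad_length(ncol(data), rate, pad_to_seconds)
  res <- rate / n_pad
  nb <- floor(n_pad / 2) + 1L
  freqs <- (seq_len(nb) - 1) * res
  idx <- band_indices(freqs, res, f, halfwidth)
  X <- stats::mvfft(pad_columns(t(data), n_pad))[idx$band, , drop = FALSE]
  list(X = X, target_row = match(idx$target, idx$band), freqs = freqs[idx$band])
}

# apply a reference transform to a complex bins x channels matrix
apply_ref_fft <- function(X, scheme, single_index = NULL) {
  if (!is.null(single_index))
    return(X - X[, single_index])
  switch(scheme$kind,
    as_recorded = X,
    single_electrode = X - X[, scheme$index],
    common_average = X - rowMeans(X),
    electrode_pair_average = X - (X[, scheme$index_a] + X[, scheme$index_b]) / 2,
    stop("unsupported scheme kind for spectral transform: ", scheme$kind))
}

# sum of per-channel target-bin / band-mean power ratios, excluding a channel
sum_relpow_band <- function(Xref, target_row, exclude = NULL) {
  P <- Mod(Xref)^2
  denom <- colMeans(P)
  num <- P[target_row, ]
  r <- ifelse(denom == 0, 0, num / denom)
  if (!is.null(exclude)) r <- r[-exclude]
  sum(r)
}

#' Exhaustive optimum-reference scan
#'
#' For each candidate electrode `r`, re-references the evoked recording to
#' `r`, computes the spectrum, and evaluates the sum relative-power at the
#' stimulus frequency over all other electrodes. The candidate maximizing
#' the statistic is the optimum reference for that frequency; exact ties
#' are broken by the lowest channel index. The scan result is invariant to
#' the recording's original single-electrode reference (re-referencing is
#' transitive). The scan uses the linearity of the FFT to transform each
#' channel once; this is algebraically identical to re-referencing in the
#' time domain.
#'
#' @param evoked An [eeg_recording()] of the evoked epoch (any current
#'   reference).
#' @param f Stimulus frequency in Hz.
#' @param pad_to Total duration in seconds after zero padding, or `NULL`
#'   to transform the epoch as is.
#' @param candidates Integer vector of channel indices to scan (default:
#'   all channels).
#' @param halfwidth Relative-power band half-width in Hz.
#' @return An object of class `ref_scan` with fields `per_candidate`
#'   (named by channel index), `optimum`, `optimum_value`, `target_freq`
#'   and `candidate_set`.
#' @export
find_optimum_reference <- function(evoked, f, pad_to = NULL,
                                   candidates = NULL, halfwidth = 1) {
  stopifnot(inherits(evoked, "eeg_recording"))
  n <- nrow(evoked$data)
  if (n < 2L) stop("reference scan needs at least 2 channels")
  if (is.null(candidates)) candidates <- seq_len(n)
  candidates <- vapply(candidates, check_channel, 0L, n = n)
  if (length(candidates) == 0L) stop("empty candidate set")
  bf <- band_fft(evoked$data, evoked$rate, pad_to, f, halfwidth)
  vals <- vapply(candidates, function(r)
    sum_relpow_band(bf$X - bf$X[, r], bf$target_row, exclude = r), 0)
  names(vals) <- candidates
  best <- which.max(vals) # first maximum = lowest candidate index on ties
  structure(
    list(per_candidate = vals,
         optimum = candidates[best],
         optimum_value = vals[[best]],
         target_freq = f,
         candidate_set = candidates),
    class = "ref_scan"
  )
}

#' @export
print.ref_scan <- function(x, ...) {
  cat(sprintf("Reference scan at %g Hz over %d candidates\n",
              x$target_freq, length(x$candidate_set)))
  cat(sprintf("  optimum reference: channel %d (sum relative-power %.4g)\n",
              x$optimum, x$optimum_value))
  invisible(x)
}

#' @export
plot.ref_scan <- function(x, ...) {
  graphics::plot(x$candidate_set, x$per_candidate, type = "h",
                 xlab = "candidate reference channel",
                 ylab = "sum relative-power",
                 main = sprintf("Reference scan, %g Hz", x$target_freq), ...)
  graphics::points(x$optimum, x$optimum_value, pch = 19, col = 2)
  invisible(x)
}

#' Spontaneous baseline under a chosen reference
#'
#' Re-references the spontaneous epoch to the given electrode and returns
#' the sum relative-power at `f` over the remaining electrodes — the
#' denominator of the SSVEP gain under that (typically optimum) reference.
#'
#' @param spontaneous An [eeg_recording()] of the spontaneous epoch.
#' @param f Frequency in Hz.
#' @param ref Reference channel index.
#' @param pad_to Zero-padding duration in seconds or `NULL`.
#' @param halfwidth Band half-width in Hz.
#' @return A non-negative scalar.
#' @export
baseline_under_reference <- function(spontaneous, f, ref, pad_to = NULL,
                                     halfwidth = 1) {
  stopifnot(inherits(spontaneous, "eeg_recording"))
  ref <- check_channel(ref, nrow(spontaneous$data), "reference")
  spec <- power_spectrum(rereference(spontaneous, ref_single(ref)), pad_to)
  sum_relative_power(spec, f, exclude = ref, halfwidth = halfwidth)
}

#' Export a reference scan as delimited text
#'
#' @param scan A `ref_scan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_txt <- function(scan, path) {
  stopifnot(inherits(scan, "ref_scan"))
  utils::write.table(
    data.frame(channel = scan$candidate_set,
               sum_relative_power = as.numeric(scan$per_candidate)),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
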
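#' Stimulus-frequency plan
#'
#' Describes the stimulation frequencies and which harmonics are available
#' for detection. The default plan derives the six frequencies from the
#' pulse-generator cycles 30, 40, 60, 80, 120 and 160 ms (the generator
#' steps in 1 ms), i.e. 33.33, 25, 16.67, 12.5, 8.33 and 6.25 Hz, spanning
#' the beta, alpha and theta bands. Second harmonics are defined exactly
#' for frequencies with `2 f` at or below the recording bandwidth cutoff
#' (49 Hz, chosen to exclude 50 Hz line noise); stimuli whose second
#' harmonic exceeds the cutoff (33.33 and 25 Hz by default) are detected
#' from the first harmonic only. In the default plan every in-band second
#' harmonic coincides (within 0.05 Hz) with another stimulus frequency.
#'
#' @param stimulus_freqs Stimulus frequencies in Hz; when `NULL` they are
#'   computed as `round(1000 / cycles_ms, 2)`.
#' @param cycles_ms Pulse cycles in milliseconds (used only when
#'   `stimulus_freqs` is `NULL`).
#' @param cutoff Recording bandwidth cutoff in Hz.
#' @param match_tol Frequency-matching tolerance in Hz used when a second
#'   harmonic coincides with another stimulus frequency.
#' @return An object of class `frequency_plan` with fields
#'   `stimulus_freqs`, `second_harmonic` (named by the fundamental),
#'   `high_freqs`, `cutoff` and `match_tol`.
#' @export
frequency_plan <- function(stimulus_freqs = NULL,
                           cycles_ms = c(30, 40, 60, 80, 120, 160),
                           cutoff = 49, match_tol = 0.05) {
  if (is.null(stimulus_freqs))
    stimulus_freqs <- round(1000 / cycles_ms, 2)
  if (anyDuplicated(stimulus_freqs)) stop("duplicate stimulus frequencies")
  h2 <- 2 * stimulus_freqs
  keep <- h2 <= cutoff
  second_harmonic <- h2[keep]
  names(second_harmonic) <- as.character(stimulus_freqs[keep])
  structure(
    list(stimulus_freqs = stimulus_freqs,
         second_harmonic = second_harmonic,
         high_freqs = stimulus_freqs[!keep],
         cutoff = cutoff, match_tol = match_tol),
    class = "frequency_plan"
  )
}

#' @export
print.frequency_plan <- function(x, ...) {
  cat("Frequency plan:", paste(x$stimulus_freqs, collapse = ", "), "Hz\n")
  cat("  first-harmonic-only (2f >", x$cutoff, "Hz):",
      paste(x$high_freqs, collapse = ", "), "Hz\n")
  invisible(x)
}

# frequencies that need their own calibrated threshold: the stimuli plus
# any in-band second harmonic that does not coincide with a stimulus
plan_target_freqs <- function(plan) {
  extra <- plan$second_harmonic[!vapply(plan$second_harmonic, function(h)
    any(abs(plan$stimulus_freqs - h) <= plan$match_tol), TRUE)]
  c(plan$stimulus_freqs, unname(extra))
}

#' Order-statistic threshold at a fixed specificity
#'
#' Places a threshold over a sample of calibration values so that a
#' fraction `specificity` of them falls strictly below it: with
#' `k = round(specificity * length(values))` the threshold is the midpoint
#' of the k-th and (k+1)-th order statistics; `k = n` gives a value just
#' above the maximum and `k = 0` just below the minimum. For the sample
#' `1..50` at specificity 0.90 this yields 45.5.
#'
#' @param values Numeric calibration values.
#' @param specificity Target fraction in (0, 1].
#' @return The threshold.
#' @export
specificity_threshold <- function(values, specificity) {
  n <- length(values)
  k <- round(specificity * n)
  s <- sort(values)
  if (k >= n) s[n] * (1 + 1e-6)
  else if (k < 1L) s[1] * (1 - 1e-6)
  else (s[k] + s[k + 1L]) / 2
}

# snap a frequency onto the closest plan target within the match tolerance
snap_freq <- function(f, freqs, tol) {
  i <- which.min(abs(freqs - f))
  if (abs(freqs[i] - f) <= tol) freqs[i] else f
}

## segment-wise spectral workhorse ---------------------------------------

segment_fft <- function(data, rate, pad_to_seconds) {
  n_pad <- pad_length(ncol(data), rate, pad_to_seconds)
  res <- rate / n_pad
  nb <- floor(n_pad / 2) + 1L
  list(X = stats::mvfft(pad_columns(t(data), n_pad))[seq_len(nb), ,
                                                     drop = FALSE],
       freqs = (seq_len(nb) - 1) * res, res = res)
}

# per-frequency reference used by a scheme (dynamic schemes pick the
# frequency's own optimum electrode; a harmonic falls back to its
# fundamental's entry)
scheme_at_freq <- function(scheme, f, plan) {
  if (scheme$kind != "optimum") return(scheme)
  r <- tryCatch(optimum_ref_for(scheme, f, plan$match_tol),
                error = function(e) NULL)
  if (is.null(r))
    r <- optimum_ref_for(scheme, f / 2, plan$match_tol)
  ref_single(r)
}

# sum relative-power of one transformed segment at frequency f
relpow_at <- function(sf, f, scheme, halfwidth = 1) {
  idx <- band_indices(sf$freqs, sf$res, f, halfwidth)
  Xb <- apply_ref_fft(sf$X[idx$band, , drop = FALSE], scheme)
  excl <- if (scheme$kind == "single_electrode") scheme$index else NULL
  sum_relpow_band(Xb, match(idx$target, idx$band), exclude = excl)
}

# named vector of sum relative-powers of a segment at several frequencies
relpow_table <- function(segment, freqs, scheme, plan, pad_to, halfwidth = 1) {
  sf <- segment_fft(segment$data, segment$rate, pad_to)
  vals <- vapply(freqs, function(f)
    relpow_at(sf, f, scheme_at_freq(scheme, f, plan), halfwidth), 0)
  names(vals) <- as.character(freqs)
  vals
}

#' Split an epoch into fixed-length segments
#'
#' Cuts the recording into `floor(duration / seg_seconds)` non-overlapping
#' contiguous segments; any remainder is discarded.
#'
#' @param rec An [eeg_recording()].
#' @param seg_seconds Segment length in seconds (default 2).
#' @return A list of [eeg_recording()] segments.
#' @export
segment_epoch <- function(rec, seg_seconds = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (seg_seconds <= 0) stop("seg_seconds must be positive")
  len <- round(seg_seconds * rec$rate)
  n_seg <- floor(ncol(rec$data) / len)
  if (n_seg < 1L)
    stop(sprintf("epoch (%g s) is shorter than one %g s segment",
                 rec_duration(rec), seg_seconds))
  lapply(seq_len(n_seg), function(k) {
    out <- rec
    out$data <- rec$data[, (k - 1L) * len + seq_len(len), drop = FALSE]
    out
  })
}

#' Calibrate detection thresholds at a fixed specificity
#'
#' For each target frequency of the plan (the stimulus frequencies plus
#' any in-band second harmonic that does not coincide with one), computes
#' the sum relative-power of every spontaneous segment under the given
#' reference scheme and places the threshold so that a fraction
#' `specificity` of the calibration segments falls strictly below it: with
#' `k = round(specificity * n)`, the threshold is the midpoint between the
#' k-th and (k+1)-th smallest values (or just above the maximum when
#' `k = n`). With 50 segments and the default 0.90 this leaves exactly 45
#' segments below each threshold.
#'
#' @param segments List of spontaneous [eeg_recording()] segments (at
#'   least 10), or a single recording which is then cut into 2 s segments.
#' @param plan A [frequency_plan()].
#' @param scheme A `ref_scheme`; for the dynamic scheme (kind
#'   `"optimum"`) each frequency is calibrated under its own optimum
#'   electrode.
#' @param specificity Target fraction of calibration segments below the
#'   threshold, in (0, 1].
#' @param pad_to Zero-padding duration in seconds applied to each segment
#'   before the FFT (default 4).
#' @param halfwidth Band half-width in Hz.
#' @return An object of class `threshold_set`: a data frame with columns
#'   `freq`, `threshold`, `n_below`, plus attributes `specificity`,
#'   `n_segments_used` and `scheme`.
#' @export
calibrate_thresholds <- function(segments, plan, scheme, specificity = 0.9,
                                 pad_to = 4, halfwidth = 1) {
  if (inherits(segments, "eeg_recording"))
    segments <- segment_epoch(segments, 2)
  n <- length(segments)
  if (n < 10L) stop("threshold calibration needs at least 10 segments")
  if (specificity <= 0 || specificity > 1)
    stop("specificity must be in (0, 1]")
  targets <- plan_target_freqs(plan)
  tab <- vapply(segments, relpow_table, numeric(length(targets)),
                freqs = targets, scheme = scheme, plan = plan,
                pad_to = pad_to, halfwidth = halfwidth)
  tab <- matrix(tab, nrow = length(targets)) # freqs x segments
  thr <- apply(tab, 1L, specificity_threshold, specificity = specificity)
  n_below <- vapply(seq_along(targets),
                    function(i) sum(tab[i, ] < thr[i]), 0L)
  if (any(apply(tab, 1L, function(v) length(unique(v)) == 1L)))
    message("degenerate calibration: all segment values equal at some frequency")
  out <- data.frame(freq = targets, threshold = thr, n_below = n_below)
  structure(out, class = c("threshold_set", "data.frame"),
            specificity = specificity, n_segments_used = n,
            scheme = scheme, pad_to = pad_to, halfwidth = halfwidth)
}

#' Look up the calibrated threshold for a frequency
#'
#' @param thresholds A `threshold_set`.
#' @param f Frequency in Hz, matched within `tol`.
#' @param tol Matching tolerance in Hz.
#' @return The threshold value.
#' @export
threshold_for <- function(thresholds, f, tol = 0.05) {
  stopifnot(inherits(thresholds, "threshold_set"))
  i <- which.min(abs(thresholds$freq - f))
  if (abs(thresholds$freq[i] - f) > tol)
    stop(sprintf("no threshold calibrated for %g Hz", f))
  thresholds$threshold[i]
}

#' Detect an SSVEP in one segment
#'
#' Applies one of the two checking standards to a 2 s evoked segment. Let
#' `R(g)` be the segment's sum relative-power at frequency `g` under the
#' scheme, and `thr(g)` the calibrated threshold. The competitor set is
#' the stimulus frequencies other than the true frequency and its second
#' harmonic (which, in the default plan, coincides with another stimulus
#' frequency and is matched by value).
#'
#' * rule `"h1"` (first harmonic only): detected iff
#'   `R(true_f) > thr(true_f)` and every competitor `g` has
#'   `R(g) <= thr(g)`.
#' * rule `"h1h2"`: for stimuli whose second harmonic is recorded,
#'   detected iff `R(true_f) > thr(true_f)` **or**
#'   `R(2 true_f) > thr(2 true_f)`, with the same competitor condition;
#'   for high-frequency stimuli (second harmonic above the cutoff) the
#'   rule degenerates to `"h1"`.
#'
#' @param segment An evoked [eeg_recording()] segment.
#' @param true_f The stimulus frequency the segment was recorded under.
#' @param thresholds A `threshold_set` calibrated under `scheme`.
#' @param plan A [frequency_plan()].
#' @param rule `"h1"` or `"h1h2"`.
#' @param scheme A `ref_scheme`.
#' @param pad_to Zero-padding duration in seconds (must match the
#'   calibration).
#' @param halfwidth Band half-width in Hz.
#' @return An object of class `detection_outcome`: list with `detected`,
#'   `true_freq`, `rule`, `exceeded` (frequencies whose sum
#'   relative-power exceeded threshold) and `relpow`.
#' @export
detect_segment <- function(segment, true_f, thresholds, plan,
                           rule = c("h1", "h1h2"), scheme, pad_to = 4,
                           halfwidth = 1) {
  rule <- match.arg(rule)
  stopifnot(inherits(plan, "frequency_plan"))
  true_f <- snap_freq(true_f, plan$stimulus_freqs, plan$match_tol)
  if (!any(abs(plan$stimulus_freqs - true_f) <= plan$match_tol))
    stop("true_f is not a stimulus frequency of the plan")
  targets <- plan_target_freqs(plan)
  r <- relpow_table(segment, targets, scheme, plan, pad_to, halfwidth)
  thr <- vapply(targets, threshold_for, 0, thresholds = thresholds,
                tol = plan$match_tol)
  over <- r > thr
  exceeded <- targets[over]

  harmonic <- if (!(true_f %in% plan$high_freqs))
    snap_freq(2 * true_f, targets, plan$match_tol) else NA_real_
  is_true <- abs(targets - true_f) <= plan$match_tol
  is_h2 <- if (is.na(harmonic)) rep(FALSE, length(targets))
           else abs(targets - harmonic) <= plan$match_tol
  competitor <- vapply(targets, function(g)
    any(abs(plan$stimulus_freqs - g) <= plan$match_tol), TRUE) &
    !is_true & !is_h2
  ok_comp <- !any(over[competitor])
  first_hit <- any(over[is_true])
  detected <- if (rule == "h1" || is.na(harmonic)) {
    first_hit && ok_comp
  } else {
    (first_hit || any(over[is_h2])) && ok_comp
  }
  structure(
    list(detected = detected, true_freq = true_f, rule = rule,
         exceeded = exceeded, relpow = r),
    class = "detection_outcome"
  )
}

#' @export
print.detection_outcome <- function(x, ...) {
  cat(sprintf("Segment at %g Hz, rule %s: %s\n", x$true_freq, x$rule,
              if (x$detected) "detected" else "not detected"))
  if (length(x$exceeded))
    cat("  exceeded thresholds at:", paste(x$exceeded, collapse = ", "),
        "Hz\n")
  invisible(x)
}

#' Detection accuracy over labelled segments
#'
#' Applies [detect_segment()] to every segment and tabulates the fraction
#' detected per true frequency and pooled.
#'
#' @param segments List of evoked [eeg_recording()] segments.
#' @param true_f Stimulus frequency per segment (scalar recycled, or a
#'   vector of `length(segments)`).
#' @inheritParams detect_segment
#' @return A list of class `detection_accuracy` with `per_freq` (data
#'   frame `freq`, `n`, `accuracy`), `overall`, and the logical vector
#'   `detected`.
#' @export
detection_accuracy <- function(segments, true_f, thresholds, plan,
                               rule = c("h1", "h1h2"), scheme, pad_to = 4,
                               halfwidth = 1) {
  rule <- match.arg(rule)
  if (length(segments) == 0L) stop("no segments supplied")
  true_f <- rep_len(true_f, length(segments))
  det <- mapply(function(s, f)
    detect_segment(s, f, thresholds, plan, rule, scheme, pad_to,
                   halfwidth)$detected,
    segments, true_f)
  per <- stats::aggregate(det, by = list(freq = true_f), FUN = mean)
  cnt <- stats::aggregate(det, by = list(freq = true_f), FUN = length)
  structure(
    list(per_freq = data.frame(freq = per$freq, n = cnt$x,
                               accuracy = per$x),
         overall = mean(det), detected = det, rule = rule),
    class = "detection_accuracy"
  )
}

#' @export
print.detection_accuracy <- function(x, ...) {
  cat(sprintf("Detection accuracy (rule %s): %.3f overall\n",
              x$rule, x$overall))
  print(x$per_freq, row.names = FALSE)
  invisible(x)
}
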
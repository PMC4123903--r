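#' Fit the dynamic reference-selection model
#'
#' The calibration stage of dynamic reference selection, bundled as a
#' model fit. For every stimulus frequency with an evoked epoch, the
#' optimum reference electrode is found by exhaustive scan of the evoked
#' sum relative-power; the spontaneous epoch is then re-baselined under
#' each frequency's optimum reference and under the static comparison
#' schemes (vertex/`Cz`, common average, linked mastoids), full-epoch
#' SSVEP and noise gains are computed, and per-frequency detection
#' thresholds are calibrated at the requested specificity on 2 s
#' spontaneous segments. [predict.ds_ssvep()] applies the fitted
#' thresholds to new evoked segments.
#'
#' @param evoked A single evoked [eeg_recording()] (with `stimulus_freq`
#'   set) or a list of them, one per stimulus frequency.
#' @param spontaneous A spontaneous [eeg_recording()] sharing the montage
#'   and rate.
#' @param plan A [frequency_plan()].
#' @param schemes Character vector of reference schemes to evaluate,
#'   subset of `c("optimum", "cz", "avg", "mastoid")`.
#' @param seg_seconds Segment length for threshold calibration (s).
#' @param pad_seconds Zero-padded segment duration for the segment FFTs
#'   (s).
#' @param specificity Calibration specificity in (0, 1].
#' @param candidates Candidate channels for the reference scan (default
#'   all; see [reduced_candidates()]).
#' @param cz_channel Channel index of the vertex reference (default: the
#'   montage's last channel).
#' @param mastoid_pair Length-2 channel indices of the mastoid pair
#'   (default `c(56, 107)`, clipped out of `schemes` when invalid for the
#'   montage).
#' @param halfwidth Relative-power band half-width (Hz).
#' @return An object of class `ds_ssvep`; see Details. Key components:
#'   `scans` (per-frequency `ref_scan`), `optimum` (named map
#'   frequency -> electrode), `baselines` and `evoked_sums` (frequency x
#'   scheme matrices of full-epoch sum relative-power), `gains`
#'   (stimulus x evaluated frequency x scheme array of
#'   evoked-to-baseline ratios), `thresholds` (one `threshold_set` per
#'   scheme).
#' @export
ds_ssvep <- function(evoked, spontaneous, plan = frequency_plan(),
                     schemes = c("optimum", "cz", "avg", "mastoid"),
                     seg_seconds = 2, pad_seconds = 4, specificity = 0.9,
                     candidates = NULL, cz_channel = NULL,
                     mastoid_pair = c(56L, 107L), halfwidth = 1) {
  if (inherits(evoked, "eeg_recording")) evoked <- list(evoked)
  stopifnot(inherits(spontaneous, "eeg_recording"))
  schemes <- match.arg(schemes, several.ok = TRUE)
  nch <- spontaneous$montage$n_channels
  if (is.null(cz_channel)) cz_channel <- nch
  ev_freqs <- vapply(evoked, function(r) {
    stopifnot(inherits(r, "eeg_recording"))
    if (is.na(r$stimulus_freq))
      stop("every evoked recording needs its stimulus_freq set")
    snap_freq(r$stimulus_freq, plan$stimulus_freqs, plan$match_tol)
  }, 0)
  if (anyDuplicated(ev_freqs))
    stop("multiple evoked recordings for the same stimulus frequency")
  names(evoked) <- as.character(ev_freqs)
  if (!all(vapply(plan$stimulus_freqs, function(f)
    any(abs(ev_freqs - f) <= plan$match_tol), TRUE))) {
    # a partial session: the dynamic scheme is only defined for stimuli
    # with an evoked epoch, so restrict the plan to those
    plan <- frequency_plan(stimulus_freqs = ev_freqs,
                           cutoff = plan$cutoff,
                           match_tol = plan$match_tol)
  }
  if ("mastoid" %in% schemes &&
      (max(mastoid_pair) > nch || min(mastoid_pair) < 1)) {
    schemes <- setdiff(schemes, "mastoid")
    warning("mastoid pair outside the montage; dropping the mastoid scheme")
  }

  # 1. exhaustive scan on each evoked epoch
  scans <- lapply(seq_along(evoked), function(i)
    find_optimum_reference(evoked[[i]], ev_freqs[i], pad_to = NULL,
                           candidates = candidates, halfwidth = halfwidth))
  names(scans) <- names(evoked)
  opt_map <- vapply(scans, function(s) s$optimum, 0L)

  scheme_objs <- list()
  for (s in schemes)
    scheme_objs[[s]] <- switch(s,
      optimum = ref_optimum(opt_map),
      cz = ref_single(cz_channel),
      avg = ref_common_average(),
      mastoid = ref_pair(mastoid_pair[1], mastoid_pair[2]))

  # 2. full-epoch baselines and evoked sums under every scheme (the FFT
  # of each epoch is computed once and shared across schemes)
  targets <- plan$stimulus_freqs
  sums_under <- function(sf, sch) {
    vapply(targets, function(g)
      relpow_at(sf, g, scheme_at_freq(sch, g, plan), halfwidth), 0)
  }
  sf_sp <- segment_fft(spontaneous$data, spontaneous$rate, NULL)
  sf_ev <- lapply(evoked, function(r) segment_fft(r$data, r$rate, NULL))
  baselines <- matrix(0, length(targets), length(scheme_objs),
                      dimnames = list(as.character(targets),
                                      names(scheme_objs)))
  evoked_sums <- array(0, c(length(evoked), length(targets),
                            length(scheme_objs)),
                       dimnames = list(stimulus = names(evoked),
                                       freq = as.character(targets),
                                       scheme = names(scheme_objs)))
  for (s in names(scheme_objs)) {
    baselines[, s] <- sums_under(sf_sp, scheme_objs[[s]])
    for (i in seq_along(evoked))
      evoked_sums[i, , s] <- sums_under(sf_ev[[i]], scheme_objs[[s]])
  }
  gains <- sweep(evoked_sums, c(2, 3), baselines, "/")

  # 3. per-scheme threshold calibration on spontaneous segments
  segs <- segment_epoch(spontaneous, seg_seconds)
  thresholds <- lapply(scheme_objs, function(sch)
    calibrate_thresholds(segs, plan, sch, specificity, pad_seconds,
                         halfwidth))

  structure(
    list(plan = plan, schemes = scheme_objs, scans = scans,
         optimum = opt_map, baselines = baselines,
         evoked_sums = evoked_sums, gains = gains,
         thresholds = thresholds,
         settings = list(seg_seconds = seg_seconds,
                         pad_seconds = pad_seconds,
                         specificity = specificity,
                         halfwidth = halfwidth,
                         cz_channel = cz_channel,
                         candidates = candidates),
         montage = spontaneous$montage),
    class = "ds_ssvep"
  )
}

#' @export
print.ds_ssvep <- function(x, ...) {
  cat("Dynamic reference-selection fit\n")
  cat("  stimuli:", paste(names(x$scans), collapse = ", "), "Hz\n")
  cat("  optimum references:",
      paste(sprintf("%s Hz -> %d", names(x$optimum), x$optimum),
            collapse = ", "), "\n")
  cat("  schemes calibrated:", paste(names(x$schemes), collapse = ", "),
      sprintf("(specificity %.2f, %d segments)\n",
              x$settings$specificity,
              attr(x$thresholds[[1]], "n_segments_used")))
  invisible(x)
}

#' Optimum reference electrodes of a fit
#'
#' @param object A `ds_ssvep` fit.
#' @param ... Unused.
#' @return Named integer vector mapping stimulus frequency (Hz) to the
#'   selected reference channel.
#' @export
coef.ds_ssvep <- function(object, ...) object$optimum

#' @export
summary.ds_ssvep <- function(object, ...) {
  stim <- dimnames(object$gains)$stimulus
  gain_tab <- do.call(rbind, lapply(stim, function(f) {
    g <- matrix(object$gains[f, , ], nrow = dim(object$gains)[2],
                dimnames = dimnames(object$gains)[2:3])
    data.frame(stimulus = f, freq = rownames(g), g, row.names = NULL,
               check.names = FALSE)
  }))
  out <- list(optimum = object$optimum, gains = gain_tab,
              baselines = object$baselines)
  class(out) <- "summary.ds_ssvep"
  out
}

#' @export
print.summary.ds_ssvep <- function(x, ...) {
  cat("Optimum references:\n")
  print(x$optimum)
  cat("\nFull-epoch gains (rows: evaluated frequency within each stimulus epoch):\n")
  print(x$gains, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.ds_ssvep <- function(x, which = seq_along(x$scans), ...) {
  op <- graphics::par(mfrow = c(length(which), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (i in which) plot(x$scans[[i]], ...)
  invisible(x)
}

#' Detect SSVEPs in new segments with a fitted model
#'
#' Segments the supplied evoked epoch (or uses a supplied segment list)
#' and applies the fitted thresholds under the chosen scheme and checking
#' standard.
#'
#' @param object A `ds_ssvep` fit.
#' @param newdata An evoked [eeg_recording()] or a list of segments.
#' @param rule `"h1h2"` (first and second harmonic where available,
#'   default) or `"h1"`.
#' @param scheme Name of a calibrated scheme (`"optimum"`, `"cz"`,
#'   `"avg"`, `"mastoid"`).
#' @param true_f True stimulus frequency; defaults to the recording's
#'   `stimulus_freq`.
#' @param ... Unused.
#' @return A [detection_accuracy()] object.
#' @export
predict.ds_ssvep <- function(object, newdata, rule = c("h1h2", "h1"),
                             scheme = "optimum", true_f = NULL, ...) {
  rule <- match.arg(rule)
  scheme <- match.arg(scheme, names(object$schemes))
  if (inherits(newdata, "eeg_recording")) {
    if (is.null(true_f)) true_f <- newdata$stimulus_freq
    newdata <- segment_epoch(newdata, object$settings$seg_seconds)
  } else if (is.null(true_f)) {
    true_f <- vapply(newdata, function(s) s$stimulus_freq, 0)
  }
  if (anyNA(true_f))
    stop("true_f missing and not recorded on the segments")
  detection_accuracy(newdata, true_f, object$thresholds[[scheme]],
                     object$plan, rule, object$schemes[[scheme]],
                     object$settings$pad_seconds,
                     object$settings$halfwidth)
}
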
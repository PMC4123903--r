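#' Multichannel EEG recording
#'
#' Container for a channels x samples matrix of potentials (microvolts)
#' with its sampling rate, montage and a descriptor of the reference the
#' data are currently expressed against.
#'
#' @param data Numeric matrix, channels x samples.
#' @param rate Sampling frequency in Hz.
#' @param montage An [eeg_montage()] with `nrow(data)` channels.
#' @param reference A reference scheme (see [ref_single()]); defaults to
#'   [ref_as_recorded()].
#' @param epoch_kind `"spontaneous"`, `"evoked"` or `NA`.
#' @param stimulus_freq Stimulus frequency in Hz for evoked epochs, or
#'   `NA`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, rate, montage,
                          reference = ref_as_recorded(),
                          epoch_kind = NA_character_,
                          stimulus_freq = NA_real_) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!inherits(montage, "eeg_montage"))
    stop("montage must be an eeg_montage")
  if (nrow(data) != montage$n_channels)
    stop(sprintf("data has %d rows but montage has %d channels",
                 nrow(data), montage$n_channels))
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a positive scalar (Hz)")
  if (ncol(data) < 1L) stop("recording must contain at least one sample")
  validate_scheme(reference, montage$n_channels)
  structure(
    list(data = data, rate = as.numeric(rate), montage = montage,
         reference = reference, epoch_kind = epoch_kind,
         stimulus_freq = as.numeric(stimulus_freq)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples (%.4g s @ %g Hz)\n",
              nrow(x$data), ncol(x$data), rec_duration(x), x$rate))
  cat("  reference:", format_scheme(x$reference), "\n")
  if (!is.na(x$epoch_kind)) cat("  epoch:", x$epoch_kind, "\n")
  if (!is.na(x$stimulus_freq))
    cat("  stimulus:", x$stimulus_freq, "Hz\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec An [eeg_recording()].
#' @return Duration in seconds.
#' @export
rec_duration <- function(rec) ncol(rec$data) / rec$rate

## ---- reference schemes ------------------------------------------------

#' Reference schemes
#'
#' Constructors for the four ways of expressing multichannel EEG against a
#' reference: as recorded, a single electrode, the common average of all
#' electrodes at each sample, or the average of an electrode pair (the
#' linked-mastoid convention; the default pair 56/107 matches the mastoid
#' positions of a 129-channel net).
#'
#' @param index,index_a,index_b 1-based channel indices.
#' @return A list of class `ref_scheme` with a `kind` field.
#' @export
ref_as_recorded <- function() {
  structure(list(kind = "as_recorded"), class = "ref_scheme")
}

#' @rdname ref_as_recorded
#' @export
ref_single <- function(index) {
  structure(list(kind = "single_electrode", index = as.integer(index)),
            class = "ref_scheme")
}

#' @rdname ref_as_recorded
#' @export
ref_common_average <- function() {
  structure(list(kind = "common_average"), class = "ref_scheme")
}

#' @rdname ref_as_recorded
#' @export
ref_pair <- function(index_a = 56L, index_b = 107L) {
  structure(list(kind = "electrode_pair_average",
                 index_a = as.integer(index_a),
                 index_b = as.integer(index_b)),
            class = "ref_scheme")
}

#' Frequency-specific dynamic reference
#'
#' Reference descriptor for the dynamic-selection scheme: each stimulus
#' frequency is analysed under its own optimum reference electrode.
#'
#' @param map Named numeric vector mapping frequency (Hz, as names) to the
#'   optimum reference channel index.
#' @return A list of class `ref_scheme` with kind `"optimum"`.
#' @export
ref_optimum <- function(map) {
  if (is.null(names(map)) || anyNA(suppressWarnings(as.numeric(names(map)))))
    stop("map must be a named vector with frequencies (Hz) as names")
  structure(list(kind = "optimum", map = map), class = "ref_scheme")
}

#' Look up the electrode a dynamic reference uses at a given frequency
#'
#' Frequencies are matched with a 0.05 Hz tolerance so that, e.g., the
#' second harmonic 33.34 Hz of a 16.67 Hz stimulus maps onto the 33.33 Hz
#' entry.
#'
#' @param scheme A `ref_scheme` of kind `"optimum"`.
#' @param f Frequency in Hz.
#' @param tol Matching tolerance in Hz.
#' @return A channel index.
#' @export
optimum_ref_for <- function(scheme, f, tol = 0.05) {
  stopifnot(inherits(scheme, "ref_scheme"), scheme$kind == "optimum")
  freqs <- as.numeric(names(scheme$map))
  i <- which.min(abs(freqs - f))
  if (abs(freqs[i] - f) > tol)
    stop(sprintf("no optimum reference recorded for %g Hz", f))
  as.integer(scheme$map[[i]])
}

validate_scheme <- function(scheme, n_channels) {
  if (!inherits(scheme, "ref_scheme")) stop("not a ref_scheme")
  switch(scheme$kind,
    single_electrode = check_channel(scheme$index, n_channels, "reference"),
    electrode_pair_average = {
      check_channel(scheme$index_a, n_channels, "reference")
      check_channel(scheme$index_b, n_channels, "reference")
    },
    optimum = {
      for (v in scheme$map) check_channel(v, n_channels, "reference")
    },
    as_recorded = NULL,
    common_average = NULL,
    stop("unknown reference scheme kind: ", scheme$kind)
  )
  invisible(scheme)
}

format_scheme <- function(scheme) {
  switch(scheme$kind,
    as_recorded = "as recorded",
    single_electrode = sprintf("single electrode %d", scheme$index),
    common_average = "common average",
    electrode_pair_average = sprintf("pair average (%d, %d)",
                                     scheme$index_a, scheme$index_b),
    optimum = sprintf("dynamic optimum (%s)",
                      paste(sprintf("%s Hz -> %d", names(scheme$map),
                                    as.integer(scheme$map)),
                            collapse = ", ")),
    scheme$kind)
}

#' @export
print.ref_scheme <- function(x, ...) {
  cat("Reference scheme:", format_scheme(x), "\n")
  invisible(x)
}

#' Re-reference a recording
#'
#' Expresses every channel against a new reference: for a single electrode
#' `r` each row becomes `data[i, ] - data[r, ]` (row `r` becomes zero);
#' for the common average, each column's across-channel mean is removed;
#' for an electrode pair, the mean of the two rows is removed. The input
#' recording is not modified. Single-electrode re-referencing is
#' transitive, so the result does not depend on the recording's previous
#' single-electrode reference.
#'
#' @param rec An [eeg_recording()].
#' @param scheme A `ref_scheme` (kinds `single_electrode`,
#'   `common_average`, `electrode_pair_average`).
#' @return A new [eeg_recording()] under `scheme`.
#' @export
rereference <- function(rec, scheme) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2L) stop("re-referencing needs at least 2 channels")
  validate_scheme(scheme, nrow(rec$data))
  d <- rec$data
  new <- switch(scheme$kind,
    single_electrode = {
      out <- d - rep(d[scheme$index, ], each = nrow(d))
      out[scheme$index, ] <- 0
      out
    },
    common_average = d - rep(colMeans(d), each = nrow(d)),
    electrode_pair_average =
      d - rep((d[scheme$index_a, ] + d[scheme$index_b, ]) / 2,
              each = nrow(d)),
    as_recorded = d,
    stop("cannot re-reference to scheme of kind ", scheme$kind)
  )
  rec$data <- new
  rec$reference <- scheme
  rec
}

## ---- text-matrix I/O --------------------------------------------------

#' Read and write the delimited text matrix format
#'
#' A small diff-friendly dialect: header lines `# rate=<Hz>` and
#' `# labels=<comma list>`, then one channel per row with tab-separated
#' samples.
#'
#' @param path File path.
#' @param montage Optional [eeg_montage()]; if omitted a flat synthetic
#'   layout is generated from the embedded labels. If given, its labels
#'   must match the file's.
#' @return `read_eeg_txt()` returns an [eeg_recording()] with reference
#'   `as_recorded`; `write_eeg_txt()` returns `path` invisibly.
#' @export
read_eeg_txt <- function(path, montage = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  rate <- sub("^#\\s*rate=", "", grep("^#\\s*rate=", hdr, value = TRUE))
  if (length(rate) != 1L)
    stop("malformed text recording: missing '# rate=' header")
  labels <- sub("^#\\s*labels=", "",
                grep("^#\\s*labels=", hdr, value = TRUE))
  if (length(labels) != 1L)
    stop("malformed text recording: missing '# labels=' header")
  labels <- strsplit(labels, ",", fixed = TRUE)[[1]]
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) != length(labels))
    stop(sprintf("channel mismatch: %d labels but %d data rows",
                 length(labels), length(body)))
  data <- do.call(rbind, lapply(strsplit(body, "\t", fixed = TRUE),
                                as.numeric))
  if (anyNA(data)) stop("malformed text recording: non-numeric sample")
  if (is.null(montage)) {
    montage <- eeg_montage(labels, default_coords(length(labels)))
  } else if (!identical(montage$labels, labels)) {
    stop("montage labels do not match recording labels")
  }
  eeg_recording(data, as.numeric(rate), montage)
}

#' @rdname read_eeg_txt
#' @param rec An [eeg_recording()].
#' @export
write_eeg_txt <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# rate=%.10g", rec$rate),
               paste0("# labels=", paste(rec$montage$labels, collapse = ","))),
             con)
  apply(rec$data, 1L, function(row)
    writeLines(paste(sprintf("%.17g", row), collapse = "\t"), con))
  invisible(path)
}

# fallback coordinates when only labels are known
default_coords <- function(n) {
  if (n >= 2L) synthetic_montage(n)$coords
  else matrix(0, 1, 2)
}

#' Read or write a recording in a chosen container format
#'
#' Thin dispatcher over the text-matrix and EDF readers/writers.
#'
#' @param path File path.
#' @param format `"text_matrix"` or `"edf"`; guessed from the file
#'   extension when missing (`.edf` means EDF).
#' @param montage Optional montage to attach (labels must match).
#' @return `read_recording()` returns an [eeg_recording()] with reference
#'   `as_recorded`.
#' @export
read_recording <- function(path, format = c("auto", "text_matrix", "edf"),
                           montage = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
              else "text_matrix"
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         text_matrix = read_eeg_txt(path, montage),
         edf = read_edf(path, montage))
}

#' @rdname read_recording
#' @param rec An [eeg_recording()].
#' @export
write_recording <- function(rec, path,
                            format = c("auto", "text_matrix", "edf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
              else "text_matrix"
  switch(format,
         text_matrix = write_eeg_txt(rec, path),
         edf = write_edf(rec, path))
}
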
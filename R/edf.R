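## Basic (non-"+") 16-bit European Data Format support.
## Header: 256 bytes global + 256 bytes per signal, all ASCII fields;
## data: records of little-endian int16, signal-major inside each record.
## The writer auto-scales each channel's physical range and emits a single
## data record covering the whole epoch, which keeps the round trip exact
## up to 16-bit quantization for any epoch length.

edf_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width) # left-justified, space padded
}

edf_num <- function(x, width) {
  for (dg in seq(10, 1)) {
    s <- sprintf("%.*g", dg, x)
    if (nchar(s) <= width) return(edf_field(s, width))
  }
  stop("cannot format ", x, " in ", width, " characters")
}

#' Write a recording as basic 16-bit EDF
#'
#' Each channel is linearly quantized to the signed 16-bit range using its
#' own physical minimum/maximum, so the worst-case round-trip error per
#' channel is `(max - min) / 65534`.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  d <- rec$data
  ns <- nrow(d)
  n <- ncol(d)
  pmin <- apply(d, 1, min)
  pmax <- apply(d, 1, max)
  flat <- pmax - pmin <= 0
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8),                       # version
    edf_field("synthetic subject", 80),      # patient id
    edf_field("ssvepds recording", 80),      # recording id
    edf_field("01.01.00", 8),                # start date
    edf_field("00.00.00", 8),                # start time
    edf_field(256L * (1L + ns), 8),          # header bytes
    edf_field("", 44),                       # reserved
    edf_field(1L, 8),                        # number of data records
    edf_num(n / rec$rate, 8),                # record duration (s)
    edf_field(ns, 4)                         # number of signals
  )
  sig <- paste0(
    paste(vapply(rec$montage$labels, edf_field, "", width = 16),
          collapse = ""),
    paste(rep(edf_field("AgAgCl electrode", 80), ns), collapse = ""),
    paste(rep(edf_field("uV", 8), ns), collapse = ""),
    paste(vapply(pmin, edf_num, "", width = 8), collapse = ""),
    paste(vapply(pmax, edf_num, "", width = 8), collapse = ""),
    paste(rep(edf_field(dmin, 8), ns), collapse = ""),
    paste(rep(edf_field(dmax, 8), ns), collapse = ""),
    paste(rep(edf_field("none", 80), ns), collapse = ""),
    paste(rep(edf_field(n, 8), ns), collapse = ""),
    paste(rep(edf_field("", 32), ns), collapse = "")
  )
  writeChar(paste0(hdr, sig), con, eos = NULL)
  # one record, signal-major; re-read the header's (truncated) physical
  # limits so quantization and de-quantization use identical endpoints
  pmin_h <- as.numeric(vapply(pmin, edf_num, "", width = 8))
  pmax_h <- as.numeric(vapply(pmax, edf_num, "", width = 8))
  for (i in seq_len(ns)) {
    q <- round((d[i, ] - pmin_h[i]) / (pmax_h[i] - pmin_h[i]) *
                 (dmax - dmin) + dmin)
    q <- pmin(pmax(q, dmin), dmax)
    writeBin(as.integer(q), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read a basic 16-bit EDF file
#'
#' @param path File path.
#' @param montage Optional [eeg_montage()] whose labels must match the
#'   signal labels stored in the file; generated from the labels when
#'   omitted.
#' @return An [eeg_recording()] with reference `as_recorded`; the
#'   sampling rate is recovered from the record duration and samples per
#'   record.
#' @export
read_edf <- function(path, montage = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  gh <- readChar(con, 256L, useBytes = TRUE)
  if (nchar(gh) < 256L) stop("malformed EDF: truncated global header")
  fld <- function(s, from, len) trimws(substr(s, from, from + len - 1L))
  if (fld(gh, 1, 8) != "0") stop("malformed EDF: unsupported version")
  n_rec <- as.integer(fld(gh, 237, 8))
  rec_dur <- as.numeric(fld(gh, 245, 8))
  ns <- as.integer(fld(gh, 253, 4))
  if (is.na(ns) || ns < 1L || is.na(n_rec) || n_rec < 1L ||
      is.na(rec_dur) || rec_dur <= 0)
    stop("malformed EDF: bad record geometry")
  sh <- readChar(con, 256L * ns, useBytes = TRUE)
  if (nchar(sh) < 256L * ns) stop("malformed EDF: truncated signal header")
  # byte offsets of the packed per-signal arrays inside the signal header:
  # label 16, transducer 80, dimension 8, then the numeric fields
  sfld <- function(start, len, i)
    trimws(substr(sh, start * ns + (i - 1L) * len + 1L, start * ns + i * len))
  labels <- vapply(seq_len(ns), function(i) sfld(0L, 16L, i), "")
  pmin <- as.numeric(vapply(seq_len(ns), function(i) sfld(104L, 8L, i), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) sfld(112L, 8L, i), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) sfld(120L, 8L, i), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) sfld(128L, 8L, i), ""))
  spr <- as.integer(vapply(seq_len(ns), function(i) sfld(216L, 8L, i), ""))
  if (anyNA(c(pmin, pmax, dmin, dmax, spr)))
    stop("malformed EDF: bad signal header fields")
  if (length(unique(spr)) != 1L)
    stop("EDF files with per-signal sampling rates are not supported")
  out <- matrix(0, ns, spr[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      q <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                   endian = "little")
      if (length(q) != spr[i]) stop("malformed EDF: truncated data record")
      out[i, (r - 1L) * spr[i] + seq_len(spr[i])] <-
        (q - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i]) + pmin[i]
    }
  }
  rate <- spr[1] / rec_dur
  if (is.null(montage)) {
    montage <- eeg_montage(labels, default_coords(ns))
  } else if (!identical(trimws(montage$labels), labels)) {
    stop("montage labels do not match EDF signal labels")
  }
  eeg_recording(out, rate, montage)
}
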
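#' Electrode montage
#'
#' An `eeg_montage` holds the ordered channel labels of an EEG cap together
#' with a 2-D head-plane projection of the electrode positions (arbitrary
#' units; only relative distances are used by the simulator). Channel
#' indexing is 1-based everywhere in the user interface.
#'
#' @param labels Character vector of unique channel names.
#' @param coords Numeric matrix with one row per channel and two columns
#'   (x, y). Convention: +y is anterior (nose), -y posterior (inion).
#' @return An object of class `eeg_montage` with elements `labels`,
#'   `coords` and `n_channels`.
#' @seealso [montage_129()], [synthetic_montage()], [read_montage()]
#' @export
eeg_montage <- function(labels, coords) {
  labels <- as.character(labels)
  coords <- as.matrix(coords)
  if (anyDuplicated(labels))
    stop("montage labels must be unique")
  if (nrow(coords) != length(labels) || ncol(coords) != 2L)
    stop("coords must be a length(labels) x 2 matrix")
  storage.mode(coords) <- "double"
  dimnames(coords) <- list(labels, c("x", "y"))
  structure(
    list(labels = labels, coords = coords, n_channels = length(labels)),
    class = "eeg_montage"
  )
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("EEG montage:", x$n_channels, "channels\n")
  cat("  labels:", x$labels[1L], "...", x$labels[x$n_channels], "\n")
  r <- sqrt(rowSums(x$coords^2))
  cat("  head radius (max):", format(max(r), digits = 3), "units\n")
  invisible(x)
}

#' Synthetic concentric-ring montage
#'
#' Lays `n - 1` electrodes on concentric rings approximating a geodesic
#' net, with the last channel (`"Cz"`) at the vertex (0, 0). The outermost
#' ring has radius 1. Ring populations grow outward so that surface
#' density is roughly uniform.
#'
#' @param n Total number of channels including the central `Cz`.
#' @return An [eeg_montage()].
#' @export
synthetic_montage <- function(n) {
  if (n < 2L) stop("need at least 2 channels")
  m <- n - 1L
  # golden-angle spiral: uniform areal density, works for any m
  k <- seq_len(m)
  r <- sqrt(k / m)
  th <- k * pi * (3 - sqrt(5))
  coords <- cbind(r * cos(th), r * sin(th))
  labels <- c(sprintf("E%d", k), "Cz")
  eeg_montage(labels, rbind(coords, c(0, 0)))
}

#' Standard 129-channel ring montage
#'
#' A generated 129-position layout: channel 129 (`"Cz"`) at the vertex and
#' 128 electrodes on seven concentric rings (6, 10, 14, 18, 24, 26 and 30
#' electrodes from inner to outer), mimicking the coverage of a dense
#' geodesic sensor net. Channels are numbered ring by ring from the vertex
#' outward; the outermost ring has radius 1.
#'
#' @return An [eeg_montage()] with 129 channels.
#' @export
montage_129 <- function() {
  counts <- c(6L, 10L, 14L, 18L, 24L, 26L, 30L)
  radii <- seq_along(counts) / length(counts)
  xs <- ys <- numeric(0)
  for (j in seq_along(counts)) {
    # stagger rings so electrodes do not align radially
    th <- 2 * pi * (seq_len(counts[j]) - 1) / counts[j] + pi / 2 +
      (j %% 2) * pi / counts[j]
    xs <- c(xs, radii[j] * cos(th))
    ys <- c(ys, radii[j] * sin(th))
  }
  labels <- c(sprintf("E%d", 1:128), "Cz")
  eeg_montage(labels, rbind(cbind(xs, ys), c(0, 0)))
}

#' Pairwise electrode distances and neighbours
#'
#' @param montage An [eeg_montage()].
#' @param from 1-based channel index distances are measured from.
#' @return `montage_distances()` returns the vector of Euclidean distances
#'   from `from` to every channel (zero at `from` itself).
#' @export
montage_distances <- function(montage, from) {
  stopifnot(inherits(montage, "eeg_montage"))
  from <- check_channel(from, montage$n_channels)
  d <- montage$coords - matrix(montage$coords[from, ], montage$n_channels, 2,
                               byrow = TRUE)
  unname(sqrt(rowSums(d^2)))
}

#' @rdname montage_distances
#' @param k Number of nearest neighbours to return.
#' @return `nearest_channels()` returns the indices of the `k` channels
#'   closest to `from` (excluding `from` itself).
#' @export
nearest_channels <- function(montage, from, k = 3L) {
  d <- montage_distances(montage, from)
  d[from] <- Inf
  order(d)[seq_len(k)]
}

#' Default occipital source channel
#'
#' The channel whose position is closest to the occipital pole (0, -0.85
#' in montage units), used as the default SSVEP source by the forward
#' simulator.
#'
#' @param montage An [eeg_montage()].
#' @return A 1-based channel index.
#' @export
occipital_channel <- function(montage) {
  stopifnot(inherits(montage, "eeg_montage"))
  tgt <- c(0, -0.85)
  d <- sweep(montage$coords, 2, tgt)
  which.min(rowSums(d^2))
}

#' Reduced-density candidate subset
#'
#' Mirrors a reduced-montage setup in which only a fraction (default one
#' third) of the electrodes in each lobe is retained. Channels are
#' partitioned into four lobes by angular sector (frontal, left, right,
#' occipital, each a 90-degree wedge; the vertex channel is assigned to
#' the frontal sector) and thinned with a regular stride inside each lobe.
#'
#' @param montage An [eeg_montage()].
#' @param fraction Fraction of channels kept per lobe.
#' @return Sorted integer vector of retained channel indices.
#' @export
reduced_candidates <- function(montage, fraction = 1 / 3) {
  stopifnot(inherits(montage, "eeg_montage"), fraction > 0, fraction <= 1)
  ang <- atan2(montage$coords[, 2], montage$coords[, 1]) # 0 = right ear
  lobe <- cut(((ang - pi / 4) %% (2 * pi)),
              breaks = c(0, pi / 2, pi, 3 * pi / 2, 2 * pi),
              labels = c("frontal", "left", "occipital", "right"),
              include.lowest = TRUE)
  keep <- integer(0)
  stride <- max(1L, round(1 / fraction))
  for (lb in levels(lobe)) {
    idx <- which(lobe == lb)
    keep <- c(keep, idx[seq(1L, length(idx), by = stride)])
  }
  sort(unique(keep))
}

#' Read or write a montage file
#'
#' The montage file is plain text: one `# n_channels=<n>` header line then
#' one line per channel with `label<TAB>x<TAB>y`.
#'
#' @param path File path.
#' @return `read_montage()` returns an [eeg_montage()];
#'   `write_montage()` returns `path` invisibly.
#' @export
read_montage <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop("malformed montage file: expected label<TAB>x<TAB>y per line")
  labels <- vapply(parts, `[[`, "", 1L)
  coords <- cbind(as.numeric(vapply(parts, `[[`, "", 2L)),
                  as.numeric(vapply(parts, `[[`, "", 3L)))
  if (anyNA(coords)) stop("malformed montage file: non-numeric coordinate")
  eeg_montage(labels, coords)
}

#' @rdname read_montage
#' @param montage An [eeg_montage()].
#' @export
write_montage <- function(montage, path) {
  stopifnot(inherits(montage, "eeg_montage"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_channels=%d", montage$n_channels), con)
  writeLines(sprintf("%s\t%.10g\t%.10g", montage$labels,
                     montage$coords[, 1], montage$coords[, 2]), con)
  invisible(path)
}

# validate a 1-based channel index
check_channel <- function(i, n, what = "channel") {
  i <- as.integer(i)
  if (length(i) != 1L || is.na(i) || i < 1L || i > n)
    stop(sprintf("%s index out of range 1..%d", what, n))
  i
}
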
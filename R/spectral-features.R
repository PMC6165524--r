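#' Segment a stream into overlapping analysis windows
#'
#' Windows of `window_seconds` advance by `window_seconds * (1 -
#' overlap_fraction)`; a trailing partial window is discarded. Each window
#' inherits the stream's label and sampling rate.
#'
#' @param stream An `imu_stream` from [simulate_activity()] or
#'   [read_imu_csv()].
#' @param window_seconds Window length in seconds (default 3).
#' @param overlap_fraction Fraction of overlap between consecutive windows,
#'   in `[0, 1)` (default 0.5).
#' @return List of `analysis_window` objects (possibly empty, with a warning,
#'   when the stream is shorter than one window). Each holds `channels`
#'   (samples x 6 matrix, columns ax..gz), `fs`, `start_time`, `label`.
#' @export
segment_stream <- function(stream, window_seconds = 3, overlap_fraction = 0.5) {
  stopifnot(inherits(stream, "imu_stream"))
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop_bad_arg("overlap_fraction must be in [0, 1)")
  }
  if (window_seconds <= 0) stop_bad_arg("window_seconds must be positive")
  n <- nrow(stream$data)
  win <- round(window_seconds * stream$fs)
  if (win > n) {
    warning("stream shorter than one analysis window; returning empty list")
    return(list())
  }
  hop <- max(1L, round(win * (1 - overlap_fraction)))
  starts <- seq.int(1L, n - win + 1L, by = hop)
  ch <- as.matrix(stream$data[, c("ax", "ay", "az", "gx", "gy", "gz")])
  lapply(starts, function(s) {
    structure(
      list(channels = ch[s:(s + win - 1L), , drop = FALSE],
           fs = stream$fs,
           start_time = (s - 1L) / stream$fs,
           label = stream$label),
      class = "analysis_window"
    )
  })
}

#' Construct an analysis window directly from channel data
#'
#' Used by readers that deliver pre-windowed data (e.g. the fixed-width
#' inertial-signals dialect) and by tests.
#'
#' @param channels Numeric matrix, samples x 6 (ax, ay, az, gx, gy, gz).
#' @param fs Sampling frequency in Hz.
#' @param label Activity class code.
#' @param start_time Window start time in seconds.
#' @return An `analysis_window`.
#' @export
analysis_window <- function(channels, fs, label, start_time = 0) {
  channels <- as.matrix(channels)
  if (ncol(channels) != 6) stop_bad_arg("channels must have 6 columns")
  colnames(channels) <- c("ax", "ay", "az", "gx", "gy", "gz")
  structure(list(channels = channels, fs = fs, start_time = start_time,
                 label = label),
            class = "analysis_window")
}

#' One-sided power spectrogram of a single channel
#'
#' Short-time Fourier transform with a Hann taper: the channel is cut into
#' segments of `segment_length` samples advancing by `hop`, each segment is
#' tapered and zero-padded to `fft_length` points, and the squared magnitudes
#' of the one-sided spectrum (DC through Nyquist, `fft_length/2 + 1` bins)
#' are returned.
#'
#' @param channel Numeric vector of samples.
#' @param fs Sampling frequency in Hz (carried in the result's attributes).
#' @param fft_length FFT size in points (default 512); segments are
#'   zero-padded up to this length.
#' @param segment_length Taper segment length in samples; defaults to
#'   `min(length(channel), 128)`.
#' @param hop Advance between segments in samples; defaults to
#'   `segment_length / 2`.
#' @return Matrix of squared STFT magnitudes, `fft_length/2 + 1` frequency
#'   rows by one column per time shift, with attributes `fs`, `fft_length`,
#'   `freqs` (bin centre frequencies in Hz).
#' @export
spectrogram <- function(channel, fs, fft_length = 512,
                        segment_length = min(length(channel), 128L),
                        hop = max(1L, floor(segment_length / 2))) {
  channel <- as.numeric(channel)
  if (segment_length > fft_length) {
    stop_bad_arg("segment_length must not exceed fft_length")
  }
  if (length(channel) < segment_length) {
    stop_bad_arg("channel shorter than segment_length")
  }
  if (hop < 1) stop_bad_arg("hop must be >= 1")
  taper <- signal::hanning(segment_length)
  starts <- seq.int(1L, length(channel) - segment_length + 1L, by = hop)
  nbin <- fft_length / 2 + 1
  out <- matrix(0, nrow = nbin, ncol = length(starts))
  for (k in seq_along(starts)) {
    seg <- channel[starts[k]:(starts[k] + segment_length - 1L)] * taper
    padded <- c(seg, rep(0, fft_length - segment_length))
    spec <- fft(padded)[seq_len(nbin)]
    out[, k] <- Re(spec)^2 + Im(spec)^2
  }
  structure(out, fs = fs, fft_length = fft_length,
            freqs = (seq_len(nbin) - 1) * fs / fft_length)
}

# Smallest-S / largest-L selection from a pooled value vector: sort all
# pooled spectral densities ascending, keep the first S and the last L,
# each block reported in ascending order.
sl_select <- function(pool, S, L) {
  if (S + L > length(pool)) {
    stop_bad_arg("S + L exceeds the pooled bin count (", length(pool), ")")
  }
  sorted <- sort(pool, method = "radix")  # stable
  list(small = sorted[seq_len(S)],
       large = sorted[seq.int(length(sorted) - L + 1L, length(sorted))])
}

#' Extract the least/largest spectral-density feature vector from one window
#'
#' All squared-magnitude spectrogram cells of the three accelerometer axes
#' are pooled into one multiset and sorted ascending; the smallest `S` and
#' largest `L` values form the accelerometer blocks. The same is done for the
#' gyroscope axes, and the four blocks are concatenated as
#' `SA || LeA || SG || LG` (each block ascending), giving a vector of length
#' `2 * (S + L)`.
#'
#' @param window An `analysis_window`.
#' @param S Number of least spectral densities per sensor.
#' @param L Number of largest spectral densities per sensor.
#' @param fft_length,segment_length,hop Passed to [spectrogram()].
#' @return Named numeric vector of length `2 * (S + L)` with attribute
#'   `label`.
#' @export
extract_features <- function(window, S = 25, L = 25, fft_length = 512,
                             segment_length = NULL, hop = NULL) {
  stopifnot(inherits(window, "analysis_window"))
  n <- nrow(window$channels)
  segment_length <- segment_length %||% min(n, 128L)
  hop <- hop %||% max(1L, floor(segment_length / 2))

  pool_of <- function(cols) {
    unlist(lapply(cols, function(j) {
      as.numeric(spectrogram(window$channels[, j], window$fs, fft_length,
                             segment_length, hop))
    }), use.names = FALSE)
  }
  acc <- sl_select(pool_of(1:3), S, L)
  gyr <- sl_select(pool_of(4:6), S, L)
  v <- c(acc$small, acc$large, gyr$small, gyr$large)
  names(v) <- paste0("Q", seq_along(v))
  attr(v, "label") <- window$label
  v
}

#' Build a labelled feature set from a collection of streams
#'
#' Runs [segment_stream()] then [extract_features()] on every stream; rows
#' are ordered by stream, then by window start time.
#'
#' @param streams List of `imu_stream` objects.
#' @param S,L Per-sensor least/largest counts (defaults 25/25, i.e. a
#'   100-feature vector).
#' @param window_seconds,overlap_fraction Passed to [segment_stream()].
#' @param fft_length,segment_length,hop Passed to [extract_features()].
#' @return A [feature_set()] with provenance `"OR"`.
#' @export
build_feature_set <- function(streams, S = 25, L = 25, window_seconds = 3,
                              overlap_fraction = 0.5, fft_length = 512,
                              segment_length = NULL, hop = NULL) {
  if (length(streams) == 0) stop_bad_arg("streams must be non-empty")
  rows <- list()
  labels <- character(0)
  for (st in streams) {
    wins <- segment_stream(st, window_seconds, overlap_fraction)
    for (w in wins) {
      v <- extract_features(w, S, L, fft_length, segment_length, hop)
      rows[[length(rows) + 1L]] <- v
      labels <- c(labels, attr(v, "label"))
    }
  }
  if (length(rows) == 0) {
    return(feature_set(matrix(numeric(0), ncol = 2 * (S + L),
                              dimnames = list(NULL, paste0("Q", seq_len(2 * (S + L))))),
                       character(0), provenance = "OR", S = S, L = L))
  }
  feature_set(do.call(rbind, rows), labels, provenance = "OR", S = S, L = L)
}

#' Labelled feature-set container
#'
#' Holds a numeric feature matrix (one row per analysis window, columns
#' `Q1..Qp`), a parallel label factor over the activity classes, and a
#' provenance tag recording which augmentation stages produced it
#' (`"OR"`, `"OR+LA1"`, `"OR+LA1+SH"`, `"OR+LA1+SH+LA2"`).
#'
#' @param features Numeric matrix, rows = samples.
#' @param labels Character or factor vector, one label per row.
#' @param provenance Provenance tag (default `"OR"`).
#' @param S,L Optional per-sensor selection counts, carried as metadata.
#' @return Object of class `feature_set`.
#' @export
feature_set <- function(features, labels, provenance = "OR",
                        S = NULL, L = NULL) {
  features <- as.matrix(features)
  if (nrow(features) != length(labels)) {
    stop_bad_arg("one label per feature row required")
  }
  labels <- factor(as.character(labels),
                   levels = union(HAR_CLASSES, unique(as.character(labels))))
  labels <- droplevels(labels, exclude = NULL)
  structure(
    list(features = features, labels = labels, provenance = provenance,
         S = S, L = L),
    class = "feature_set"
  )
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d x %d [%s]  classes: %s\n",
              nrow(x$features), ncol(x$features), x$provenance,
              paste(sprintf("%s=%d", levels(x$labels),
                            as.integer(table(x$labels))), collapse = " ")))
  invisible(x)
}

#' @export
dim.feature_set <- function(x) dim(x$features)

#' @export
as.data.frame.feature_set <- function(x, ...) {
  df <- as.data.frame(x$features)
  df$label <- as.character(x$labels)
  df
}

# Per-class row counts, in label-level order.
class_counts <- function(fs) as.integer(table(fs$labels))
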
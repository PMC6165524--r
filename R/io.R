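#' Write / read labelled IMU streams as CSV
#'
#' Format: header `t,ax,ay,az,gx,gy,gz,label`, one row per sample. Several
#' streams written to one file are concatenated; on reading, streams are
#' split at label-change boundaries and the sampling rate is inferred from
#' the median timestamp delta.
#'
#' @param streams An `imu_stream` or list of them.
#' @param path CSV file path.
#' @return `write_imu_csv`: `path`, invisibly. `read_imu_csv`: list of
#'   `imu_stream` objects, one per label block / timestamp reset.
#' @export
write_imu_csv <- function(streams, path) {
  if (inherits(streams, "imu_stream")) streams <- list(streams)
  blocks <- lapply(streams, function(s) {
    df <- s$data
    df$label <- s$label
    df
  })
  df <- do.call(rbind, blocks)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_imu_csv
#' @export
read_imu_csv <- function(path) {
  if (!file.exists(path)) stop_bad_arg("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  expected <- c("t", "ax", "ay", "az", "gx", "gy", "gz", "label")
  if (!identical(names(df), expected)) {
    stop_bad_arg("header must be ", paste(expected, collapse = ","))
  }
  if (nrow(df) == 0) {
    warning("empty data section in ", path)
    return(list())
  }
  num_cols <- expected[1:7]
  for (col in num_cols) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]))
    if (length(bad)) {
      stop_bad_arg("malformed value in column ", col, " at data row ", bad[1])
    }
    df[[col]] <- vals
  }
  # a new stream starts at every label change or timestamp reset
  # (concatenated recordings each restart their clock at 0)
  label_change <- c(TRUE, df$label[-1] != df$label[-nrow(df)])
  time_reset <- c(TRUE, diff(df$t) < 0)
  starts <- which(label_change | time_reset)
  ends <- c(starts[-1] - 1L, nrow(df))
  lapply(seq_along(starts), function(k) {
    block <- df[starts[k]:ends[k], ]
    dt <- diff(block$t)
    if (length(dt) && any(dt == 0)) {
      stop_bad_arg("non-monotone timestamps within stream ", k)
    }
    fs <- if (length(dt)) 1 / stats::median(dt) else 1
    structure(list(data = block[, num_cols], fs = fs,
                   label = block$label[1], seed = NA_integer_),
              class = "imu_stream")
  })
}

#' Write / read feature sets as delimited text
#'
#' CSV with columns `Q1..Qp` and a final `label` column; provenance and the
#' augmentation bookkeeping go to a JSON sidecar (`<path>.meta.json`).
#'
#' @param fs A [feature_set()].
#' @param path CSV file path.
#' @return `write_feature_csv`: `path` invisibly; `read_feature_csv`: a
#'   `feature_set`.
#' @export
write_feature_csv <- function(fs, path) {
  stopifnot(inherits(fs, "feature_set"))
  df <- as.data.frame(fs)
  utils::write.csv(format(df, digits = 15, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  counts <- as.list(setNames(as.integer(table(fs$labels)), levels(fs$labels)))
  jsonlite::write_json(
    list(provenance = fs$provenance, S = fs$S, L = fs$L,
         n_rows = nrow(fs$features), class_counts = counts),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  if (!file.exists(path)) stop_bad_arg("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"label" %in% names(df)) stop_bad_arg("missing label column")
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list(provenance = "OR", S = NULL, L = NULL)
  feats <- as.matrix(df[, setdiff(names(df), "label"), drop = FALSE])
  feature_set(feats, df$label, provenance = meta$provenance %||% "OR",
              S = meta$S, L = meta$L)
}

#' Write / read a confusion matrix as CSV
#'
#' Layout: first column `true` with class labels, remaining columns the
#' predicted-class counts.
#'
#' @param cm A `har_cm` (or any square count matrix with dimnames).
#' @param path CSV file path.
#' @return `write_cm_csv`: `path` invisibly; `read_cm_csv`: a `har_cm`.
#' @export
write_cm_csv <- function(cm, path) {
  cm <- as.matrix(cm)
  df <- data.frame(true = rownames(cm), cm, check.names = FALSE,
                   row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cm_csv
#' @export
read_cm_csv <- function(path) {
  if (!file.exists(path)) stop_bad_arg("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  as_confusion_matrix(m, classes = df[[1]])
}

#' Write fixed-width inertial-signals fixtures
#'
#' Emits windows in the fixed-width text dialect used by the UCI HAR
#' "Inertial Signals" release: one file per channel with
#' `samples_per_row` floating-point numbers per line, plus a label file of
#' integer class codes (one per row). Intended for generating small test
#' fixtures; files are named `<channel>.txt` and `labels.txt`.
#'
#' @param windows List of `analysis_window` objects (equal lengths).
#' @param dir Output directory (created if needed).
#' @param label_codes Named integer vector mapping class code to integer
#'   (default `c(WA = 1, SI = 4, ST = 5)`, the standard release coding).
#' @return `dir`, invisibly.
#' @export
write_uci_fixture <- function(windows, dir,
                              label_codes = c(WA = 1L, SI = 4L, ST = 5L)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  channels <- c("acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z")
  for (j in seq_along(channels)) {
    lines <- vapply(windows, function(w) {
      paste(sprintf("% .7e", w$channels[, j]), collapse = " ")
    }, character(1))
    writeLines(lines, file.path(dir, paste0(channels[j], ".txt")))
  }
  codes <- vapply(windows, function(w) label_codes[[w$label]], integer(1))
  writeLines(as.character(codes), file.path(dir, "labels.txt"))
  invisible(dir)
}

#' Read fixed-width inertial-signals windows
#'
#' Reads per-channel fixed-width text files (`samples_per_row` floats per
#' line, whitespace-separated) and an integer label file, returning one
#' 6-channel `analysis_window` per row. Rows whose label code is not in
#' `label_map` (e.g. lying-down classes) are dropped; the exclusion count is
#' attached as attribute `n_excluded` and reported via a message.
#'
#' @param dir Directory with the channel files and label file.
#' @param channels Channel file basenames, in axis order ax..gz.
#' @param labels_file Label file basename (default `"labels.txt"`).
#' @param label_map Named integer vector mapping retained class codes
#'   (default `c(WA = 1L, SI = 4L, ST = 5L)`).
#' @param fs Sampling frequency of the windows in Hz (default 50).
#' @param samples_per_row Expected samples per window row (default 128).
#' @return List of `analysis_window` objects with attribute `n_excluded`.
#' @export
read_uci_inertial <- function(dir,
                              channels = c("acc_x", "acc_y", "acc_z",
                                           "gyro_x", "gyro_y", "gyro_z"),
                              labels_file = "labels.txt",
                              label_map = c(WA = 1L, SI = 4L, ST = 5L),
                              fs = 50, samples_per_row = 128L) {
  read_channel <- function(base) {
    f <- file.path(dir, paste0(base, ".txt"))
    if (!file.exists(f)) f <- file.path(dir, base)  # allow full filenames
    if (!file.exists(f)) stop_bad_arg("missing channel file: ", base)
    lines <- readLines(f)
    vals <- lapply(seq_along(lines), function(r) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(lines[r]), "\\s+")[[1]]))
      if (length(v) != samples_per_row || anyNA(v)) {
        stop_bad_arg("file ", basename(f), " row ", r, ": expected ",
                     samples_per_row, " numeric values")
      }
      v
    })
    do.call(rbind, vals)
  }
  mats <- lapply(channels, read_channel)
  n_rows <- unique(vapply(mats, nrow, integer(1)))
  if (length(n_rows) != 1) {
    stop_bad_arg("channel files disagree on row count: ",
                 paste(vapply(mats, nrow, integer(1)), collapse = ", "))
  }
  lf <- file.path(dir, labels_file)
  if (!file.exists(lf)) stop_bad_arg("missing label file: ", labels_file)
  codes <- as.integer(readLines(lf))
  if (length(codes) != n_rows) {
    stop_bad_arg("label count (", length(codes), ") != window count (",
                 n_rows, ")")
  }
  code_to_class <- setNames(names(label_map), label_map)
  keep <- codes %in% label_map
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    message(n_excluded, " window(s) with unmapped activity codes excluded")
  }
  wins <- lapply(which(keep), function(r) {
    ch <- vapply(mats, function(m) m[r, ], numeric(samples_per_row))
    analysis_window(ch, fs = fs, label = code_to_class[[as.character(codes[r])]])
  })
  attr(wins, "n_excluded") <- n_excluded
  wins
}

#' Extract features from pre-windowed data
#'
#' Applies [extract_features()] to a list of `analysis_window` objects (as
#' returned by [read_uci_inertial()]), assembling a feature set directly.
#'
#' @param windows List of `analysis_window` objects.
#' @param S,L Per-sensor least/largest counts.
#' @param fft_length,segment_length,hop Passed to [extract_features()].
#' @return A [feature_set()] with provenance `"OR"`.
#' @export
features_from_windows <- function(windows, S = 25, L = 25, fft_length = 512,
                                  segment_length = NULL, hop = NULL) {
  if (length(windows) == 0) stop_bad_arg("no windows supplied")
  rows <- lapply(windows, extract_features, S = S, L = L,
                 fft_length = fft_length, segment_length = segment_length,
                 hop = hop)
  labels <- vapply(windows, function(w) w$label, character(1))
  feature_set(do.call(rbind, rows), labels, provenance = "OR", S = S, L = L)
}

#' Default pipeline configuration
#'
#' One nested list holding every tunable of the pipeline with its default:
#' windowing, STFT, feature selection, augmentation, classifier and sweep
#' settings. The CLI echoes the effective configuration into every output
#' directory as `config.json`.
#'
#' @param ... Named overrides for top-level entries (partial lists are
#'   merged).
#' @return Nested configuration list of class `har_config`.
#' @export
har_config <- function(...) {
  cfg <- list(
    window = list(seconds = 3, overlap = 0.5),
    stft = list(fft_length = 512, segment_length = 128, hop = 64, fs = 50),
    features = list(S = 25, L = 25),
    augmentation = list(G1 = 4, G2 = 2, shuffle_seed = 1L),
    lstm = unclass(lstm_config()),
    sweep = list(learning_rates = c(0.0002, 0.003, 0.006, 0.01, 0.015)),
    seed = 1L
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = "har_config")
}

#' Echo an effective configuration (plus seeds) into an output directory
#'
#' @param cfg A [har_config()].
#' @param dir Output directory (created if needed).
#' @return Path of the written `config.json`, invisibly.
#' @export
write_config_json <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "config.json")
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
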
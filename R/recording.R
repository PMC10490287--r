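#' Continuous EEG recording container
#'
#' A light S3 container for continuous multichannel EEG: a channels x samples
#' matrix in microvolts, channel names, the sample rate in Hz, and (optionally)
#' a per-sample state label.
#'
#' @param data numeric matrix, channels x samples, amplitudes in microvolts.
#' @param channel_names character vector, one name per row of `data`.
#' @param sample_rate sampling frequency in Hz.
#' @param labels optional character/factor vector of per-sample state labels
#'   (length = number of samples).
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, channel_names, sample_rate, labels = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop_eeg("`data` must be numeric", "format_error")
  if (length(channel_names) != nrow(data)) {
    stop_eeg("number of channel names must equal number of data rows",
             "format_error")
  }
  check_scalar_number(sample_rate, "sample_rate")
  if (!is.null(labels)) {
    if (length(labels) != ncol(data)) {
      stop_eeg("label length must equal the sample count", "format_error")
    }
    labels <- as.character(labels)
  }
  rownames(data) <- channel_names
  structure(
    list(data = data, channel_names = as.character(channel_names),
         sample_rate = sample_rate, labels = labels),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sample_rate,
              ncol(x$data) / x$sample_rate))
  if (!is.null(x$labels)) {
    tab <- table(state_factor(x$labels))
    cat("labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
as_tibble.eeg_recording <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(t(x$data)))
  names(out) <- x$channel_names
  if (!is.null(x$labels)) out$label <- x$labels
  out
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

sidecar_path <- function(path) paste0(path, ".meta.yaml")

#' Write a recording to delimited text
#'
#' Writes one CSV column per channel plus a `label` column (when labels are
#' present), and a small key-value sidecar (`<path>.meta.yaml`) holding the
#' sample rate and channel names so the file round-trips without extra
#' arguments.
#'
#' @param rec an [eeg_recording()].
#' @param path output CSV path.
#' @param meta optional named list merged into the sidecar (e.g. the
#'   simulation seed and config echo).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, meta = list()) {
  stopifnot(inherits(rec, "eeg_recording"))
  readr::write_csv(as_tibble(rec), path)
  side <- c(list(sample_rate = rec$sample_rate,
                 channels = rec$channel_names,
                 label_column = if (is.null(rec$labels)) NULL else "label"),
            meta)
  yaml::write_yaml(side, sidecar_path(path))
  invisible(path)
}

#' Read a recording from delimited text
#'
#' Reads a CSV with one column per channel (amplitudes in microvolts) and a
#' per-sample label column. Column layout is taken from the explicit
#' arguments, falling back to the sidecar metadata file written by
#' [write_recording()]. Declared columns that are missing raise a format
#' error; non-numeric amplitudes raise a format error naming the first
#' offending row; undeclared extra columns are ignored with a warning.
#'
#' @param path CSV path.
#' @param channels character vector of channel column names; `NULL` means
#'   take them from the sidecar, or failing that every column except the
#'   label column.
#' @param label_col name of the label column, or `NA` for an unlabeled
#'   recording. Default "label".
#' @param sample_rate sampling rate in Hz; `NULL` means read it from the
#'   sidecar.
#' @return an [eeg_recording()].
#' @export
read_recording <- function(path, channels = NULL, label_col = "label",
                           sample_rate = NULL) {
  if (!file.exists(path)) stop_eeg(paste("no such file:", path), "format_error")
  side <- if (file.exists(sidecar_path(path))) {
    yaml::read_yaml(sidecar_path(path))
  } else list()
  sample_rate <- sample_rate %||% side$sample_rate
  if (is.null(sample_rate)) {
    stop_eeg("sample_rate not given and no sidecar metadata found",
             "format_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  channels <- channels %||% side$channels %||%
    setdiff(names(df), if (is.na(label_col)) character() else label_col)
  missing_cols <- setdiff(c(channels, if (!is.na(label_col)) label_col),
                          names(df))
  if (length(missing_cols) > 0) {
    stop_eeg(paste("declared column(s) missing from file:",
                   paste(missing_cols, collapse = ", ")), "format_error")
  }
  extra <- setdiff(names(df), c(channels, if (!is.na(label_col)) label_col))
  if (length(extra) > 0) {
    warn(paste("ignoring undeclared column(s):", paste(extra, collapse = ", ")))
  }
  amp <- matrix(NA_real_, nrow = length(channels), ncol = nrow(df),
                dimnames = list(channels, NULL))
  for (ch in channels) {
    v <- suppressWarnings(as.numeric(df[[ch]]))
    bad <- which(is.na(v) & !is.na(df[[ch]]))
    if (length(bad) > 0 || anyNA(df[[ch]])) {
      row <- if (length(bad) > 0) bad[1] else which(is.na(df[[ch]]))[1]
      stop_eeg(sprintf("non-numeric amplitude in column '%s' at data row %d",
                       ch, row), "format_error")
    }
    amp[ch, ] <- v
  }
  labels <- if (!is.na(label_col)) df[[label_col]] else NULL
  eeg_recording(amp, channels, sample_rate, labels)
}
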
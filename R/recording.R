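#' Multichannel EEG recording container
#'
#' A `recording` holds one subject's continuous multichannel signal
#' together with its sampling rate, montage, group label and condition
#' annotations. Annotations are half-open sample intervals
#' `[start, end)` (0-based) tagged with a condition (`"EO"` eyes-open /
#' `"EC"` eyes-closed).
#'
#' @param data Channels x samples numeric matrix; row order matches the
#'   montage.
#' @param fs Sampling rate in Hz.
#' @param montage A [montage()] tibble with one row per data row.
#' @param annotations Tibble/data.frame with columns `condition`,
#'   `start`, `end` (samples, half-open, 0-based); may have zero rows.
#' @param subject_id Subject identifier string.
#' @param group Group label, `"case"` or `"control"` (or `NA`).
#' @return An object of class `"recording"`.
#' @export
recording <- function(data, fs, montage, annotations = NULL,
                      subject_id = "S01", group = NA_character_) {
  if (!is.matrix(data)) data <- as.matrix(data)
  if (nrow(data) != nrow(montage)) {
    abort("`data` must have one row per montage channel.")
  }
  if (!is.numeric(fs) || fs <= 0) abort("`fs` must be positive.")
  if (is.null(annotations)) {
    annotations <- tibble::tibble(condition = character(),
                                  start = integer(), end = integer())
  }
  annotations <- tibble::as_tibble(annotations)
  if (nrow(annotations)) {
    annotations <- dplyr::arrange(annotations, .data$start)
    if (any(annotations$start < 0) || any(annotations$end > ncol(data))) {
      abort("Annotations out of data bounds.")
    }
    if (any(annotations$end <= annotations$start)) {
      abort("Annotations must satisfy start < end.")
    }
    if (nrow(annotations) > 1 &&
        any(annotations$start[-1] < annotations$end[-nrow(annotations)])) {
      abort("Annotations must not overlap.")
    }
  }
  rownames(data) <- montage$label
  structure(list(subject_id = subject_id, group = group, data = data,
                 fs = fs, montage = montage, annotations = annotations),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s (%s): %d channels x %d samples @ %g Hz, %d annotation(s)\n",
              x$subject_id, x$group %||% "?", nrow(x$data), ncol(x$data),
              x$fs, nrow(x$annotations)))
  invisible(x)
}

#' Tidy a recording into a long tibble
#'
#' One row per (channel, sample), with the condition active at that
#' sample (NA outside annotated intervals). Intended for plotting and
#' inspection of short recordings; the wide matrix in `x$data` remains
#' the computational representation.
#'
#' @param x A [recording()].
#' @param ... Unused.
#' @return Tibble with columns `channel`, `time`, `value`, `condition`.
#' @export
tidy.recording <- function(x, ...) {
  n <- ncol(x$data)
  cond <- rep(NA_character_, n)
  for (k in seq_len(nrow(x$annotations))) {
    a <- x$annotations[k, ]
    cond[(a$start + 1):a$end] <- a$condition
  }
  tibble::tibble(
    channel = rep(rownames(x$data), each = n),
    time = rep((seq_len(n) - 1) / x$fs, nrow(x$data)),
    value = as.vector(t(x$data)),
    condition = rep(cond, nrow(x$data)))
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' Write / read a recording in the array fixture format
#'
#' The fixture format stores the raw signal as a flat little-endian
#' float64 binary (`<stem>.bin`, column-major over the channels x
#' samples matrix) next to a JSON sidecar (`<stem>.json`) holding the
#' sampling rate, montage, annotations, subject id and group. It is the
#' package's simple array container for round-tripping recordings.
#'
#' @param rec A [recording()].
#' @param stem Path stem (without extension).
#' @return `write_recording()` returns `stem` invisibly;
#'   `read_recording()` returns a [recording()].
#' @export
write_recording <- function(rec, stem) {
  meta <- list(
    subject_id = rec$subject_id, group = rec$group, fs = rec$fs,
    n_channels = nrow(rec$data), n_samples = ncol(rec$data),
    montage = as.data.frame(rec$montage),
    annotations = as.data.frame(rec$annotations))
  jsonlite::write_json(meta, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(paste0(stem, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$data), con, size = 8, endian = "little")
  invisible(stem)
}

#' @rdname write_recording
#' @export
read_recording <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  con <- file(paste0(stem, ".bin"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = meta$n_channels * meta$n_samples,
                  size = 8, endian = "little")
  mon <- montage(meta$montage$label, meta$montage$x, meta$montage$y,
                 meta$montage$region)
  ann <- tibble::as_tibble(meta$annotations)
  recording(matrix(vals, nrow = meta$n_channels), fs = as.numeric(meta$fs),
            montage = mon, annotations = ann,
            subject_id = meta$subject_id, group = meta$group)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
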
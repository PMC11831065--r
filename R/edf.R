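# Minimal EDF+C reader/writer.
#
# Supports what the pipeline needs: continuous 16-bit signals at one
# common sampling rate, 1-second data records, and condition
# annotations (EO/EC intervals) stored as EDF+ time-stamped annotation
# lists in a dedicated "EDF Annotations" signal. Not a general-purpose
# EDF library: discontinuous files, per-signal rates and sub-second
# records are out of scope.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

# format a physical min/max in at most 8 ASCII characters
edf_num8 <- function(v) {
  for (d in 7:1) {
    s <- formatC(v, format = "g", digits = d)
    if (nchar(s) <= 8) return(s)
  }
  s
}

#' Write a recording to EDF+
#'
#' Serialises a [recording()] as an EDF+C file: one 16-bit signal per
#' channel (physical range from the per-channel data range) plus an
#' annotations signal carrying the condition intervals. The recording
#' is zero-padded to a whole number of 1-second records; subject id and
#' group are stored in the patient-identification header field.
#'
#' @param rec A [recording()]; `fs` must be an integer.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) abort("EDF export needs an integer sampling rate.")
  fs <- as.integer(round(fs))
  n_ch <- nrow(rec$data)
  n_rec <- ceiling(ncol(rec$data) / fs)
  data <- rec$data
  if (ncol(data) < n_rec * fs) {
    data <- cbind(data, matrix(0, n_ch, n_rec * fs - ncol(data)))
  }

  pmin_ <- apply(data, 1, min); pmax_ <- apply(data, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  # widen by 0.1% then snap to the 8-character header representation so
  # writer and reader share the exact scaling
  span <- pmax_ - pmin_
  pmin_ <- vapply(pmin_ - 0.001 * span, function(v) as.numeric(edf_num8(v)), 0)
  pmax_ <- vapply(pmax_ + 0.001 * span, function(v) as.numeric(edf_num8(v)), 0)
  dmin <- -32768; dmax <- 32767

  ann_samples <- 60L  # 120 bytes per record for annotation TALs

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(edf_pad(x, width), con, nchars = width,
                                     eos = NULL)
  # fixed header (256 bytes)
  wr("0", 8)
  wr(paste(rec$subject_id, rec$group %||% "X"), 80)
  wr("Startdate 01-JAN-2026 coherenet synthetic", 80)
  wr("01.01.26", 8)
  wr("00.00.00", 8)
  wr(256 * (1 + n_ch + 1), 8)
  wr("EDF+C", 44)
  wr(n_rec, 8)
  wr("1", 8)
  wr(n_ch + 1, 4)
  # signal headers
  for (l in rec$montage$label) wr(paste("EEG", l), 16)
  wr("EDF Annotations", 16)
  for (i in seq_len(n_ch + 1)) wr("", 80)                      # transducer
  for (i in seq_len(n_ch)) wr("uV", 8); wr("", 8)              # dimension
  for (v in pmin_) wr(edf_num8(v), 8); wr("-1", 8)             # phys min
  for (v in pmax_) wr(edf_num8(v), 8); wr("1", 8)              # phys max
  for (i in seq_len(n_ch)) wr(dmin, 8); wr(dmin, 8)            # dig min
  for (i in seq_len(n_ch)) wr(dmax, 8); wr(dmax, 8)            # dig max
  for (i in seq_len(n_ch + 1)) wr("", 80)                      # prefilter
  for (i in seq_len(n_ch)) wr(fs, 8); wr(ann_samples, 8)       # samples/record
  for (i in seq_len(n_ch + 1)) wr("", 32)                      # reserved

  # digital conversion
  gain <- (dmax - dmin) / (pmax_ - pmin_)
  dig <- round((data - pmin_) * gain + dmin)
  dig <- pmin(pmax(dig, dmin), dmax)

  ann_by_rec <- vector("list", n_rec)
  for (k in seq_len(nrow(rec$annotations))) {
    a <- rec$annotations[k, ]
    r <- floor(a$start / fs) + 1
    tal <- sprintf("+%g\x15%g\x14%s\x14", a$start / fs,
                   (a$end - a$start) / fs, a$condition)
    ann_by_rec[[r]] <- c(ann_by_rec[[r]], tal)
  }

  for (r in seq_len(n_rec)) {
    block <- dig[, ((r - 1) * fs + 1):(r * fs), drop = FALSE]
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
    tals <- paste0(sprintf("+%d\x14\x14", r - 1),
                   paste(ann_by_rec[[r]] %||% "", collapse = ""))
    raw_tal <- charToRaw(tals)
    if (length(raw_tal) > 2 * ann_samples) {
      abort("Annotation record overflow; increase annotation signal size.")
    }
    writeBin(c(raw_tal, raw(2 * ann_samples - length(raw_tal))), con)
  }
  invisible(path)
}

#' Read an EDF/EDF+ file into a recording
#'
#' Reads a (coherenet-style) EDF+C file: all ordinary signals must
#' share one sampling rate; `EO`/`EC` annotations become condition
#' intervals. Channel labels are matched against `montage` when given,
#' otherwise a schematic montage is synthesised from the labels.
#'
#' @param path EDF file path.
#' @param montage Optional [montage()] supplying positions/regions for
#'   the channel labels in the file.
#' @return A [recording()].
#' @export
read_edf <- function(path, montage = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                                   # version
  patient <- rd(80)
  rd(80); rd(8); rd(8)                    # recording id, date, time
  rd(8)                                   # header bytes
  rd(44)                                  # reserved
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  n_sig <- as.integer(rd(4))

  labels <- vapply(seq_len(n_sig), function(i) rd(16), "")
  for (i in seq_len(n_sig)) rd(80)        # transducer
  for (i in seq_len(n_sig)) rd(8)         # dimension
  pmin_ <- as.numeric(vapply(seq_len(n_sig), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(n_sig), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(n_sig), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(n_sig), function(i) rd(8), ""))
  for (i in seq_len(n_sig)) rd(80)        # prefilter
  spr <- as.integer(vapply(seq_len(n_sig), function(i) rd(8), ""))
  for (i in seq_len(n_sig)) rd(32)        # reserved

  is_ann <- grepl("EDF Annotations", labels, fixed = TRUE)
  sig_idx <- which(!is_ann)
  fs_all <- spr[sig_idx] / rec_dur
  if (length(unique(fs_all)) != 1) {
    abort("All EEG signals must share one sampling rate.")
  }
  fs <- fs_all[1]

  data <- matrix(0, length(sig_idx), n_rec * spr[sig_idx[1]])
  ann_raw <- raw()
  for (r in seq_len(n_rec)) {
    for (s in seq_len(n_sig)) {
      if (is_ann[s]) {
        ann_raw <- c(ann_raw, readBin(con, "raw", n = 2 * spr[s]))
      } else {
        v <- readBin(con, "integer", n = spr[s], size = 2, endian = "little")
        row <- match(s, sig_idx)
        g <- (pmax_[s] - pmin_[s]) / (dmax[s] - dmin[s])
        data[row, ((r - 1) * spr[s] + 1):(r * spr[s])] <-
          (v - dmin[s]) * g + pmin_[s]
      }
    }
  }

  ann <- parse_edf_annotations(ann_raw, fs)
  ch_labels <- sub("^EEG ", "", labels[sig_idx])
  if (is.null(montage)) {
    montage <- schematic_montage(length(ch_labels))
    montage$label <- ch_labels
  } else {
    montage <- montage[match(ch_labels, montage$label), ]
    if (anyNA(montage$label)) abort("EDF channel labels not found in montage.")
    class(montage) <- c("montage", class(tibble::tibble()))
  }
  parts <- strsplit(patient, " +")[[1]]
  subject_id <- parts[1] %||% "S01"
  group <- if (length(parts) > 1 && parts[2] %in% c("case", "control")) {
    parts[2]
  } else NA_character_
  recording(data, fs = fs, montage = montage, annotations = ann,
            subject_id = subject_id, group = group)
}

parse_edf_annotations <- function(ann_raw, fs) {
  txt <- rawToChar(ann_raw[ann_raw != as.raw(0)], multiple = FALSE)
  out <- list()
  # each fragment may contain record keepers "+t" and TALs "+on\x15dur\x14lab"
  pieces <- unlist(strsplit(txt, "\x14"))
  i <- 1
  while (i <= length(pieces)) {
    p <- pieces[i]
    if (grepl("\x15", p)) {
      od <- strsplit(p, "\x15")[[1]]
      onset <- as.numeric(od[1]); dur <- as.numeric(od[2])
      lab <- if (i + 1 <= length(pieces) &&
                 !grepl("^[+-]", pieces[i + 1])) pieces[i + 1] else ""
      if (nzchar(lab)) {
        out[[length(out) + 1]] <- tibble::tibble(
          condition = lab,
          start = as.integer(round(onset * fs)),
          end = as.integer(round((onset + dur) * fs)))
        i <- i + 2
        next
      }
    }
    i <- i + 1
  }
  if (!length(out)) {
    return(tibble::tibble(condition = character(), start = integer(),
                          end = integer()))
  }
  dplyr::bind_rows(out) |> dplyr::arrange(.data$start)
}
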
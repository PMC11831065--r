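#' Preprocessing configuration
#'
#' Parameters of the deterministic preprocessing chain: zero-phase
#' band-pass filtering, kurtosis-based bad-channel rejection, average
#' re-referencing, and condition segmentation with a leading-interval
#' discard. Defaults follow a standard resting-state protocol:
#' 0.5--35 Hz pass band, kurtosis z threshold 5, first 4 s of each
#' condition interval discarded (auditory-cue transient), analysis
#' epochs capped at 56 s.
#'
#' @param highpass,lowpass Pass-band edges, Hz.
#' @param kurtosis_z_threshold Absolute z-score of channel excess
#'   kurtosis (across channels) beyond which a channel is rejected.
#' @param discard_lead_s Seconds dropped from the start of every
#'   annotated interval.
#' @param epoch_s Maximum analysis-epoch length, seconds (longer
#'   remainders are truncated to this).
#' @return A list of class `"preprocess_config"`.
#' @export
preprocess_config <- function(highpass = 0.5, lowpass = 35,
                              kurtosis_z_threshold = 5,
                              discard_lead_s = 4, epoch_s = 56) {
  if (highpass <= 0 || lowpass <= highpass) {
    abort("Need 0 < highpass < lowpass.")
  }
  if (kurtosis_z_threshold <= 0) abort("`kurtosis_z_threshold` must be > 0.")
  if (discard_lead_s < 0) abort("`discard_lead_s` must be >= 0.")
  structure(list(highpass = highpass, lowpass = lowpass,
                 kurtosis_z_threshold = kurtosis_z_threshold,
                 discard_lead_s = discard_lead_s, epoch_s = epoch_s),
            class = "preprocess_config")
}

#' Zero-phase band-pass filter a recording
#'
#' Applies a zero-phase (forward-backward) Butterworth band-pass
#' per channel. Zero-phase filtering leaves cross-spectral phase -- and
#' hence coherence -- undistorted. Output length equals input length and
#' annotations are preserved.
#'
#' @param rec A [recording()].
#' @param cfg A [preprocess_config()].
#' @return The filtered [recording()].
#' @export
bandpass_filter <- function(rec, cfg = preprocess_config()) {
  if (rec$fs <= 2 * cfg$lowpass) {
    abort("Sampling rate must exceed twice the low-pass edge.")
  }
  bf <- signal::butter(4, c(cfg$highpass, cfg$lowpass) / (rec$fs / 2),
                       type = "pass")
  min_len <- 3 * (length(bf$a) - 1)
  if (ncol(rec$data) <= min_len) {
    abort("Recording too short to filter (needs > 3 x filter order samples).")
  }
  rec$data <- t(apply(rec$data, 1, function(x)
    as.numeric(signal::filtfilt(bf, x))))
  rownames(rec$data) <- rec$montage$label
  rec
}

# Fisher excess kurtosis with population moments
excess_kurtosis <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 == 0) return(0)
  mean(x^4) / m2^2 - 3
}

#' Detect bad channels by kurtosis
#'
#' Computes the Fisher excess kurtosis of every channel and flags those
#' whose z-score across channels, `(k_i - mean(k)) / sd(k)`, exceeds the
#' threshold in absolute value. Single pass; no re-iteration after
#' removal. When the channel kurtoses have zero spread no channel is
#' rejected. Note that for `n` channels the largest attainable |z| of a
#' single outlier is `(n - 1) / sqrt(n)`, so the default threshold of 5
#' can only fire on montages with at least 27 channels.
#'
#' @inheritParams bandpass_filter
#' @return Character vector of rejected channel labels (possibly empty).
#' @export
detect_bad_channels <- function(rec, cfg = preprocess_config()) {
  if (nrow(rec$data) < 3) abort("Need at least 3 channels.")
  k <- apply(rec$data, 1, excess_kurtosis)
  s <- sd(k)
  if (!is.finite(s) || s == 0) return(character())
  z <- (k - mean(k)) / s
  bad <- rownames(rec$data)[abs(z) > cfg$kurtosis_z_threshold]
  if (length(bad)) {
    inform(sprintf("Rejecting channel(s) %s (kurtosis z: %s)",
                   paste(bad, collapse = ", "),
                   paste(round(z[abs(z) > cfg$kurtosis_z_threshold], 2),
                         collapse = ", ")))
  }
  bad
}

#' Re-reference to the channel average
#'
#' Subtracts the instantaneous mean over channels from every channel,
#' so each sample's channel mean is zero. Idempotent.
#'
#' @param rec A [recording()].
#' @return The re-referenced [recording()].
#' @export
rereference_average <- function(rec) {
  if (nrow(rec$data) < 2) abort("Need at least 2 channels to re-reference.")
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec
}

#' Drop channels from a recording
#'
#' @param rec A [recording()].
#' @param labels Channel labels to remove.
#' @return The reduced [recording()] (montage reduced accordingly).
#' @export
drop_channels <- function(rec, labels) {
  if (!length(labels)) return(rec)
  keep <- !(rec$montage$label %in% labels)
  if (sum(keep) < 2) abort("Cannot drop channels: fewer than 2 would remain.")
  rec$data <- rec$data[keep, , drop = FALSE]
  rec$montage <- rec$montage[keep, ]
  class(rec$montage) <- c("montage", class(tibble::tibble()))
  rec
}

#' Epoch set
#'
#' Container for one subject x condition's analysis epochs: a list of
#' equally-sized channels x samples matrices plus sampling rate,
#' (possibly reduced) montage and the labels rejected upstream.
#'
#' @param epochs List of channels x samples matrices (same channel
#'   count; possibly different lengths when remainders were kept).
#' @param fs Sampling rate, Hz.
#' @param montage A [montage()] matching the epoch rows.
#' @param condition `"EO"` or `"EC"`.
#' @param subject_id,group Carried subject metadata.
#' @param rejected_channels Labels removed before epoching.
#' @return An object of class `"epoch_set"`.
#' @export
epoch_set <- function(epochs, fs, montage, condition,
                      subject_id = "S01", group = NA_character_,
                      rejected_channels = character()) {
  if (!length(epochs)) abort("Epoch set needs at least one epoch.")
  nch <- vapply(epochs, nrow, 0L)
  if (length(unique(nch)) != 1 || nch[1] != nrow(montage)) {
    abort("All epochs must have one row per montage channel.")
  }
  if (any(vapply(epochs, ncol, 0L) < 1)) abort("Empty epoch.")
  if (length(intersect(rejected_channels, montage$label))) {
    abort("Rejected channels must not remain in the montage.")
  }
  structure(list(subject_id = subject_id, group = group,
                 condition = condition, epochs = epochs, fs = fs,
                 montage = montage, rejected_channels = rejected_channels),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %s/%s (%s): %d epoch(s) of %s samples, %d channels @ %g Hz\n",
              x$subject_id, x$condition, x$group %||% "?", length(x$epochs),
              paste(unique(vapply(x$epochs, ncol, 0L)), collapse = "/"),
              nrow(x$montage), x$fs))
  invisible(x)
}

#' Segment a recording into condition epoch sets
#'
#' For every annotated interval, drops the first `discard_lead_s`
#' seconds, truncates the remainder to `epoch_s` seconds if longer
#' (keeping shorter remainders with a message), and groups the
#' resulting epochs by condition.
#'
#' @inheritParams bandpass_filter
#' @param rejected_channels Labels to exclude before epoching.
#' @return Named list of [epoch_set()]s, one per condition present.
#' @export
segment_conditions <- function(rec, cfg = preprocess_config(),
                               rejected_channels = character()) {
  if (!nrow(rec$annotations)) abort("Recording has no condition annotations.")
  lead <- round(cfg$discard_lead_s * rec$fs)
  max_len <- round(cfg$epoch_s * rec$fs)
  if (any(rec$annotations$end - rec$annotations$start <= lead)) {
    abort("Annotated interval shorter than the leading discard.")
  }
  rec <- drop_channels(rec, rejected_channels)
  out <- list()
  for (cond in unique(rec$annotations$condition)) {
    ivs <- rec$annotations[rec$annotations$condition == cond, ]
    eps <- lapply(seq_len(nrow(ivs)), function(k) {
      a <- ivs$start[k] + lead
      b <- ivs$end[k]
      if (b - a > max_len) b <- a + max_len
      if (b - a < max_len) {
        inform(sprintf("%s/%s interval %d yields a short epoch (%.1f s < %.1f s); kept.",
                       rec$subject_id, cond, k, (b - a) / rec$fs, cfg$epoch_s))
      }
      rec$data[, (a + 1):b, drop = FALSE]
    })
    out[[cond]] <- epoch_set(eps, fs = rec$fs, montage = rec$montage,
                             condition = cond, subject_id = rec$subject_id,
                             group = rec$group,
                             rejected_channels = rejected_channels)
  }
  out
}

#' Full preprocessing chain for one recording
#'
#' Band-pass filter, kurtosis-based bad-channel rejection, channel
#' removal, average re-referencing, an optional cleaning hook, then
#' condition segmentation. The hook (`clean_fun`, a
#' `recording -> recording` function, default identity) is where an
#' external artifact-removal stage such as ICA would plug in.
#'
#' @inheritParams bandpass_filter
#' @param clean_fun Optional `function(recording) recording` applied
#'   after re-referencing.
#' @return Named list of [epoch_set()]s by condition, with the rejected
#'   labels attached as attribute `"rejected_channels"`.
#' @export
preprocess_recording <- function(rec, cfg = preprocess_config(),
                                 clean_fun = NULL) {
  rec <- bandpass_filter(rec, cfg)
  bad <- detect_bad_channels(rec, cfg)
  rec <- drop_channels(rec, bad)
  rec <- rereference_average(rec)
  if (!is.null(clean_fun)) rec <- clean_fun(rec)
  out <- segment_conditions(rec, cfg, rejected_channels = bad)
  attr(out, "rejected_channels") <- bad
  out
}
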
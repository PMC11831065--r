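#' Welch estimation configuration
#'
#' Parameters of the Welch auto-/cross-spectral estimator. Defaults:
#' 2-s Hann-tapered segments, 50% overlap, per-segment constant
#' detrend. At 250 Hz this gives a 0.5-Hz frequency grid, which
#' resolves every band boundary of [eeg_bands()] (all are multiples of
#' 0.5 Hz), and roughly 165 segments over a 3 x 56-s condition, making
#' the 1/K independent-noise coherence bias negligible (~0.006).
#'
#' @param segment_s Segment length, seconds.
#' @param overlap_fraction Segment overlap in \[0, 1).
#' @param window Taper; only `"hann"` is provided.
#' @param detrend `"constant"` (subtract each segment's mean per
#'   channel) or `"none"`.
#' @return A list of class `"welch_config"`.
#' @export
welch_config <- function(segment_s = 2, overlap_fraction = 0.5,
                         window = "hann", detrend = "constant") {
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    abort("`overlap_fraction` must be in [0, 1).")
  }
  window <- match.arg(window, "hann")
  detrend <- match.arg(detrend, c("constant", "none"))
  structure(list(segment_s = segment_s, overlap_fraction = overlap_fraction,
                 window = window, detrend = detrend),
            class = "welch_config")
}

#' The 11 canonical EEG frequency bands
#'
#' Band definitions used throughout: delta (1--4 Hz), theta (4--7.5),
#' theta1 (4--6), theta2 (6--7.5), alpha (7.5--13), alpha1 (7.5--9.5),
#' alpha2 (9.5--11), alpha3 (11--13), beta (13--35), beta1 (13--20),
#' beta2 (20--35). Band membership is half-open `[low, high)`, so each
#' boundary bin belongs to exactly one band and sub-bands partition
#' their parent.
#'
#' @return Tibble with columns `band`, `low`, `high`.
#' @export
eeg_bands <- function() {
  tibble::tribble(
    ~band,     ~low, ~high,
    "delta",    1,    4,
    "theta",    4,    7.5,
    "theta1",   4,    6,
    "theta2",   6,    7.5,
    "alpha",    7.5, 13,
    "alpha1",   7.5,  9.5,
    "alpha2",   9.5, 11,
    "alpha3",  11,   13,
    "beta",    13,   35,
    "beta1",   13,   20,
    "beta2",   20,   35)
}

#' Welch auto- and cross-spectra of an epoch set
#'
#' Tiles Hann-tapered segments of `segment_s` seconds with the
#' configured overlap within each epoch (segments never straddle epoch
#' boundaries), FFTs them, and averages periodograms and
#' cross-periodograms over all segments of all epochs, with one-sided
#' density normalisation. Cross-spectra are kept for every unordered
#' channel pair.
#'
#' @param es An [epoch_set()] (or a bare channels x samples matrix,
#'   with `fs` taken from `cfg_fs`).
#' @param cfg A [welch_config()].
#' @param cfg_fs Sampling rate when `es` is a bare matrix.
#' @return A list of class `"spectral_estimate"` with elements `freqs`
#'   (Hz grid), `Pxx` (channels x freqs auto-spectral densities),
#'   `cross` (channels x channels x freqs complex cross-spectral
#'   densities, Hermitian in the first two dimensions), `K` (number of
#'   averaged segments) and `labels`.
#' @export
welch_spectra <- function(es, cfg = welch_config(), cfg_fs = NULL) {
  if (inherits(es, "epoch_set")) {
    epochs <- es$epochs; fs <- es$fs; labels <- es$montage$label
  } else {
    if (is.null(cfg_fs)) abort("`cfg_fs` required for a bare matrix.")
    epochs <- list(as.matrix(es)); fs <- cfg_fs
    labels <- rownames(epochs[[1]]) %||% paste0("ch", seq_len(nrow(epochs[[1]])))
  }
  L <- round(cfg$segment_s * fs)
  if (L < 8) abort("Welch segments must be at least 8 samples long.")
  step <- max(1L, round(L * (1 - cfg$overlap_fraction)))
  w <- hann_window(L)
  scale <- 1 / (fs * sum(w^2))
  n_freq <- L %/% 2 + 1
  freqs <- (seq_len(n_freq) - 1) * fs / L
  n_ch <- nrow(epochs[[1]])

  segs <- list()
  for (ep in epochs) {
    n <- ncol(ep)
    if (n < L) {
      warn(sprintf("Skipping epoch of %d samples (< one %d-sample segment).",
                   n, L))
      next
    }
    starts <- seq(1L, n - L + 1L, by = step)
    for (s0 in starts) segs[[length(segs) + 1L]] <- ep[, s0:(s0 + L - 1), drop = FALSE]
  }
  K <- length(segs)
  if (K == 0) abort("No epoch is long enough for a single Welch segment.")

  # FFT all channels of all segments; XA[f, ch, k]
  XA <- array(0i, dim = c(n_freq, n_ch, K))
  for (k in seq_len(K)) {
    seg <- segs[[k]]
    if (cfg$detrend == "constant") seg <- seg - rowMeans(seg)
    X <- mvfft(t(seg * rep(w, each = n_ch)))
    XA[, , k] <- X[seq_len(n_freq), , drop = FALSE]
  }

  # one-sided scaling: interior bins doubled; DC (and Nyquist for even L) not
  one_sided <- rep(2, n_freq)
  one_sided[1] <- 1
  if (L %% 2 == 0) one_sided[n_freq] <- 1

  cross <- array(0i, dim = c(n_ch, n_ch, n_freq),
                 dimnames = list(labels, labels, NULL))
  for (f in seq_len(n_freq)) {
    Xf <- matrix(XA[f, , ], nrow = n_ch, ncol = K)   # ch x K
    cross[, , f] <- (Xf %*% Conj(t(Xf))) * (scale * one_sided[f] / K)
  }
  Pxx <- matrix(0, n_ch, n_freq, dimnames = list(labels, NULL))
  for (f in seq_len(n_freq)) {
    Pxx[, f] <- Re(diag(matrix(cross[, , f], n_ch, n_ch)))
  }

  structure(list(freqs = freqs, Pxx = Pxx, cross = cross, K = K,
                 labels = labels, fs = fs, cfg = cfg),
            class = "spectral_estimate")
}

hann_window <- function(L) {
  0.5 - 0.5 * cos(2 * pi * seq_len(L) / L)  # periodic Hann
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf("<spectral_estimate> %d channels, %d bins (0-%g Hz, df = %g Hz), K = %d segments\n",
              length(x$labels), length(x$freqs), max(x$freqs),
              x$freqs[2] - x$freqs[1], x$K))
  invisible(x)
}

#' Magnitude-squared coherence of a channel pair
#'
#' Evaluates `|Pxy(f)|^2 / (Pxx(f) Pyy(f))` on the estimate's frequency
#' grid, clipped to \[0, 1\] against rounding. Symmetric in pair order.
#' Requires `K >= 2` averaged segments (a single segment gives
#' identically 1). Bins with zero power on either channel are returned
#' as `NA` (undefined coherence) and are excluded from band averages.
#'
#' @param se A [welch_spectra()] estimate.
#' @param chan_a,chan_b Channel labels.
#' @return Tibble with columns `freq`, `coherence`.
#' @export
msc <- function(se, chan_a, chan_b) {
  stopifnot(inherits(se, "spectral_estimate"))
  if (se$K < 2) {
    abort("Coherence from a single Welch segment is degenerate (K must be >= 2).")
  }
  i <- match(chan_a, se$labels); j <- match(chan_b, se$labels)
  if (is.na(i) || is.na(j)) abort("Unknown channel label.")
  # canonicalise to the upper-triangle entry so msc(a, b) and msc(b, a)
  # are bit-identical
  if (i > j) { tmp <- i; i <- j; j <- tmp }
  pxx <- se$Pxx[i, ]; pyy <- se$Pxx[j, ]
  num <- Mod(se$cross[i, j, ])^2
  den <- pxx * pyy
  coh <- ifelse(den > 0, pmin(1, pmax(0, num / den)), NA_real_)
  tibble::tibble(freq = se$freqs, coherence = coh)
}

# full coherence array [ch, ch, freq]; NA where a channel has zero power
msc_array <- function(se) {
  if (se$K < 2) {
    abort("Coherence from a single Welch segment is degenerate (K must be >= 2).")
  }
  n_ch <- length(se$labels); n_f <- length(se$freqs)
  out <- array(NA_real_, dim = c(n_ch, n_ch, n_f),
               dimnames = list(se$labels, se$labels, NULL))
  for (f in seq_len(n_f)) {
    p <- se$Pxx[, f]
    den <- outer(p, p)
    v <- Mod(se$cross[, , f])^2 / den
    v[den <= 0] <- NA_real_
    out[, , f] <- pmin(1, pmax(0, v))
  }
  out
}

#' Mean coherence over a frequency band
#'
#' Unweighted mean of per-bin coherence over grid frequencies `f` with
#' `low <= f < high` (half-open), skipping undefined (`NA`) bins.
#'
#' @param coherence Per-frequency coherence values.
#' @param freqs Matching frequency grid, Hz.
#' @param low,high Band edges, Hz.
#' @return Scalar mean coherence.
#' @export
band_average <- function(coherence, freqs, low, high) {
  sel <- freqs >= low & freqs < high
  if (!any(sel)) {
    abort(sprintf("No frequency bin in [%g, %g) Hz: Welch resolution too coarse.",
                  low, high))
  }
  mean(coherence[sel], na.rm = TRUE)
}

#' Per-subject band coherence profile
#'
#' Composes [welch_spectra()], [msc()] and [band_average()] over every
#' unordered channel pair and every band: the subject's coherence
#' profile for one condition, in long format. This tibble (and its
#' row-bound cohort version) is the contract between the spectral stage
#' and all downstream group statistics.
#'
#' @param es An [epoch_set()].
#' @param wcfg A [welch_config()].
#' @param bands Band definition tibble as from [eeg_bands()].
#' @return Tibble with columns `subject_id`, `group`, `condition`,
#'   `band`, `chan_i`, `chan_j`, `coherence` (pairs with `chan_i`
#'   before `chan_j` in montage order).
#' @export
coherence_profile <- function(es, wcfg = welch_config(), bands = eeg_bands()) {
  stopifnot(inherits(es, "epoch_set"))
  se <- welch_spectra(es, wcfg)
  coh <- msc_array(se)
  pairs <- channel_pairs(se$labels)
  ii <- match(pairs$chan_i, se$labels)
  jj <- match(pairs$chan_j, se$labels)
  res <- lapply(seq_len(nrow(bands)), function(b) {
    sel <- se$freqs >= bands$low[b] & se$freqs < bands$high[b]
    if (!any(sel)) {
      abort(sprintf("Band %s is empty on this frequency grid.", bands$band[b]))
    }
    sub <- coh[, , sel, drop = FALSE]
    bm <- apply(sub, c(1, 2), mean, na.rm = TRUE)
    tibble::tibble(band = bands$band[b],
                   chan_i = pairs$chan_i, chan_j = pairs$chan_j,
                   coherence = bm[cbind(ii, jj)])
  })
  dplyr::bind_rows(res) |>
    dplyr::mutate(subject_id = es$subject_id, group = es$group,
                  condition = es$condition, .before = 1)
}

#' Cohort coherence profiles
#'
#' Preprocesses every recording of a cohort and computes its coherence
#' profile for each condition, returning one long tibble.
#'
#' @param recordings List of [recording()]s.
#' @param pcfg A [preprocess_config()].
#' @param wcfg A [welch_config()].
#' @param bands Band tibble as from [eeg_bands()].
#' @param clean_fun Optional cleaning hook, see [preprocess_recording()].
#' @return Long profile tibble (see [coherence_profile()]).
#' @export
cohort_coherence <- function(recordings, pcfg = preprocess_config(),
                             wcfg = welch_config(), bands = eeg_bands(),
                             clean_fun = NULL) {
  purrr::map(recordings, function(rec) {
    sets <- preprocess_recording(rec, pcfg, clean_fun)
    purrr::map(sets, coherence_profile, wcfg = wcfg, bands = bands) |>
      dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Symmetric band-coherence matrix from a long profile
#'
#' Rebuilds the channels x channels coherence matrix (diagonal 1) for
#' one subject x condition x band slice of a profile tibble.
#'
#' @param profile Profile tibble filtered to a single subject,
#'   condition and band.
#' @param labels Optional channel ordering; defaults to order of
#'   appearance.
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
profile_matrix <- function(profile, labels = NULL) {
  if (is.null(labels)) labels <- unique(c(profile$chan_i, profile$chan_j))
  m <- matrix(NA_real_, length(labels), length(labels),
              dimnames = list(labels, labels))
  diag(m) <- 1
  i <- match(profile$chan_i, labels); j <- match(profile$chan_j, labels)
  m[cbind(i, j)] <- profile$coherence
  m[cbind(j, i)] <- profile$coherence
  m
}
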
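#' Band-limited oscillatory source specification
#'
#' A source is Gaussian white noise band-pass filtered (zero-phase
#' 4th-order Butterworth) to `[center_freq - bandwidth/2,
#' center_freq + bandwidth/2]` and mixed into a subset of channels.
#' Channels sharing a source acquire pairwise coherence in the source
#' band, controllable through the mixing gain and the noise level (see
#' [analytic_coherence()]). Group and condition multipliers let a
#' source be attenuated in one group (a planted connectivity deficit)
#' or restricted to one recording condition.
#'
#' @param center_freq Source centre frequency, Hz.
#' @param bandwidth Full bandwidth, Hz.
#' @param target_channels Character vector of montage labels receiving
#'   the source.
#' @param gain Mixing amplitude (dimensionless, >= 0).
#' @param group_gain_scale Named numeric, multipliers for `case` and
#'   `control` subjects.
#' @param condition_gain_scale Named numeric, multipliers for the `EO`
#'   and `EC` conditions.
#' @return A list of class `"source_spec"`.
#' @export
source_spec <- function(center_freq, bandwidth, target_channels, gain = 1,
                        group_gain_scale = c(case = 1, control = 1),
                        condition_gain_scale = c(EO = 1, EC = 1)) {
  if (center_freq - bandwidth / 2 <= 0) {
    abort("Source band must lie above 0 Hz.")
  }
  if (gain < 0 || any(group_gain_scale < 0) || any(condition_gain_scale < 0)) {
    abort("Gains and gain scales must be non-negative.")
  }
  if (!all(c("case", "control") %in% names(group_gain_scale))) {
    abort("`group_gain_scale` needs named entries for case and control.")
  }
  if (!all(c("EO", "EC") %in% names(condition_gain_scale))) {
    abort("`condition_gain_scale` needs named entries for EO and EC.")
  }
  structure(list(center_freq = center_freq, bandwidth = bandwidth,
                 target_channels = as.character(target_channels),
                 gain = gain, group_gain_scale = group_gain_scale,
                 condition_gain_scale = condition_gain_scale),
            class = "source_spec")
}

#' Synthetic-cohort configuration
#'
#' Defines the generative law for a two-group resting-state EEG cohort:
#' each subject's recording is a sum of shared band-limited sources
#' (see [source_spec()]) and independent 1/f^`noise_exponent`
#' background noise, organised as `n_epochs` alternating annotated
#' intervals per condition (EO first), each `epoch_s` seconds long.
#' Defaults emulate a 6-min recording alternating 1-min eyes-open /
#' eyes-closed blocks three times at 250 Hz.
#'
#' @param montage A [montage()].
#' @param n_per_group Subjects per group (>= 2).
#' @param sources List of [source_spec()] objects.
#' @param noise_exponent Spectral slope of the background noise
#'   (power ~ 1/f^exponent).
#' @param noise_sd Standard deviation of the background noise per channel.
#' @param fs Sampling rate, Hz.
#' @param epoch_s Length of each annotated condition interval, seconds.
#' @param n_epochs Intervals per condition.
#' @param gain_jitter_sd Log-sd of the per-subject lognormal gain jitter
#'   (default 0.1, i.e. about +/-10%), so subjects are not identical
#'   replicates.
#' @param seed Integer master seed; every subject's signal is derived
#'   deterministically from it.
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(montage = fixture_montage(), n_per_group = 12,
                         sources = list(), noise_exponent = 1, noise_sd = 1,
                         fs = 250, epoch_s = 60, n_epochs = 3,
                         gain_jitter_sd = 0.1, seed = 1) {
  if (n_per_group < 2) abort("`n_per_group` must be >= 2.")
  if (abs(epoch_s * fs - round(epoch_s * fs)) > 1e-9) {
    abort("`epoch_s * fs` must be an integer sample count.")
  }
  for (s in sources) {
    if (!inherits(s, "source_spec")) abort("`sources` must be source_spec objects.")
    if (s$center_freq + s$bandwidth / 2 >= fs / 2) {
      abort("Source band must lie below the Nyquist frequency.")
    }
    missing_ch <- setdiff(s$target_channels, montage$label)
    if (length(missing_ch)) {
      abort(paste0("Source targets not in montage: ",
                   paste(missing_ch, collapse = ", ")))
    }
  }
  structure(list(montage = montage, n_per_group = n_per_group,
                 sources = sources, noise_exponent = noise_exponent,
                 noise_sd = noise_sd, fs = fs, epoch_s = epoch_s,
                 n_epochs = n_epochs, gain_jitter_sd = gain_jitter_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' 1/f^a background noise
#'
#' Synthesises coloured noise by frequency-domain shaping of white
#' Gaussian noise: Fourier amplitudes are scaled by f^(-a/2) (DC set to
#' zero), giving an exact target power-law slope, then the series is
#' rescaled to standard deviation `sd`. Draws from the current RNG
#' state.
#'
#' @param n Number of samples.
#' @param exponent Spectral exponent a (power ~ 1/f^a).
#' @param fs Sampling rate in Hz (sets the frequency grid).
#' @param sd Target standard deviation.
#' @return Numeric vector of length `n`.
#' @export
pink_noise <- function(n, exponent = 1, fs = 250, sd = 1) {
  w <- rnorm(n)
  if (exponent == 0) return(w * sd / stats::sd(w))
  X <- fft(w)
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  shape <- c(0, f[-1]^(-exponent / 2))
  x <- Re(fft(X * shape, inverse = TRUE)) / n
  x * sd / stats::sd(x)
}

#' Narrowband Gaussian noise
#'
#' White Gaussian noise filtered with a zero-phase 4th-order Butterworth
#' band-pass to `[center - bandwidth/2, center + bandwidth/2]`.
#' Stationary with an analytically tractable power spectral density
#' (in-band one-sided PSD approximately `2/fs` per unit input variance).
#' Draws from the current RNG state.
#'
#' @inheritParams pink_noise
#' @param center Centre frequency, Hz.
#' @param bandwidth Full bandwidth, Hz.
#' @return Numeric vector of length `n`.
#' @export
narrowband_noise <- function(n, center, bandwidth, fs = 250) {
  band <- c(center - bandwidth / 2, center + bandwidth / 2) / (fs / 2)
  bf <- signal::butter(4, band, type = "pass")
  as.numeric(signal::filtfilt(bf, rnorm(n)))
}

#' Population coherence of two channels sharing one source
#'
#' Closed-form magnitude-squared coherence at one frequency for the
#' linear one-shared-source model `x = g_x s + n_x`, `y = g_y s + n_y`
#' with independent additive noise:
#' \deqn{C_{xy} = \frac{(g_x g_y S)^2}{(g_x^2 S + N_x)(g_y^2 S + N_y)}}
#' where `S` is the source PSD and `N_x`, `N_y` the noise PSDs at that
#' frequency. This is the generator's analytic oracle: the empirical
#' Welch MSC of generated channel pairs converges to it.
#'
#' @param gain_x,gain_y Mixing amplitudes (>= 0).
#' @param source_psd Source power spectral density at the frequency.
#' @param noise_psd_x,noise_psd_y Noise PSDs at the frequency.
#' @return Coherence value in \[0, 1\].
#' @examples
#' analytic_coherence(1, 1, 1, 1, 1)  # 0.25
#' @export
analytic_coherence <- function(gain_x, gain_y, source_psd,
                               noise_psd_x, noise_psd_y) {
  stopifnot(gain_x >= 0, gain_y >= 0, source_psd >= 0,
            noise_psd_x >= 0, noise_psd_y >= 0)
  den_x <- gain_x^2 * source_psd + noise_psd_x
  den_y <- gain_y^2 * source_psd + noise_psd_y
  if (den_x <= 0 || den_y <= 0) {
    abort("Coherence undefined: zero total power on a channel.")
  }
  (gain_x * gain_y * source_psd)^2 / (den_x * den_y)
}

# deterministic per-subject seed below 2^31, independent across
# (seed, subject_index, group)
derive_seed <- function(seed, subject_index, group) {
  g <- if (identical(group, "case")) 1L else 2L
  as.integer((as.numeric(seed) %% 1000003) * 2011 +
               subject_index * 405 + g * 101) %% 2147483647L
}

#' Generate one synthetic subject
#'
#' Realises one subject's recording under a [synth_config()]: for each
#' source, a fresh narrowband realisation scaled by
#' `gain * group_gain_scale[group] * condition_gain_scale[condition] *
#' jitter` is added to its target channels, on top of independent
#' 1/f background noise per channel. Deterministic given
#' `(config$seed, subject_index, group)`.
#'
#' @param config A [synth_config()].
#' @param subject_index 1-based subject index within the group.
#' @param group `"case"` or `"control"`.
#' @return A [recording()] with `n_epochs` annotated intervals per
#'   condition, alternating EO / EC.
#' @export
generate_subject <- function(config, subject_index, group) {
  stopifnot(inherits(config, "synth_config"))
  if (subject_index < 1 || subject_index > config$n_per_group) {
    abort("`subject_index` out of range for this config.")
  }
  group <- match.arg(group, c("case", "control"))
  fs <- config$fs
  n_int <- config$epoch_s * fs
  conds <- rep(c("EO", "EC"), config$n_epochs)
  n_total <- n_int * length(conds)
  ann <- tibble::tibble(condition = conds,
                        start = (seq_along(conds) - 1L) * n_int,
                        end = seq_along(conds) * n_int)
  cond_of_sample <- rep(conds, each = n_int)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(derive_seed(config$seed, subject_index, group))

  n_ch <- nrow(config$montage)
  data <- matrix(0, nrow = n_ch, ncol = n_total,
                 dimnames = list(config$montage$label, NULL))
  for (src in config$sources) {
    jitter <- exp(rnorm(1, 0, config$gain_jitter_sd))
    s <- narrowband_noise(n_total, src$center_freq, src$bandwidth, fs)
    amp <- src$gain * src$group_gain_scale[[group]] * jitter
    cond_scale <- unname(src$condition_gain_scale[cond_of_sample])
    contrib <- s * amp * cond_scale
    for (ch in src$target_channels) {
      data[ch, ] <- data[ch, ] + contrib
    }
  }
  for (i in seq_len(n_ch)) {
    data[i, ] <- data[i, ] +
      pink_noise(n_total, config$noise_exponent, fs, sd = config$noise_sd)
  }
  recording(data, fs = fs, montage = config$montage, annotations = ann,
            subject_id = sprintf("%s%02d", group, subject_index),
            group = group)
}

#' Generate a two-group synthetic cohort
#'
#' @param config A [synth_config()].
#' @return List of `2 * n_per_group` [recording()]s (all case subjects,
#'   then all control subjects), named by subject id.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  recs <- c(
    lapply(seq_len(config$n_per_group), function(i)
      generate_subject(config, i, "case")),
    lapply(seq_len(config$n_per_group), function(i)
      generate_subject(config, i, "control")))
  names(recs) <- vapply(recs, `[[`, "", "subject_id")
  recs
}
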
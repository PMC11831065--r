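# Shared fixtures and independent oracles, built in code.

# small montages --------------------------------------------------------

tiny_montage <- function(n = 4) {
  montage(LETTERS[seq_len(n)],
          x = seq(-0.5, 0.5, length.out = n), y = rep(0, n),
          region = rep(c("frontal-left", "frontal-right"), length.out = n))
}

half_fixture_montage <- function(k = 16) {
  m <- fixture_montage()[seq_len(k), ]
  montage(m$label, m$x, m$y, m$region)
}

# a minimal epoch_set straight from a matrix
matrix_epochs <- function(..., fs = 250, condition = "EO",
                          mont = NULL, group = NA_character_) {
  eps <- list(...)
  n <- nrow(eps[[1]])
  if (is.null(mont)) mont <- tiny_montage(n)
  epoch_set(eps, fs = fs, montage = mont, condition = condition,
            subject_id = "T01", group = group)
}

# a recording of pure iid Gaussian noise with EO/EC annotations
noise_recording <- function(n_ch = 4, seconds = 8, fs = 250, seed = 1,
                            mont = NULL) {
  set.seed(seed)
  n <- seconds * fs
  if (is.null(mont)) mont <- tiny_montage(n_ch)
  ann <- tibble::tibble(condition = c("EO", "EC"),
                        start = c(0L, as.integer(n / 2)),
                        end = c(as.integer(n / 2), as.integer(n)))
  recording(matrix(rnorm(n_ch * n), n_ch, n), fs = fs, montage = mont,
            annotations = ann, subject_id = "N01", group = "control")
}

# oracles ---------------------------------------------------------------

# exact two-sided Mann-Whitney p by exhaustive enumeration of all
# group assignments (midranks; independent of the package's path)
enum_mw <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  combs <- utils::combn(length(r), nx)
  Us <- colSums(matrix(r[combs], nrow = nx)) - nx * (nx + 1) / 2
  U_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  p <- 2 * min(mean(Us <= U_obs), mean(Us >= U_obs))
  list(U = U_obs, p = min(1, p))
}

# BH step-up by direct evaluation of q_(i) = min_{j>=i} m p_(j) / j
stepup_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# single-segment periodogram argmax (direct DFT, no Welch machinery)
dft_peak_freq <- function(x, fs) {
  n <- length(x)
  P <- Mod(fft(x))^2
  half <- seq_len(n %/% 2 + 1)
  ((half - 1) * fs / n)[which.max(P[half])]
}

# zero-phase magnitude response of the preprocessing band-pass at f Hz
# (direct transfer-function evaluation on the unit circle)
bandpass_gain <- function(f, fs, highpass = 0.5, lowpass = 35) {
  bf <- signal::butter(4, c(highpass, lowpass) / (fs / 2), type = "pass")
  z <- exp(-1i * 2 * pi * f / fs)
  h <- sum(bf$b * z^(seq_along(bf$b) - 1)) / sum(bf$a * z^(seq_along(bf$a) - 1))
  Mod(h)^2  # forward-backward application squares the magnitude
}
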
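# Welch spectra, magnitude-squared coherence, band averaging.

test_that("Welch PSD satisfies Parseval for white noise", {
  set.seed(1)
  fs <- 250
  es <- matrix_epochs(matrix(rnorm(2 * 30 * fs), 2), fs = fs)
  se <- welch_spectra(es)
  df <- se$freqs[2] - se$freqs[1]
  total <- sum(se$Pxx[1, ]) * df
  expect_lt(abs(total - 1), 0.1)  # unit variance, within 10%
})

test_that("a pure sinusoid peaks at its own frequency bin", {
  fs <- 250
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * t)
  se <- welch_spectra(matrix_epochs(rbind(x, x)))
  expect_equal(se$freqs[which.max(se$Pxx[1, ])], 10)
  # oracle: single-segment direct DFT peaks at the same frequency
  expect_equal(dft_peak_freq(x[1:500], fs), 10)
})

test_that("zero signal gives identically zero spectra and NA coherence", {
  es <- matrix_epochs(matrix(0, 2, 5000))
  se <- welch_spectra(es)
  expect_equal(max(se$Pxx), 0)
  expect_equal(max(Mod(se$cross)), 0)
  coh <- msc(se, "A", "B")
  expect_true(all(is.na(coh$coherence)))
})

test_that("self-coherence is 1 wherever power is nonzero", {
  set.seed(2)
  se <- welch_spectra(matrix_epochs(matrix(rnorm(3 * 6000), 3,
                                           dimnames = list(c("A","B","C"), NULL))))
  coh <- msc(se, "B", "B")
  expect_equal(coh$coherence, rep(1, length(coh$coherence)))
})

test_that("coherence respects the Cauchy-Schwarz bound on random pairs", {
  set.seed(3)
  for (i in 1:25) {
    n <- sample(2000:6000, 1)
    x <- rbind(pink_noise(n, 1), arima.sim(list(ar = 0.5), n))
    se <- welch_spectra(matrix_epochs(x))
    expect_true(all(Mod(se$cross[1, 2, ])^2 <=
                      se$Pxx[1, ] * se$Pxx[2, ] * (1 + 1e-12)))
    coh <- msc(se, "A", "B")$coherence
    expect_true(all(coh >= 0 & coh <= 1, na.rm = TRUE))
  }
})

test_that("pair order does not change coherence, bit-exactly", {
  set.seed(4)
  se <- welch_spectra(matrix_epochs(matrix(rnorm(2 * 4000), 2)))
  expect_identical(msc(se, "A", "B")$coherence, msc(se, "B", "A")$coherence)
})

test_that("coherence is invariant under channel rescaling", {
  set.seed(5)
  x <- matrix(rnorm(2 * 8000), 2)
  x[2, ] <- x[1, ] + rnorm(8000)        # genuinely coherent pair
  se1 <- welch_spectra(matrix_epochs(x))
  x2 <- x; x2[1, ] <- 37.5 * x2[1, ]; x2[2, ] <- -0.01 * x2[2, ]
  se2 <- welch_spectra(matrix_epochs(x2))
  expect_lt(max(abs(msc(se1, "A", "B")$coherence -
                    msc(se2, "A", "B")$coherence)), 1e-10)
})

test_that("a delayed copy keeps coherence ~1 across passband bins", {
  set.seed(6)
  fs <- 250
  bp <- signal::butter(4, c(2, 40) / (fs / 2), "pass")
  x <- as.numeric(signal::filtfilt(bp, rnorm(20 * fs)))
  lag <- 5  # 20 ms << 2 s segment
  y <- c(rep(0, lag), x[1:(length(x) - lag)])
  se <- welch_spectra(matrix_epochs(rbind(x, y)))
  coh <- msc(se, "A", "B")
  pass <- coh$freq >= 5 & coh$freq <= 30
  expect_gt(min(coh$coherence[pass]), 0.95)
})

test_that("independent white noise has mean coherence ~ 1/K", {
  set.seed(7)
  fs <- 250
  # 8 non-overlapping 2-s segments
  es <- matrix_epochs(matrix(rnorm(2 * 8 * 2 * fs), 2), fs = fs)
  se <- welch_spectra(es, welch_config(overlap_fraction = 0))
  expect_equal(se$K, 8)
  mean_coh <- mean(msc(se, "A", "B")$coherence)
  expect_lt(abs(mean_coh - 1 / 8), 0.03)
})

test_that("single-segment coherence is rejected as degenerate", {
  es <- matrix_epochs(matrix(rnorm(2 * 500), 2))
  se <- welch_spectra(es, welch_config(overlap_fraction = 0))
  expect_equal(se$K, 1)
  expect_error(msc(se, "A", "B"), "K must be >= 2")
})

test_that("segments never straddle epoch boundaries", {
  set.seed(8)
  fs <- 250
  # epochs of 2.8 s: two 2-s half-overlapped segments fit, then per-epoch rest unused
  e1 <- matrix(rnorm(2 * 700), 2); e2 <- matrix(rnorm(2 * 700), 2)
  se <- welch_spectra(matrix_epochs(e1, e2))
  expect_equal(se$K, 2 * (1 + (700 - 500) %/% 250))
  # a too-short epoch is skipped with a warning
  expect_warning(
    se2 <- welch_spectra(matrix_epochs(e1, matrix(rnorm(2 * 100), 2))),
    "Skipping epoch")
  expect_equal(se2$K, 1)  # only the long epoch contributes
})

test_that("band averaging follows the half-open bin convention", {
  freqs <- seq(0, 125, by = 0.5)
  coh <- rep(0.6, length(freqs))
  for (b in seq_len(nrow(eeg_bands()))) {
    expect_equal(band_average(coh, freqs, eeg_bands()$low[b],
                              eeg_bands()$high[b]), 0.6)
  }
  # alpha3 at 0.5 Hz resolution averages bins {11, 11.5, 12, 12.5} only
  coh2 <- numeric(length(freqs))
  coh2[freqs == 13] <- 1  # boundary bin belongs to beta, not alpha3
  expect_equal(band_average(coh2, freqs, 11, 13), 0)
  coh2[freqs == 11] <- 1
  expect_equal(band_average(coh2, freqs, 11, 13), 0.25)
  expect_error(band_average(coh, freqs, 11.1, 11.2), "No frequency bin")
})

test_that("coherence profiles are complete, bounded and band-resolved", {
  cfg <- synth_config(
    montage = tiny_montage(), n_per_group = 2,
    sources = list(source_spec(12, 2, c("A", "B"), gain = 2.5)),
    epoch_s = 30, n_epochs = 1, seed = 9)
  rec <- generate_subject(cfg, 1, "control")
  sets <- segment_conditions(rec, preprocess_config(discard_lead_s = 0,
                                                    epoch_s = 30))
  prof <- coherence_profile(sets$EO)
  expect_equal(nrow(prof), 6 * 11)  # C(4,2) pairs x 11 bands
  expect_true(all(prof$coherence >= 0 & prof$coherence <= 1))
  ab <- prof[prof$chan_i == "A" & prof$chan_j == "B", ]
  expect_gt(ab$coherence[ab$band == "alpha3"],
            ab$coherence[ab$band == "delta"])
  m <- profile_matrix(prof[prof$band == "alpha3", ],
                      labels = c("A", "B", "C", "D"))
  expect_true(isSymmetric(m))
  expect_equal(diag(m), rep(1, 4), ignore_attr = TRUE)
})
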
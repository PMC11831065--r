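# Deterministic preprocessing chain: filtering, bad channels,
# re-referencing, segmentation.

sine_recording <- function(freq, seconds = 30, fs = 250) {
  t <- seq(0, seconds - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * freq * t)
  recording(rbind(x, x, x, x), fs = fs, montage = tiny_montage(4),
            annotations = tibble::tibble(condition = "EO", start = 0L,
                                         end = length(t)))
}

test_that("band-pass attenuation matches the frequency-response oracle", {
  fs <- 250
  r50 <- bandpass_filter(sine_recording(50), preprocess_config())
  ratio50 <- sd(r50$data[1, ]) / sd(sine_recording(50)$data[1, ])
  expect_lt(ratio50, 0.05)
  expect_lt(abs(ratio50 - bandpass_gain(50, fs)), 0.01)

  r10 <- bandpass_filter(sine_recording(10), preprocess_config())
  ratio10 <- sd(r10$data[1, ]) / sd(sine_recording(10)$data[1, ])
  expect_gt(ratio10, 0.95)
  expect_lt(ratio10, 1.05)
  expect_lt(abs(ratio10 - bandpass_gain(10, fs)), 0.02)
})

test_that("filtering zero signal yields zero and preserves shape", {
  rec <- noise_recording(seconds = 4)
  rec$data[] <- 0
  out <- bandpass_filter(rec)
  expect_equal(dim(out$data), dim(rec$data))
  expect_equal(max(abs(out$data)), 0)
  expect_identical(out$annotations, rec$annotations)
})

test_that("filtering and average re-referencing commute", {
  rec <- noise_recording(seconds = 6, seed = 8)
  a <- rereference_average(bandpass_filter(rec))
  b <- bandpass_filter(rereference_average(rec))
  expect_lt(max(abs(a$data - b$data)), 1e-6)
})

test_that("a too-short recording cannot be filtered", {
  rec <- noise_recording(seconds = 4)
  rec$data <- rec$data[, 1:20]
  expect_error(bandpass_filter(rec), "too short")
})

test_that("kurtosis rejection flags only genuinely spiky channels", {
  fs <- 250
  mont <- fixture_montage()
  set.seed(42)
  data <- matrix(rnorm(32 * 20 * fs), 32)
  rec <- recording(data, fs, mont)
  expect_identical(detect_bad_channels(rec), character())

  # inject sparse large spikes (20 x SD, 0.5% of samples) into one channel
  spiky <- rec
  idx <- sample(ncol(data), round(0.005 * ncol(data)))
  spiky$data["T7", idx] <- spiky$data["T7", idx] + 20
  expect_message(bad <- detect_bad_channels(spiky), "T7")
  expect_identical(bad, "T7")

  # oracle: the spiky channel's excess kurtosis must be the extreme one
  k <- apply(spiky$data, 1, function(x) {
    x <- x - mean(x); mean(x^4) / mean(x^2)^2 - 3
  })
  expect_identical(names(which.max(k)), "T7")
})

test_that("identical channels give zero kurtosis spread and no rejection", {
  x <- rnorm(1000)
  rec <- recording(rbind(x, x, x, x), 250, tiny_montage(4))
  expect_identical(detect_bad_channels(rec), character())
})

test_that("kurtosis rejection is permutation-equivariant", {
  set.seed(7)
  mont <- fixture_montage()
  data <- matrix(rnorm(32 * 3000), 32)
  data[5, sample(3000, 15)] <- 25
  rec <- recording(data, 250, mont)
  perm <- sample(32)
  mont_p <- montage(mont$label[perm], mont$x[perm], mont$y[perm],
                    mont$region[perm])
  rec_p <- recording(data[perm, ], 250, mont_p)
  suppressMessages({
    expect_setequal(detect_bad_channels(rec), detect_bad_channels(rec_p))
  })
})

test_that("average re-referencing zeroes the channel mean and is idempotent", {
  rec <- noise_recording(seconds = 2, seed = 3)
  out <- rereference_average(rec)
  expect_lt(max(abs(colSums(out$data))), 1e-10)
  out2 <- rereference_average(out)
  expect_equal(out2$data, out$data)
  # zero-mean input is untouched
  x <- rnorm(500)
  two <- recording(rbind(x, -x), 250, tiny_montage(2))
  expect_equal(rereference_average(two)$data, two$data,
               ignore_attr = TRUE)
})

test_that("condition segmentation reproduces the 3 x 56 s epoch design", {
  fs <- 250
  n_min <- 60 * fs
  ann <- tibble::tibble(condition = rep(c("EO", "EC"), 3),
                        start = (0:5) * n_min, end = (1:6) * n_min)
  rec <- recording(matrix(rnorm(2 * 6 * n_min), 2), fs, tiny_montage(2),
                   annotations = ann)
  sets <- segment_conditions(rec, preprocess_config())  # discard 4 s, cap 56 s
  expect_named(sets, c("EO", "EC"))
  for (cond in c("EO", "EC")) {
    expect_length(sets[[cond]]$epochs, 3)
    expect_true(all(vapply(sets[[cond]]$epochs, ncol, 0L) == 56 * fs))
  }
  # no discard: epochs equal the full annotated intervals
  sets0 <- segment_conditions(rec, preprocess_config(discard_lead_s = 0,
                                                     epoch_s = 60))
  expect_true(all(vapply(sets0$EO$epochs, ncol, 0L) == n_min))
  # sample conservation under the discard + truncation rule
  kept <- sum(vapply(c(sets$EO$epochs, sets$EC$epochs), ncol, 0L))
  expect_equal(kept, sum(pmin(ann$end - ann$start - 4 * fs, 56 * fs)))
})

test_that("short remainders are kept with a message; short intervals error", {
  fs <- 250
  rec <- recording(matrix(rnorm(2 * 10 * fs), 2), fs, tiny_montage(2),
                   annotations = tibble::tibble(condition = "EO", start = 0L,
                                                end = 10L * fs))
  expect_message(sets <- segment_conditions(rec, preprocess_config()),
                 "short epoch")
  expect_equal(ncol(sets$EO$epochs[[1]]), 6 * fs)

  rec$annotations$end <- 3L * fs  # 3 s < 4 s discard
  expect_error(segment_conditions(rec, preprocess_config()),
               "shorter than the leading discard")
  rec$annotations <- rec$annotations[0, ]
  expect_error(segment_conditions(rec, preprocess_config()),
               "no condition annotations")
})

test_that("the full chain drops bad channels before epoching", {
  fs <- 250
  mont <- fixture_montage()
  set.seed(11)
  n <- 16 * fs
  data <- matrix(rnorm(32 * n), 32)
  data[3, sample(n, 20)] <- 30
  ann <- tibble::tibble(condition = c("EO", "EC"),
                        start = c(0L, n %/% 2L), end = c(n %/% 2L, n))
  rec <- recording(data, fs, mont, annotations = ann, subject_id = "P01",
                   group = "case")
  suppressMessages(
    sets <- preprocess_recording(rec, preprocess_config(discard_lead_s = 1,
                                                        epoch_s = 7)))
  bad <- attr(sets, "rejected_channels")
  expect_identical(bad, mont$label[3])
  expect_equal(nrow(sets$EO$montage), 31)
  expect_identical(sets$EO$rejected_channels, bad)
  expect_false(mont$label[3] %in% sets$EO$montage$label)
  # re-referencing happened after the drop: channel mean is zero
  expect_lt(max(abs(colSums(sets$EC$epochs[[1]]))), 1e-8)
})
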
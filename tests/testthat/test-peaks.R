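fake_dec <- function(w, alignment = 0, fs = 100) {
  structure(list(coefficients = w, alignment = alignment,
                 sampling_rate_hz = fs),
            class = "wavelet_decomposition")
}
thr_pair <- function(thp, thn) {
  structure(list(thp = thp, thn = thn, c_thr = NA), class = "threshold_pair")
}

test_that("wavelet coefficients vanish on constants and stay flat on ramps", {
  fs <- 100
  w0 <- wavelet_scale3(ppg_record(rep(2, 500), fs))
  expect_true(all(abs(w0$coefficients) < 1e-12))
  ramp <- wavelet_scale3(ppg_record(seq(0, 1, length.out = 500), fs))
  inner <- ramp$coefficients[50:450]
  expect_lt(diff(range(inner)), 1e-6 + 0.1 * max(abs(inner)))
})

test_that("a single pulse yields one max-min pair straddling its peak", {
  fs <- 100
  t <- seq(0, 6, by = 1 / fs)
  x <- exp(-((t - 3)^2) / (2 * 0.05^2))
  dec <- wavelet_scale3(ppg_record(x, fs))
  thr <- wavelet_thresholds(dec)
  pairs <- find_maxima_pairs(dec, thr)
  expect_identical(nrow(pairs), 1L)
  peak <- locate_peaks(pairs, dec)
  expect_lte(abs(peak - (3 * fs + 1)), 1)
})

test_that("pairing keeps monotone above-threshold pairs and drops orphans", {
  # one clean pair
  w <- c(0, 0, 3, 1, -1, -3, 0, 0)
  p <- find_maxima_pairs(fake_dec(w), thr_pair(2, -2))
  expect_identical(nrow(p), 1L)
  expect_identical(as.integer(p[1, ]), c(3L, 6L))
  # all sub-threshold
  expect_identical(nrow(find_maxima_pairs(fake_dec(w), thr_pair(5, -5))), 0L)
  # isolated positive extremum is an orphan
  w2 <- c(0, 1, 4, 1, 0.5, 0.8, 0.2, 0)
  expect_identical(nrow(find_maxima_pairs(fake_dec(w2), thr_pair(2, -2))), 0L)
  # non-monotone path between the extrema is rejected
  # (sub-threshold bump of +1 on the way down, above the 10% tolerance)
  w3 <- c(0, 4, 1, 2, 0.5, -4, 0)
  expect_identical(nrow(find_maxima_pairs(fake_dec(w3), thr_pair(2, -2),
                                          mono_tol = 0.1)), 0L)
})

test_that("zero-crossings are interpolated between the pair members", {
  w <- c(0, 3, 1, -1, -3, 0)
  dec <- fake_dec(w)
  p <- matrix(c(2L, 5L), ncol = 2)
  expect_identical(locate_peaks(p, dec), 4L) # crossing at 3.5 -> sample 4
  # symmetric pair: crossing at the midpoint
  w2 <- c(0, 4, 2, 0.5, -0.5, -2, -4, 0)
  p2 <- matrix(c(2L, 7L), ncol = 2)
  expect_identical(locate_peaks(p2, fake_dec(w2)), 4L) # 4.5 rounds to 4
  # no sign change: skipped with a warning
  w3 <- c(0, 3, 2, 1, 0.5, 0.2, 0)
  expect_warning(out <- locate_peaks(matrix(c(2L, 6L), ncol = 2),
                                     fake_dec(w3)),
                 "zero-crossing")
  expect_length(out, 0)
})

test_that("the 200 ms refractory rule suppresses early candidates", {
  fs <- 1000
  expect_identical(apply_refractory(c(1L, 151L, 901L), fs), c(1L, 901L))
  spaced <- c(1L, 301L, 601L)
  expect_identical(apply_refractory(spaced, fs), spaced)
  expect_identical(apply_refractory(integer(0), fs), integer(0))
})

test_that("clean 60 bpm recording gives 60 +- 1 peaks, all >= 200 ms apart", {
  sim <- generate_ppg(synth_config(duration_s = 60, hr_variability_sd_ms = 20,
                                   seed = 13))
  tr <- detect_peaks(sim$record)
  expect_lte(abs(length(tr$peak_indices) - 60), 1)
  expect_true(all(diff(tr$peak_indices) >= 0.2 * 100))
  # constant input: empty train
  empty <- detect_peaks(ppg_record(rep(1, 7000), 100))
  expect_length(empty$peak_indices, 0)
})

test_that("a deleted beat in a regular rhythm is recovered at 4/5 thresholds", {
  sim <- generate_ppg(synth_config(duration_s = 62, hr_variability_sd_ms = 0,
                                   seed = 5))
  rec <- sim$record
  dec <- wavelet_scale3(rec)
  thr <- wavelet_thresholds(dec)
  full <- apply_refractory(locate_peaks(find_maxima_pairs(dec, thr), dec), 100)
  victim <- full[30]
  train <- make_peak_train(full[-30], amps = rec$samples[full[-30]])
  fixed <- recover_missed(train, dec, thr, rec)
  expect_lte(min(abs(fixed$peak_indices - victim)), 5) # within 50 ms
  expect_true(all(diff(fixed$peak_indices) >= 20))
  # no long gaps: unchanged
  same <- recover_missed(make_peak_train(full, amps = rec$samples[full]),
                         dec, thr, rec)
  expect_identical(same$peak_indices, full)
})

test_that("lowering the thresholds never loses maxima pairs", {
  sim <- generate_ppg(synth_config(duration_s = 62, hr_variability_sd_ms = 30,
                                   noise_emg_amp = 0.05, seed = 17))
  dec <- wavelet_scale3(sim$record)
  counts <- vapply(c(2.5, 1.8, 1.2, 0.8), function(c_thr) {
    nrow(find_maxima_pairs(dec, wavelet_thresholds(dec, c_thr)))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("peak detection commutes with a time shift of the input", {
  sim <- generate_ppg(synth_config(duration_s = 62, hr_variability_sd_ms = 10,
                                   seed = 19))
  x <- sim$record$samples
  k <- 137
  a <- detect_peaks(ppg_record(x, 100))$peak_indices
  b <- detect_peaks(ppg_record(x[-(1:k)], 100))$peak_indices
  inner_a <- a[a > 500 & a < length(x) - 500]
  inner_b <- b[b > 500 - k & b < length(x) - 500 - k] + k
  expect_equal(inner_a, inner_b)
})
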
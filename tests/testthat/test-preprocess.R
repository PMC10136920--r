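test_that("running medians agree exactly with the naive sorting oracle", {
  set.seed(11)
  for (rep in 1:6) {
    n <- sample(50:500, 1)
    x <- rnorm(n)
    k <- sample(c(3, 9, 25, 51), 1)
    expect_identical(apneascreen:::running_median(x, k),
                     naive_running_median(x, k))
  }
})

test_that("baseline removal zeroes constants and strips slow ramps", {
  rec <- ppg_record(rep(3.7, 500), 100)
  expect_equal(remove_baseline(rec)$samples, rep(0, 500))

  # slow ramp + fast pulse train: output decorrelated from the ramp
  t <- seq(0, 20, by = 0.01)[-1]
  ramp <- 0.5 * t
  pulses <- exp(-((t %% 1 - 0.5)^2) / (2 * 0.05^2))
  out <- remove_baseline(ppg_record(ramp + pulses, 100))$samples
  expect_lt(abs(cor(out, ramp)), 0.1)

  # 1 Hz sine: equals input minus the sort-based oracle baseline, exactly
  x <- sin(2 * pi * seq(0, 5, by = 0.01))
  got <- remove_baseline(ppg_record(x, 100))$samples
  expect_identical(got, x - naive_running_median(x, 250))

  expect_error(remove_baseline(ppg_record(rnorm(100), 100)), "too short")
})

test_that("median denoise removes impulses, keeps monotone order, matches oracle", {
  fs <- 10
  x <- rep(1, 100); x[50] <- 40
  out <- median_denoise(ppg_record(x, fs), window_s = 0.5)$samples
  expect_equal(out, rep(1, 100))

  set.seed(4)
  y <- rnorm(200)
  expect_identical(median_denoise(ppg_record(y, fs), window_s = 2)$samples,
                   naive_running_median(y, 20))

  mono <- sort(rnorm(150))
  got <- median_denoise(ppg_record(mono, fs), window_s = 1.5)$samples
  expect_true(!is.unsorted(got))

  expect_error(median_denoise(ppg_record(rnorm(10), fs), window_s = 2),
               "too short")
})

test_that("lowpass designs meet the printed attenuation and ripple", {
  d10 <- design_lowpass(100)
  expect_lte(d10$stopband_max_db, -60 + 1e-6)
  expect_lte(d10$passband_ripple_measured_db, 1 + 1e-6)
  d5 <- design_lowpass(100, order = 5, stopband_atten_db = 40)
  expect_lte(d5$stopband_max_db, -40 + 1e-6)
  # identical spec => identical coefficients
  expect_identical(design_lowpass(100)$b, d10$b)
  expect_identical(design_lowpass(100)$a, d10$a)
  expect_error(design_lowpass(100, cutoff_hz = 60), "Nyquist|cutoff")
  # a low order still meets spec, paying with a wide transition band
  d2 <- design_lowpass(100, order = 2, cutoff_hz = 4.8, stopband_atten_db = 60)
  expect_gt(d2$stopband_edge_hz, d10$stopband_edge_hz)
})

test_that("filtering drops M/2 samples, keeps DC, kills a 20 Hz tone", {
  d <- design_lowpass(100)
  n <- 2000
  dc <- apply_lowpass(ppg_record(rep(1, n), 100), d)
  expect_length(dc$samples, n - 5)
  tail_dc <- tail(dc$samples, 500)
  expect_true(all(abs(20 * log10(abs(tail_dc))) < 1))

  tone <- sin(2 * pi * 20 * (0:(n - 1)) / 100)
  ft <- apply_lowpass(ppg_record(tone, 100), d)
  expect_lt(max(abs(tail(ft$samples, 500))), 10^(-60 / 20))

  expect_error(apply_lowpass(ppg_record(rep(1, 100), 50), d), "sampling rate")
})

test_that("SNR follows 10 log10(Ps/Pn)", {
  expect_equal(compute_snr(1, 1), 0)
  expect_equal(compute_snr(100, 1), 20)
  expect_equal(compute_snr(10^6.149, 1), 61.49)
  expect_error(compute_snr(0, 1), "positive")
})

test_that("60-s windowing slides by 1 s and carries majority-minute labels", {
  fs <- 50
  expect_length(segment_windows(ppg_record(rnorm(120 * fs), fs)), 61)
  expect_length(segment_windows(ppg_record(rnorm(60 * fs), fs)), 1)
  expect_error(segment_windows(ppg_record(rnorm(59 * fs), fs)), "shorter")

  labels <- c(0L, 1L, 0L)
  w <- segment_windows(ppg_record(rnorm(180 * fs), fs), labels = labels)
  lab <- vapply(w, function(x) x$label, integer(1))
  # window starting at s takes minute floor(s/60) while s %% 60 <= 30
  expect_identical(lab[1], 0L)    # start 0
  expect_identical(lab[31], 0L)   # start 30: tie goes to the earlier minute
  expect_identical(lab[32], 1L)   # start 31: majority in minute 2
  expect_identical(lab[61], 1L)   # start 60
})

test_that("windows of the filtered record are exact slices of it", {
  set.seed(9)
  rec <- ppg_record(rnorm(70 * 100), 100)
  d <- design_lowpass(100)
  filt <- apply_lowpass(rec, d)
  w <- segment_windows(filt, step_s = 2)
  for (k in c(1, 3, length(w))) {
    s0 <- round(w[[k]]$start_s * 100) + 1
    expect_identical(w[[k]]$samples, filt$samples[s0:(s0 + 6000 - 1)])
  }
})
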
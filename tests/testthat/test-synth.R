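test_that("noise-free fixed-rate config yields an exact beat grid", {
  sim <- generate_ppg(synth_config(duration_s = 30, base_heart_rate_bpm = 60,
                                   hr_variability_sd_ms = 0, seed = 1))
  expect_true(all(abs(diff(sim$truth$peak_indices) - 100) <= 1))
})

test_that("generation is seed-deterministic and seed-sensitive", {
  cfg <- synth_config(duration_s = 30, hr_variability_sd_ms = 40, seed = 5,
                      noise_emg_amp = 0.05)
  a <- generate_ppg(cfg)
  b <- generate_ppg(cfg)
  expect_identical(a$record$samples, b$record$samples)
  expect_identical(a$truth$peak_indices, b$truth$peak_indices)
  cfg2 <- cfg; cfg2$seed <- 6L
  c <- generate_ppg(cfg2)
  expect_false(identical(a$truth$peak_indices, c$truth$peak_indices))
})

test_that("apnea episodes paint exactly the overlapped minute labels", {
  cfg <- synth_config(duration_s = 300, apnea_episodes = list(c(120, 240)))
  sim <- generate_ppg(cfg)
  expect_identical(sim$truth$window_labels, c(0L, 0L, 1L, 1L, 0L))
  # a sub-10 s brush with a minute does not label it
  cfg2 <- synth_config(duration_s = 180, apnea_episodes = list(c(55, 95)))
  sim2 <- generate_ppg(cfg2)
  expect_identical(sim2$truth$window_labels, c(0L, 1L, 0L))
})

test_that("peak count tracks duration x HR within 2% at small jitter", {
  for (hr in c(55, 72)) {
    cfg <- synth_config(duration_s = 120, base_heart_rate_bpm = hr,
                        hr_variability_sd_ms = 10, seed = hr)
    sim <- generate_ppg(cfg)
    expect_lt(abs(length(sim$truth$peak_indices) - 120 * hr / 60),
              0.02 * 120 * hr / 60 + 1)
  }
})

test_that("apneic minutes show clearly larger PP-interval dispersion", {
  cfg <- synth_config(duration_s = 240, hr_variability_sd_ms = 30,
                      apnea_episodes = list(c(60, 120), c(180, 240)), seed = 2)
  sim <- generate_ppg(cfg)
  pk_s <- (sim$truth$peak_indices - 1) / 100
  sd_in_minute <- function(m) {
    p <- pk_s[pk_s >= 60 * (m - 1) & pk_s < 60 * m]
    sd(diff(p))
  }
  apneic <- which(sim$truth$window_labels == 1)
  normal <- which(sim$truth$window_labels == 0)
  ratio <- mean(sapply(apneic, sd_in_minute)) / mean(sapply(normal, sd_in_minute))
  expect_gt(ratio, 2)
})

test_that("config validation rejects bad geometry", {
  expect_error(synth_config(sampling_rate_hz = 0), "positive")
  expect_error(synth_config(duration_s = -3), "positive")
  expect_error(synth_config(duration_s = 60,
                            apnea_episodes = list(c(10, 70))), "within")
  expect_error(synth_config(duration_s = 100,
                            apnea_episodes = list(c(30, 50), c(40, 60))),
               "non-overlapping")
})

test_that("SpO2 stays >= 96 at baseline and dips below 90 in episodes", {
  cfg <- synth_config(duration_s = 200, seed = 3)
  sim <- generate_ppg(cfg)
  tr <- generate_spo2(cfg, sim$truth)
  expect_true(all(tr$spo2_series >= 96))

  cfg2 <- synth_config(duration_s = 200, apnea_episodes = list(c(60, 110)),
                       seed = 3)
  sim2 <- generate_ppg(cfg2)
  tr2 <- generate_spo2(cfg2, sim2$truth)
  expect_lt(min(tr2$spo2_series[61:110]), 90)
})

test_that("artifact intervals produce flagged sub-90 drops", {
  cfg <- synth_config(duration_s = 120,
                      spo2_artifact_intervals = list(c(30, 60)), seed = 4)
  sim <- generate_ppg(cfg)
  tr <- generate_spo2(cfg, sim$truth)
  drop <- tr$spo2_series < 90
  expect_true(any(drop))
  expect_true(all(tr$artifact_flags[drop]))
  expect_true(all(which(drop) %in% 31:60))
})

test_that("dual-wavelength channels round-trip the target SpO2 within 1%", {
  cfg <- synth_config(duration_s = 120, apnea_episodes = list(c(30, 75)),
                      seed = 6)
  sim <- generate_ppg(cfg)
  tr <- generate_spo2(cfg, sim$truth)
  dw <- generate_dual_wavelength(cfg, tr)
  est <- compute_spo2(dw$red, dw$ir)
  expect_lt(max(abs(est$values - tr$spo2_series), na.rm = TRUE), 1)
  expect_lt(min(est$values, na.rm = TRUE), 90) # the episode dip survives
  # constant target
  tr$spo2_series[] <- 98
  est2 <- compute_spo2(generate_dual_wavelength(cfg, tr)$red,
                       generate_dual_wavelength(cfg, tr)$ir)
  expect_true(all(abs(est2$values - 98) < 1, na.rm = TRUE))
  # dual-wavelength generation requires a completed SpO2 series
  sim$truth$spo2_series[] <- NA_real_
  expect_error(generate_dual_wavelength(cfg, sim$truth), "generate_spo2")
})

test_that("recordings survive a CSV round trip", {
  cfg <- synth_config(duration_s = 10, seed = 8)
  sim <- generate_ppg(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ppg_csv(sim$record, path)
  back <- read_ppg_csv(path)
  expect_equal(back$ppg$samples, sim$record$samples, tolerance = 1e-12)
  expect_equal(back$ppg$sampling_rate_hz, 100, tolerance = 1e-6)
})
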
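test_that("AHI is events per hour with the standard severity bands", {
  expect_equal(compute_ahi(10, 2), 5)
  expect_equal(compute_ahi(0, 7), 0)
  expect_equal(compute_ahi(56, 8), 7)
  expect_error(compute_ahi(3, 0), "positive")
  expect_identical(severity_class(2), "none")
  expect_identical(severity_class(7), "mild")
  expect_identical(severity_class(20), "moderate")
  expect_identical(severity_class(45), "severe")
})

test_that("positive windows merge into events only when contiguous", {
  merged <- apneascreen:::.merge_positive_windows(c(0, 60, 300), 60)
  expect_identical(nrow(merged), 2L)
  expect_equal(merged$start_s, c(0, 300))
  expect_equal(merged$end_s, c(120, 360))
  none <- apneascreen:::.merge_positive_windows(numeric(0), 60)
  expect_identical(nrow(none), 0L)
})

test_that("a healthy recording screens clean; apneic minutes are found", {
  fm <- cached_corpus(30, 30, seed = 7)
  model <- train_model(fm, model_kind = "rf", seed = 7)

  cfg <- synth_config(duration_s = 360, noise_emg_amp = 0.05,
                      baseline_drift_amp = 0.2, noise_powerline_amp = 0.02,
                      seed = 31)
  sim <- generate_ppg(cfg)
  truth <- generate_spo2(cfg, sim$truth)
  rep0 <- diagnose(sim$record, model,
                   spo2 = oximetry_series(truth$spo2_series,
                                          truth$artifact_flags))
  expect_identical(rep0$event_count, 0L)
  expect_equal(rep0$ahi, 0)
  expect_identical(rep0$severity, "none")

  cfg1 <- synth_config(duration_s = 360, apnea_episodes = list(c(120, 170)),
                       noise_emg_amp = 0.05, baseline_drift_amp = 0.2,
                       noise_powerline_amp = 0.02, seed = 32)
  sim1 <- generate_ppg(cfg1)
  truth1 <- generate_spo2(cfg1, sim1$truth)
  rep1 <- diagnose(sim1$record, model,
                   spo2 = oximetry_series(truth1$spo2_series,
                                          truth1$artifact_flags))
  expect_identical(rep1$event_count, 1L)
  expect_identical(rep1$per_window$final_decision[3], 1L)
})

test_that("artifact-flagged desaturations are gated out with warnings", {
  fm <- cached_corpus(30, 30, seed = 7)
  model <- train_model(fm, model_kind = "rf", seed = 7)
  # apneic-looking PPG, but the only SpO2 drop is a probe artifact
  cfg <- synth_config(duration_s = 300, apnea_episodes = list(c(60, 110)),
                      spo2_artifact_intervals = list(c(60, 110)), seed = 33)
  sim <- generate_ppg(cfg)
  spo2_vals <- rep(97, 300)
  spo2_vals[61:110] <- 70
  rep <- diagnose(sim$record, model,
                  spo2 = oximetry_series(spo2_vals, sim$truth$artifact_flags))
  expect_identical(rep$event_count, 0L)
  expect_gt(length(rep$warnings), 0)
  expect_true(any(grepl("artifact", rep$warnings)))
  # the gate invariant: no confirmed window without pathological evidence
  pw <- rep$per_window
  expect_true(all(pw$final_decision[pw$spo2_evidence %in%
                                      c("artifact", "no_desat", "none")] == 0))
})

test_that("reports survive a JSON round trip", {
  fm <- cached_corpus(30, 30, seed = 7)
  model <- train_model(fm, model_kind = "rf", seed = 7)
  cfg <- synth_config(duration_s = 120, seed = 34)
  sim <- generate_ppg(cfg)
  rep <- diagnose(sim$record, model) # no SpO2: low-confidence path
  expect_true(any(grepl("low confidence", rep$warnings)))
  back <- report_from_json(report_to_json(rep))
  expect_equal(back$ahi, rep$ahi)
  expect_identical(back$severity, rep$severity)
  expect_equal(back$per_window, rep$per_window)
  expect_identical(back$event_count, rep$event_count)
  path <- withr::local_tempfile(fileext = ".json")
  report_to_json(rep, path)
  expect_equal(report_from_json(path)$ahi, rep$ahi)
})

test_that("screening rejects unusable inputs", {
  fm <- cached_corpus(30, 30, seed = 7)
  model <- train_model(fm, model_kind = "rf", seed = 7)
  expect_error(diagnose(ppg_record(rnorm(100), 100), model), "shorter")
})
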
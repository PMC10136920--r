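#' Feature-extract one analysis window
#'
#' Convenience wrapper used by the corpus builder and the screening pipeline:
#' computes the multiscale-entropy vector and, via peak detection, the PRV
#' feature set of a (preprocessed) signal window.
#'
#' @param samples Numeric window samples (preprocessed PPG).
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param window_duration_s Nominal window duration used for PR (defaults to
#'   the actual sample span).
#' @param scale_max,m,r,method Passed to [mse_vector()].
#' @return List with `mse` ([mse_vector()]) and `prv` ([compute_prv()]).
#' @export
window_features <- function(samples, sampling_rate_hz,
                            window_duration_s = NULL,
                            scale_max = 15, m = 2, r = 0.2,
                            method = "improved") {
  if (is.null(window_duration_s)) {
    window_duration_s <- length(samples) / sampling_rate_hz
  }
  rec <- ppg_record(samples, sampling_rate_hz)
  ent <- mse_vector(samples, m = m, r = r, scale_max = scale_max,
                    method = method)
  train <- detect_peaks(rec)
  prv <- compute_prv(train, window_duration_s)
  list(mse = ent, prv = prv)
}

#' Build a labelled synthetic training corpus
#'
#' Simulates independent 60-second windows — each a fresh synthetic recording
#' with realistic noise (modest EMG, baseline drift, power-line pickup) and a
#' heart rate drawn uniformly from `hr_range_bpm` — preprocesses them, and
#' extracts the combined entropy + PRV feature matrix with ground-truth
#' labels. Apneic windows are generated with the apnea modulation of
#' [generate_ppg()] active for the whole window.
#'
#' @param n_normal,n_apnea Number of normal / apneic windows.
#' @param seed Base RNG seed; window `i` uses `seed + i` internally, so the
#'   corpus is fully reproducible.
#' @param sampling_rate_hz Sampling rate (default 100 Hz).
#' @param hr_range_bpm Range the per-window heart rate is drawn from.
#' @param hr_variability_sd_ms Baseline beat-interval jitter SD.
#' @param noise_emg_amp,baseline_drift_amp,noise_powerline_amp Noise levels
#'   handed to [synth_config()].
#' @param scale_max Entropy scales per window.
#' @return A `feature_matrix` (see [assemble_features()]) with labels.
#' @export
generate_corpus <- function(n_normal = 45, n_apnea = 45, seed = 1L,
                            sampling_rate_hz = 100,
                            hr_range_bpm = c(55, 80),
                            hr_variability_sd_ms = 30,
                            noise_emg_amp = 0.05,
                            baseline_drift_amp = 0.2,
                            noise_powerline_amp = 0.02,
                            scale_max = 15) {
  n_total <- n_normal + n_apnea
  labels <- c(rep(0L, n_normal), rep(1L, n_apnea))
  hrs <- with_seed(seed, runif(n_total, hr_range_bpm[1], hr_range_bpm[2]))
  dur <- 62
  ents <- vector("list", n_total)
  prvs <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    cfg <- synth_config(
      sampling_rate_hz = sampling_rate_hz, duration_s = dur,
      base_heart_rate_bpm = hrs[i],
      hr_variability_sd_ms = hr_variability_sd_ms,
      apnea_episodes = if (labels[i] == 1L) list(c(0, dur)) else list(),
      noise_emg_amp = noise_emg_amp,
      baseline_drift_amp = baseline_drift_amp,
      noise_powerline_amp = noise_powerline_amp,
      seed = seed + i)
    sim <- generate_ppg(cfg)
    proc <- preprocess_ppg(sim$record)
    w <- proc$samples[seq_len(60 * sampling_rate_hz)]
    f <- window_features(w, sampling_rate_hz, window_duration_s = 60,
                         scale_max = scale_max)
    ents[[i]] <- f$mse
    prvs[[i]] <- f$prv
  }
  assemble_features(ents, prvs, labels = labels)
}
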
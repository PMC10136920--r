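#' Configuration for synthetic PPG / SpO2 recordings
#'
#' Collects every knob of the synthetic-recording generator. Defaults describe
#' a resting adult measured by a finger-worn reflective PPG sensor: 60 bpm
#' pulse, modest beat-to-beat variability, and no noise unless requested.
#'
#' Apnea episodes modulate the generator: inside an episode the beat-interval
#' standard deviation is multiplied by `apnea_sd_factor` (default 3) and the
#' pulse amplitude by `apnea_amp_factor` (default 0.8), so apneic minutes are
#' statistically separable from normal ones by variability and amplitude
#' features.
#'
#' @param sampling_rate_hz Sampling rate in Hz (default 100).
#' @param duration_s Recording duration in seconds.
#' @param base_heart_rate_bpm Mean pulse rate, in beats per minute, in
#'   `[40, 180]`.
#' @param hr_variability_sd_ms Standard deviation of beat-to-beat interval
#'   jitter, milliseconds (default 30).
#' @param apnea_episodes List of `c(start_s, end_s)` pairs, non-overlapping,
#'   sorted, inside `[0, duration_s]`.
#' @param noise_powerline_amp Amplitude of the 50 Hz power-line sine.
#' @param noise_emg_amp Amplitude (SD) of band-limited (>10 Hz) EMG-like noise.
#' @param baseline_drift_amp Peak amplitude of the sub-0.5 Hz random-walk
#'   baseline drift.
#' @param spo2_artifact_intervals List of `c(start_s, end_s)` intervals of
#'   non-pathological SpO2 drops (probe loosening).
#' @param seed Integer RNG seed; fixed seed gives bit-identical recordings.
#' @param apnea_sd_factor,apnea_amp_factor Apnea modulation factors (see
#'   Details).
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(sampling_rate_hz = 100,
                         duration_s = 120,
                         base_heart_rate_bpm = 60,
                         hr_variability_sd_ms = 30,
                         apnea_episodes = list(),
                         noise_powerline_amp = 0,
                         noise_emg_amp = 0,
                         baseline_drift_amp = 0,
                         spo2_artifact_intervals = list(),
                         seed = 1L,
                         apnea_sd_factor = 3,
                         apnea_amp_factor = 0.8) {
  if (sampling_rate_hz <= 0) stop("sampling_rate_hz must be positive")
  if (duration_s <= 0) stop("duration_s must be positive")
  if (base_heart_rate_bpm < 40 || base_heart_rate_bpm > 180) {
    stop("base_heart_rate_bpm must lie in [40, 180]")
  }
  if (hr_variability_sd_ms < 0) stop("hr_variability_sd_ms must be >= 0")
  check_intervals <- function(iv, what, no_overlap = FALSE) {
    if (length(iv) == 0) return(invisible())
    m <- do.call(rbind, lapply(iv, as.numeric))
    if (ncol(m) != 2 || any(m[, 2] <= m[, 1])) {
      stop(sprintf("%s must be (start_s, end_s) pairs with end > start", what))
    }
    if (any(m < 0) || any(m > duration_s)) {
      stop(sprintf("%s must lie within [0, duration_s]", what))
    }
    if (no_overlap && nrow(m) > 1) {
      if (is.unsorted(m[, 1], strictly = TRUE) ||
          any(m[-1, 1] < m[-nrow(m), 2])) {
        stop(sprintf("%s must be sorted and non-overlapping", what))
      }
    }
  }
  check_intervals(apnea_episodes, "apnea_episodes", no_overlap = TRUE)
  check_intervals(spo2_artifact_intervals, "spo2_artifact_intervals")
  structure(list(sampling_rate_hz = sampling_rate_hz,
                 duration_s = duration_s,
                 base_heart_rate_bpm = base_heart_rate_bpm,
                 hr_variability_sd_ms = hr_variability_sd_ms,
                 apnea_episodes = apnea_episodes,
                 noise_powerline_amp = noise_powerline_amp,
                 noise_emg_amp = noise_emg_amp,
                 baseline_drift_amp = baseline_drift_amp,
                 spo2_artifact_intervals = spo2_artifact_intervals,
                 seed = as.integer(seed),
                 apnea_sd_factor = apnea_sd_factor,
                 apnea_amp_factor = apnea_amp_factor),
            class = "synth_config")
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

in_interval <- function(t, intervals) {
  if (length(intervals) == 0) return(rep(FALSE, length(t)))
  out <- rep(FALSE, length(t))
  for (iv in intervals) out <- out | (t >= iv[1] & t < iv[2])
  out
}

interval_overlap <- function(a0, a1, intervals) {
  if (length(intervals) == 0) return(0)
  sum(vapply(intervals, function(iv) {
    max(0, min(a1, iv[2]) - max(a0, iv[1]))
  }, numeric(1)))
}

# two-Gaussian systolic + dicrotic pulse template, evaluated at time offsets dt
pulse_template <- function(dt, amp = 1) {
  amp * (exp(-(dt^2) / (2 * 0.045^2)) +
           0.25 * exp(-((dt - 0.32)^2) / (2 * 0.07^2)))
}

#' Generate a synthetic PPG recording with ground truth
#'
#' Builds a quasi-periodic pulse wave as a sum of per-beat two-Gaussian
#' (systolic + dicrotic) templates at beat times drawn from the configured
#' heart rate and interval jitter. During apnea episodes the interval SD and
#' the pulse amplitude are modulated (see [synth_config()]). Three noise
#' classes can be added: a 50 Hz power-line sine, band-limited (>10 Hz)
#' EMG-like noise, and a slow (<0.5 Hz) random-walk baseline drift.
#'
#' Ground-truth minute labels mark a minute as apneic when apnea episodes
#' overlap it by at least `min_label_overlap_s` seconds (default 10 s, the
#' conventional minimum apnea duration).
#'
#' @param config A [synth_config()].
#' @param min_label_overlap_s Minimum episode overlap for an apneic minute.
#' @return A list with `record` (a [ppg_record()]) and `truth`, a `ppg_truth`
#'   list holding `peak_indices` (1-based sample positions of systolic peaks),
#'   `window_labels` (per-minute 0/1), `spo2_series` (per-second, `NA` until
#'   [generate_spo2()] fills it) and `artifact_flags` (per-second logical).
#' @examples
#' sim <- generate_ppg(synth_config(duration_s = 10, hr_variability_sd_ms = 0))
#' diff(sim$truth$peak_indices)
#' @export
generate_ppg <- function(config, min_label_overlap_s = 10) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$sampling_rate_hz
  dur <- config$duration_s
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs

  with_seed(config$seed, {
    base_iv <- 60 / config$base_heart_rate_bpm
    sd_s <- config$hr_variability_sd_ms / 1000
    beats <- numeric(0)
    amps <- numeric(0)
    tb <- 0.5
    while (tb < dur - 0.3) {
      apneic <- in_interval(tb, config$apnea_episodes)
      beats <- c(beats, tb)
      amps <- c(amps, (if (apneic) config$apnea_amp_factor else 1) *
                  (1 + rnorm(1, 0, 0.03)))
      sd_now <- sd_s * (if (apneic) config$apnea_sd_factor else 1)
      iv <- base_iv + (if (sd_now > 0) rnorm(1, 0, sd_now) else 0)
      tb <- tb + max(0.3, iv)
    }

    x <- numeric(n)
    for (b in seq_along(beats)) {
      lo <- max(1, floor((beats[b] - 0.4) * fs) + 1)
      hi <- min(n, ceiling((beats[b] + 0.7) * fs) + 1)
      idx <- lo:hi
      x[idx] <- x[idx] + pulse_template(t[idx] - beats[b], amps[b])
    }

    if (config$noise_powerline_amp > 0) {
      x <- x + config$noise_powerline_amp * sin(2 * pi * 50 * t + runif(1, 0, 2 * pi))
    }
    if (config$noise_emg_amp > 0) {
      w <- rnorm(n)
      hp <- signal::butter(4, min(0.99, 10 / (fs / 2)), type = "high")
      e <- as.numeric(signal::filter(hp, w))
      x <- x + config$noise_emg_amp * e / stats::sd(e)
    }
    if (config$baseline_drift_amp > 0) {
      rw <- cumsum(rnorm(n))
      lp <- signal::butter(2, min(0.99, 0.5 / (fs / 2)), type = "low")
      d <- as.numeric(signal::filter(lp, rw))
      d <- d - mean(d)
      x <- x + config$baseline_drift_amp * d / max(abs(d))
    }

    peak_idx <- round(beats * fs) + 1L
    peak_idx <- peak_idx[peak_idx >= 1 & peak_idx <= n]

    n_min <- floor(dur / 60)
    labels <- integer(n_min)
    if (n_min > 0) {
      for (i in seq_len(n_min)) {
        ov <- interval_overlap(60 * (i - 1), 60 * i, config$apnea_episodes)
        labels[i] <- as.integer(ov >= min_label_overlap_s)
      }
    }
    n_sec <- floor(dur)
    art <- in_interval(seq_len(n_sec) - 1, config$spo2_artifact_intervals)

    truth <- structure(list(peak_indices = peak_idx,
                            window_labels = labels,
                            spo2_series = rep(NA_real_, n_sec),
                            artifact_flags = art),
                       class = "ppg_truth")
    list(record = ppg_record(x, fs), truth = truth)
  })
}

#' Fill in a ground-truth SpO2 series
#'
#' Produces a per-second SpO2 trace: a baseline between 96 and 99%, linear
#' desaturation during apnea episodes (5 s onset delay, 0.5 %/s fall to a
#' nadir, default 85%), linear recovery over 15 s after episode end, and
#' sharp non-pathological drops during `spo2_artifact_intervals` (probe
#' loosening) whose seconds carry `artifact_flags = TRUE`.
#'
#' Episodes of at least ~20 s dip below the 90% abnormality threshold.
#'
#' @param config The [synth_config()] used for [generate_ppg()].
#' @param truth The `ppg_truth` from [generate_ppg()].
#' @param nadir_pct Minimum SpO2 reached during long episodes.
#' @param fall_rate_pct_s Desaturation slope in percent per second.
#' @param onset_delay_s Lag between apnea onset and desaturation onset.
#' @param recovery_s Recovery ramp duration after episode end.
#' @param artifact_floor_pct Level reached during probe artifacts.
#' @return `truth` with `spo2_series` filled.
#' @export
generate_spo2 <- function(config, truth, nadir_pct = 85, fall_rate_pct_s = 0.5,
                          onset_delay_s = 5, recovery_s = 15,
                          artifact_floor_pct = 70) {
  stopifnot(inherits(config, "synth_config"), inherits(truth, "ppg_truth"))
  n_sec <- length(truth$spo2_series)
  tt <- seq_len(n_sec) - 1
  with_seed(config$seed + 104729L, {
    base <- 97.5 + 0.6 * sin(2 * pi * tt / 300 + runif(1, 0, 2 * pi)) +
      rnorm(n_sec, 0, 0.1)
    base <- pmin(98.8, pmax(96.2, base))
    s <- base
    for (iv in config$apnea_episodes) {
      lo <- iv[1] + onset_delay_s
      drop_end <- iv[2]
      for (k in which(tt >= lo & tt < drop_end + recovery_s)) {
        tk <- tt[k]
        if (tk < drop_end) {
          v <- base[k] - fall_rate_pct_s * (tk - lo)
        } else {
          v_end <- base[k] - fall_rate_pct_s * (drop_end - lo)
          v_end <- max(nadir_pct, v_end)
          v <- v_end + (base[k] - v_end) * (tk - drop_end) / recovery_s
        }
        s[k] <- min(s[k], max(nadir_pct, v))
      }
    }
    for (iv in config$spo2_artifact_intervals) {
      k <- which(tt >= iv[1] & tt < iv[2])
      if (length(k)) s[k] <- artifact_floor_pct + rnorm(length(k), 0, 0.5)
    }
    truth$spo2_series <- pmin(100, pmax(0, s))
    truth
  })
}

#' Generate dual-wavelength (red / infrared) PPG channels
#'
#' Constructs red and infrared intensity channels whose AC/DC structure
#' encodes the target SpO2 through the ratio-of-ratios
#' `R = (AC_red/DC_red) / (AC_ir/DC_ir)` and the package's linear calibration
#' (see [compute_spo2()]), so that `compute_spo2()` recovers the ground-truth
#' SpO2 within 1%.
#'
#' @param config The [synth_config()].
#' @param truth A `ppg_truth` whose `spo2_series` has been filled by
#'   [generate_spo2()].
#' @return List with `red` and `ir` [ppg_record()]s.
#' @export
generate_dual_wavelength <- function(config, truth) {
  stopifnot(inherits(truth, "ppg_truth"))
  if (anyNA(truth$spo2_series)) {
    stop("truth$spo2_series is incomplete; run generate_spo2() first")
  }
  fs <- config$sampling_rate_hz
  n <- round(config$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  f_hr <- config$base_heart_rate_bpm / 60
  pulse <- sin(2 * pi * f_hr * t)
  sec <- pmin(length(truth$spo2_series), floor(t) + 1)
  r_per_sec <- (110 - truth$spo2_series) / 25
  r_t <- r_per_sec[sec]
  ir <- 1 + 0.02 * pulse
  red <- 1 + 0.02 * r_t * pulse
  list(red = ppg_record(red, fs), ir = ppg_record(ir, fs))
}
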
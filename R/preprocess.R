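#' Running median with reflected edges
#'
#' Centered running median of odd window length `k`, with the input reflected
#' at both ends so every output sample is a true `k`-point median. This is the
#' primitive behind both [remove_baseline()] and [median_denoise()].
#'
#' @param x Numeric vector.
#' @param k Window length; even values are rounded up to the next odd.
#' @return Numeric vector, same length as `x`.
#' @keywords internal
running_median <- function(x, k) {
  k <- as.integer(k)
  if (k %% 2L == 0L) k <- k + 1L
  if (k <= 1L) return(x)
  if (k > 2L * length(x) - 1L) stop("median window longer than reflected input")
  h <- (k - 1L) %/% 2L
  xp <- c(x[(h + 1L):2L], x, x[(length(x) - 1L):(length(x) - h)])
  out <- stats::runmed(xp, k, endrule = "keep")
  out[(h + 1L):(h + length(x))]
}

#' Remove baseline drift from a PPG signal
#'
#' Estimates the baseline as a running median over a window of 2.5 seconds
#' (2.5 N samples at sampling rate N) and subtracts it, leaving the pulsatile
#' component. The long window straddles several pulse periods so the median
#' tracks the slow drift, not the pulses.
#'
#' @param rec A [ppg_record()] of at least 2.5 s.
#' @param window_s Baseline window in seconds (default 2.5).
#' @return A [ppg_record()] with the baseline removed.
#' @export
remove_baseline <- function(rec, window_s = 2.5) {
  rec <- as_ppg_record(rec)
  k <- round(window_s * rec$sampling_rate_hz)
  if (length(rec$samples) < k) {
    stop(sprintf("record too short for baseline removal: need >= %d samples", k))
  }
  base <- running_median(rec$samples, k)
  ppg_record(rec$samples - base, rec$sampling_rate_hz)
}

#' Median denoising of a PPG signal
#'
#' Replaces each sample with the median of its centered neighborhood
#' (reflect-padded at the edges), removing impulsive bursts while preserving
#' monotone trends. The default window is 2 seconds (2 N samples); note that a
#' window this long also flattens the pulse band, so the composite pipeline
#' [preprocess_ppg()] uses a much shorter despiking window by default.
#'
#' @param rec A [ppg_record()] of at least `window_s` seconds.
#' @param window_s Median window in seconds (default 2).
#' @return A denoised [ppg_record()].
#' @export
median_denoise <- function(rec, window_s = 2) {
  rec <- as_ppg_record(rec)
  k <- round(window_s * rec$sampling_rate_hz)
  if (length(rec$samples) < k) {
    stop(sprintf("record too short for median denoise: need >= %d samples", k))
  }
  ppg_record(running_median(rec$samples, k), rec$sampling_rate_hz)
}

#' Design the IIR lowpass used for PPG denoising
#'
#' Chebyshev type II lowpass: the passband edge is placed at `cutoff_hz`
#' (response within `passband_ripple_db` of 0 dB up to the cutoff) and the
#' stopband edge — the first frequency at which the attenuation reaches
#' `stopband_atten_db` — is solved numerically and reported in the design.
#' Defaults reproduce the 10th-order, 4.8 Hz, -60 dB / 1 dB filter of the
#' host-side pipeline; `order = 5, stopband_atten_db = 40` gives the lighter
#' on-sensor variant.
#'
#' @param sampling_rate_hz Sampling rate the filter will run at.
#' @param order Filter order M (the delay compensation drops M/2 samples).
#' @param cutoff_hz Passband edge in Hz.
#' @param stopband_atten_db Minimum stopband attenuation, positive dB.
#' @param passband_ripple_db Maximum passband deviation, dB.
#' @return A `lowpass_design` with coefficients `b`, `a`, the verified
#'   response extremes and the solved `stopband_edge_hz`.
#' @examples
#' d <- design_lowpass(100)
#' d$stopband_edge_hz
#' @export
design_lowpass <- function(sampling_rate_hz, order = 10, cutoff_hz = 4.8,
                           stopband_atten_db = 60, passband_ripple_db = 1) {
  nyq <- sampling_rate_hz / 2
  if (cutoff_hz <= 0 || cutoff_hz >= nyq) stop("cutoff must lie in (0, Nyquist)")
  mag_at <- function(ws_hz, f_hz) {
    flt <- signal::cheby2(order, stopband_atten_db, ws_hz / nyq)
    h <- signal::freqz(flt$b, flt$a, n = c(f_hz, f_hz), Fs = sampling_rate_hz)
    20 * log10(abs(h$h[1]))
  }
  # place the stopband edge so the response is exactly -ripple at the cutoff
  obj <- function(ws_hz) mag_at(ws_hz, cutoff_hz) + passband_ripple_db
  lo <- cutoff_hz * 1.001
  hi <- nyq * 0.999
  if (obj(lo) > 0 || obj(hi) < 0) {
    stop("infeasible lowpass specification at this order and band edges")
  }
  ws <- stats::uniroot(obj, c(lo, hi), tol = 1e-10)$root
  flt <- signal::cheby2(order, stopband_atten_db, ws / nyq)

  f_grid <- seq(0, nyq * 0.9999, length.out = 4096)
  mag <- 20 * log10(abs(signal::freqz(flt$b, flt$a, n = f_grid,
                                      Fs = sampling_rate_hz)$h))
  pass <- f_grid <= cutoff_hz
  stopb <- f_grid >= ws
  ripple <- max(abs(mag[pass]))
  atten <- max(mag[stopb])
  if (ripple > passband_ripple_db + 1e-6 || atten > -stopband_atten_db + 1e-6) {
    stop("infeasible lowpass specification: verified response misses spec")
  }
  structure(list(order = order, cutoff_hz = cutoff_hz,
                 stopband_atten_db = stopband_atten_db,
                 passband_ripple_db = passband_ripple_db,
                 sampling_rate_hz = sampling_rate_hz,
                 stopband_edge_hz = ws,
                 b = as.numeric(flt$b), a = as.numeric(flt$a),
                 passband_ripple_measured_db = ripple,
                 stopband_max_db = atten),
            class = "lowpass_design")
}

#' @export
print.lowpass_design <- function(x, ...) {
  cat(sprintf(paste0("<lowpass_design: order %d, passband to %.3g Hz ",
                     "(ripple %.3g dB), stopband from %.3g Hz (%.1f dB) @ %g Hz>\n"),
              x$order, x$cutoff_hz, x$passband_ripple_measured_db,
              x$stopband_edge_hz, -x$stopband_max_db, x$sampling_rate_hz))
  invisible(x)
}

#' Apply the IIR lowpass with delay compensation
#'
#' Filters the record and drops the first M/2 samples (M = filter order) to
#' compensate the IIR group delay.
#'
#' @param rec A [ppg_record()] at the design's sampling rate.
#' @param design A [design_lowpass()] object.
#' @return A filtered [ppg_record()], shorter by `order/2` samples.
#' @export
apply_lowpass <- function(rec, design) {
  rec <- as_ppg_record(rec)
  stopifnot(inherits(design, "lowpass_design"))
  if (!isTRUE(all.equal(rec$sampling_rate_hz, design$sampling_rate_hz))) {
    stop("record sampling rate does not match the filter design")
  }
  y <- as.numeric(signal::filter(design$b, design$a, rec$samples))
  drop <- floor(design$order / 2)
  ppg_record(y[(drop + 1):length(y)], rec$sampling_rate_hz)
}

#' Signal-to-noise ratio in dB
#'
#' `SNR = 10 log10(Ps / Pn)` for signal power `Ps` and noise power `Pn`.
#'
#' @param signal_power,noise_power Positive power estimates.
#' @return SNR in dB.
#' @examples
#' compute_snr(100, 1) # 20 dB
#' @export
compute_snr <- function(signal_power, noise_power) {
  if (any(signal_power <= 0) || any(noise_power <= 0)) {
    stop("powers must be positive")
  }
  10 * log10(signal_power / noise_power)
}

#' Cut a recording into sliding 60-second windows
#'
#' Windows of `window_s` seconds are slid by `step_s` (default 1 s: the first
#' second is dropped, one new second appended). When per-minute apnea labels
#' are supplied, each window takes the label of the minute containing at least
#' half of it.
#'
#' @param rec A [ppg_record()] of at least `window_s` seconds.
#' @param labels Optional integer/logical per-minute apnea labels.
#' @param window_s Window length in seconds (default 60).
#' @param step_s Slide step in seconds (default 1).
#' @return A list of `signal_window` objects with `samples`, `start_s` and
#'   `label`.
#' @export
segment_windows <- function(rec, labels = NULL, window_s = 60, step_s = 1) {
  rec <- as_ppg_record(rec)
  fs <- rec$sampling_rate_hz
  wl <- round(window_s * fs)
  n <- length(rec$samples)
  if (n < wl) stop("record shorter than one window")
  step <- round(step_s * fs)
  starts <- seq(1L, n - wl + 1L, by = step)
  lapply(starts, function(s0) {
    start_s <- (s0 - 1) / fs
    lab <- NA_integer_
    if (!is.null(labels)) {
      # minute holding >= 50% of the window
      minute <- if ((start_s %% 60) <= window_s / 2) floor(start_s / 60) else ceiling(start_s / 60)
      minute <- min(minute, length(labels) - 1)
      lab <- as.integer(labels[minute + 1])
    }
    structure(list(samples = rec$samples[s0:(s0 + wl - 1L)],
                   start_s = start_s, label = lab,
                   sampling_rate_hz = fs),
              class = "signal_window")
  })
}

#' Full PPG preprocessing chain
#'
#' Baseline-drift removal (2.5 s running median), short median despiking,
#' then the IIR lowpass with delay compensation. The despiking window default
#' (0.15 s) is deliberately much shorter than the standalone
#' [median_denoise()] default: a multi-second median annihilates the pulse
#' band, while a sub-pulse-width median removes isolated bursts and leaves
#' the waveform intact.
#'
#' @param rec Raw [ppg_record()].
#' @param design Optional [design_lowpass()]; defaults to the 10th-order
#'   4.8 Hz design at the record's rate.
#' @param baseline_window_s,denoise_window_s Median window lengths (seconds).
#' @return Preprocessed [ppg_record()] (shorter by `order/2` samples).
#' @export
preprocess_ppg <- function(rec, design = NULL, baseline_window_s = 2.5,
                           denoise_window_s = 0.15) {
  rec <- as_ppg_record(rec)
  if (is.null(design)) design <- design_lowpass(rec$sampling_rate_hz)
  out <- remove_baseline(rec, baseline_window_s)
  if (denoise_window_s > 0) out <- median_denoise(out, denoise_window_s)
  apply_lowpass(out, design)
}
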
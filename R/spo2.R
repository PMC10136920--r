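#' Compute SpO2 from dual-wavelength PPG channels
#'
#' For each whole second, the ratio-of-ratios
#' `R = (AC_red/DC_red) / (AC_ir/DC_ir)` is formed (DC = per-second mean,
#' AC = per-second standard deviation about the mean) and mapped to percent
#' saturation through the conventional empirical pulse-oximetry calibration
#' `SpO2 = cal[1] + cal[2] * R` (default `110 - 25 R`), clipped to the 0-100 range.
#' Seconds with a non-positive DC or an AC amplitude below `ac_floor` are
#' flagged invalid (`NA` value, quality flag `TRUE`); an error is raised only
#' when no second at all is valid.
#'
#' @param red,ir [ppg_record()]s of equal length and rate.
#' @param cal Length-2 calibration `c(intercept, slope)`.
#' @param ac_floor Minimum admissible AC amplitude (same units as the input).
#' @return An `oximetry_series`: `values` (percent, per second),
#'   `quality_flags` (`TRUE` = unreliable second).
#' @export
compute_spo2 <- function(red, ir, cal = c(110, -25), ac_floor = 1e-6) {
  stopifnot(inherits(red, "ppg_record"), inherits(ir, "ppg_record"))
  if (length(red$samples) != length(ir$samples) ||
      !isTRUE(all.equal(red$sampling_rate_hz, ir$sampling_rate_hz))) {
    stop("red and ir channels must share length and sampling rate")
  }
  fs <- red$sampling_rate_hz
  n_sec <- floor(length(red$samples) / fs)
  if (n_sec < 1) stop("channels shorter than one second")
  vals <- rep(NA_real_, n_sec)
  flags <- rep(TRUE, n_sec)
  for (s in seq_len(n_sec)) {
    k <- (round((s - 1) * fs) + 1):round(s * fs)
    dc_r <- mean(red$samples[k]); dc_i <- mean(ir$samples[k])
    ac_r <- stats::sd(red$samples[k]); ac_i <- stats::sd(ir$samples[k])
    if (dc_r <= 0 || dc_i <= 0 || ac_r < ac_floor || ac_i < ac_floor) next
    R <- (ac_r / dc_r) / (ac_i / dc_i)
    vals[s] <- min(100, max(0, cal[1] + cal[2] * R))
    flags[s] <- FALSE
  }
  if (all(flags)) stop("no valid seconds: channels carry no usable AC/DC structure")
  oximetry_series(vals, flags)
}

#' Oxygen-saturation series container
#'
#' @param values Per-second SpO2 percent values (`NA` allowed when flagged).
#' @param quality_flags Per-second logical, `TRUE` for artifact/unreliable
#'   seconds. Defaults to all-`FALSE`.
#' @return An `oximetry_series` object.
#' @export
oximetry_series <- function(values, quality_flags = NULL) {
  values <- as.numeric(values)
  if (is.null(quality_flags)) quality_flags <- rep(FALSE, length(values))
  stopifnot(length(quality_flags) == length(values))
  bad <- !is.na(values) & (values < 0 | values > 100)
  if (any(bad)) stop("SpO2 values must lie in [0, 100]")
  structure(list(values = values, quality_flags = as.logical(quality_flags)),
            class = "oximetry_series")
}

#' @export
print.oximetry_series <- function(x, ...) {
  cat(sprintf("<oximetry_series: %d s, median %.1f%%, %d flagged>\n",
              length(x$values), stats::median(x$values, na.rm = TRUE),
              sum(x$quality_flags)))
  invisible(x)
}

#' Detect oxygen desaturation events
#'
#' Maximal runs of seconds with SpO2 strictly below `threshold_pct`
#' (default 90%, the abnormality level) become events; `NA` seconds do not
#' count as desaturated. Events are disjoint, sorted, and their union is
#' exactly the set of sub-threshold seconds.
#'
#' @param series An [oximetry_series()].
#' @param threshold_pct Desaturation threshold, percent.
#' @return `data.frame` with `start_s`, `end_s` (half-open, seconds from
#'   recording start), `min_spo2` and `pathological` (`NA` until
#'   [classify_artifact()]).
#' @export
detect_desaturation <- function(series, threshold_pct = 90) {
  stopifnot(inherits(series, "oximetry_series"))
  below <- !is.na(series$values) & series$values < threshold_pct
  if (!any(below)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      min_spo2 = numeric(0), pathological = logical(0)))
  }
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(start_s = starts[keep] - 1,
             end_s = ends[keep],
             min_spo2 = vapply(keep, function(k) {
               min(series$values[starts[k]:ends[k]])
             }, numeric(1)),
             pathological = NA)
}

#' Classify a desaturation event as pathological or artifact
#'
#' A desaturation is attributed to a signal artifact (probe loosening, motion,
#' weak perfusion) — i.e. `pathological = FALSE` — when at least half of its
#' seconds carry a quality/artifact flag, combining the oximetry series' own
#' flags with optional per-second PPG quality flags. Non-pathological events
#' emit a warning so the wearer can be told to check the probe.
#'
#' @param events Event `data.frame` from [detect_desaturation()].
#' @param series The [oximetry_series()] the events came from.
#' @param ppg_quality Optional per-second logical PPG quality flags
#'   (`TRUE` = bad).
#' @param min_flag_frac Flagged-second fraction at which an event becomes
#'   non-pathological (default 0.5).
#' @return `events` with the `pathological` column filled.
#' @export
classify_artifact <- function(events, series, ppg_quality = NULL,
                              min_flag_frac = 0.5) {
  stopifnot(inherits(series, "oximetry_series"))
  bad <- series$quality_flags
  if (!is.null(ppg_quality)) {
    stopifnot(length(ppg_quality) == length(bad))
    bad <- bad | ppg_quality
  }
  if (nrow(events) == 0) return(events)
  for (k in seq_len(nrow(events))) {
    sec <- (events$start_s[k] + 1):events$end_s[k]
    frac <- mean(bad[sec])
    events$pathological[k] <- frac < min_flag_frac
    if (!events$pathological[k]) {
      warning(sprintf(paste0("SpO2 drop at %d-%d s looks non-pathological ",
                             "(probe/motion artifact); check sensor contact"),
                      events$start_s[k], events$end_s[k]))
    }
  }
  events
}
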
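#' PPG recording container
#'
#' A `ppg_record` holds a single-channel photoplethysmogram: the sampled light
#' intensity (or its AC component after preprocessing) together with the
#' sampling rate in Hz.
#'
#' @param samples Numeric vector of signal samples. Must be finite.
#' @param sampling_rate_hz Positive sampling rate in Hz.
#' @return An object of class `ppg_record` with fields `samples` and
#'   `sampling_rate_hz`.
#' @examples
#' rec <- ppg_record(sin(2 * pi * seq(0, 10, by = 0.01)), 100)
#' rec
#' @export
ppg_record <- function(samples, sampling_rate_hz) {
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1 ||
      !is.finite(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("`sampling_rate_hz` must be a positive number")
  }
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("`samples` must be non-empty")
  if (!all(is.finite(samples))) stop("`samples` must be finite")
  structure(list(samples = samples, sampling_rate_hz = sampling_rate_hz),
            class = "ppg_record")
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("<ppg_record: %d samples @ %g Hz (%.1f s)>\n",
              length(x$samples), x$sampling_rate_hz,
              length(x$samples) / x$sampling_rate_hz))
  invisible(x)
}

#' @export
length.ppg_record <- function(x) length(x$samples)

duration_s <- function(rec) length(rec$samples) / rec$sampling_rate_hz

as_ppg_record <- function(x, sampling_rate_hz = NULL) {
  if (inherits(x, "ppg_record")) return(x)
  if (is.null(sampling_rate_hz)) stop("sampling rate required")
  ppg_record(x, sampling_rate_hz)
}

#' Read / write a PPG recording as CSV
#'
#' The CSV layout is `time_s, ppg` with optional extra channels (`red`, `ir`,
#' `spo2`) as written by [write_ppg_csv()]. The sampling rate is recovered
#' from the median spacing of `time_s`.
#'
#' @param path File path.
#' @return `read_ppg_csv()` returns a list with a `ppg` record and, when
#'   present, `red`/`ir` records and a numeric `spo2` column.
#' @export
read_ppg_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("time_s", "ppg") %in% names(df))) {
    stop("CSV must contain columns time_s and ppg")
  }
  fs <- 1 / median(diff(df$time_s))
  out <- list(ppg = ppg_record(df$ppg, fs))
  for (ch in c("red", "ir")) {
    if (ch %in% names(df)) out[[ch]] <- ppg_record(df[[ch]], fs)
  }
  if ("spo2" %in% names(df)) out$spo2 <- df$spo2
  out
}

#' @param rec A [ppg_record()].
#' @param extra Optional named list of extra aligned channels (numeric vectors
#'   of the same length, e.g. `red`, `ir`, `spo2`).
#' @rdname read_ppg_csv
#' @export
write_ppg_csv <- function(rec, path, extra = NULL) {
  n <- length(rec$samples)
  df <- data.frame(time_s = (seq_len(n) - 1) / rec$sampling_rate_hz,
                   ppg = rec$samples)
  for (nm in names(extra)) {
    v <- extra[[nm]]
    if (inherits(v, "ppg_record")) v <- v$samples
    stopifnot(length(v) == n)
    df[[nm]] <- v
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
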
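# Dyadic (a-trous) wavelet pulse-peak detection.
#
# The detail coefficients at scale 2^3 of a quadratic-spline wavelet act as a
# smoothed derivative: each pulse produces a positive modulus maximum on its
# rising edge and a negative one on the falling edge, and the zero-crossing
# between the pair sits on the waveform peak.

# smoothing filter H = (1,3,3,1)/8 and detail filter G = (2,-2) of the
# quadratic-spline wavelet; causal taps at offsets k*dilation
.mz_h <- c(1, 3, 3, 1) / 8
.mz_g <- c(2, -2)

# causal dilated convolution with symmetric start padding
.atrous_conv <- function(x, f, dilation) {
  n <- length(x)
  span <- (length(f) - 1L) * dilation
  xp <- c(rev(x[seq_len(min(span, n))]), x)
  if (span > n) xp <- c(rep(x[1], span - n), xp)
  acc <- numeric(n)
  for (k in seq_along(f)) {
    off <- (k - 1L) * dilation
    acc <- acc + f[k] * xp[(span - off + 1L):(span - off + n)]
  }
  acc
}

#' Dyadic wavelet detail coefficients at scale 2^3
#'
#' Undecimated (a-trous) quadratic-spline wavelet transform of the input at
#' decomposition level 3. The output has the same length as the input;
#' `alignment` gives the (fractional) shift such that coefficient position
#' `p` reflects input position `p - alignment`.
#'
#' @param rec A [ppg_record()] (or numeric vector with `sampling_rate_hz`).
#' @param sampling_rate_hz Rate, when `rec` is a bare vector.
#' @return A `wavelet_decomposition`: `coefficients`, `alignment`,
#'   `sampling_rate_hz`.
#' @export
wavelet_scale3 <- function(rec, sampling_rate_hz = NULL) {
  rec <- as_ppg_record(rec, sampling_rate_hz)
  x <- rec$samples
  if (length(x) < 64) stop("record too short for level-3 wavelet transform")
  s1 <- .atrous_conv(x, .mz_h, 1L)
  s2 <- .atrous_conv(s1, .mz_h, 2L)
  w3 <- .atrous_conv(s2, .mz_g, 4L)
  # causal group delays: 1.5 + 3 (smoothing) + 2 (detail) = 6.5 samples
  structure(list(coefficients = w3, alignment = 6.5,
                 sampling_rate_hz = rec$sampling_rate_hz),
            class = "wavelet_decomposition")
}

#' Adaptive modulus-maxima thresholds
#'
#' `thp = c * RMS(positive coefficients)`, `thn = -c * RMS(negative
#' coefficients)`. The modulus-maxima pairing keeps only extrema beyond these.
#'
#' @param dec A [wavelet_scale3()] decomposition.
#' @param c_thr Multiplier (default 1.5).
#' @return A `threshold_pair` list with `thp > 0 > thn`.
#' @export
wavelet_thresholds <- function(dec, c_thr = 1.5) {
  w <- dec$coefficients
  pos <- w[w > 0]; neg <- w[w < 0]
  if (length(pos) == 0 || length(neg) == 0) {
    return(structure(list(thp = Inf, thn = -Inf, c_thr = c_thr),
                     class = "threshold_pair"))
  }
  structure(list(thp = c_thr * sqrt(mean(pos^2)),
                 thn = -c_thr * sqrt(mean(neg^2)),
                 c_thr = c_thr),
            class = "threshold_pair")
}

.local_extrema <- function(w) {
  n <- length(w)
  if (n < 3) return(list(max = integer(0), min = integer(0)))
  i <- 2:(n - 1)
  list(max = i[w[i] >= w[i - 1] & w[i] > w[i + 1]],
       min = i[w[i] <= w[i - 1] & w[i] < w[i + 1]])
}

#' Pair positive and negative modulus maxima
#'
#' Scans above-threshold local extrema left to right. A positive extremum
#' followed by a negative one with a monotone (non-increasing, up to
#' `mono_tol` of the pair range) coefficient path between them forms a pair;
#' extrema that cannot be paired are orphans and are removed.
#'
#' @param dec A [wavelet_scale3()] decomposition.
#' @param thr A [wavelet_thresholds()] pair.
#' @param mono_tol Allowed fractional backtracking on the path (default 0.1).
#' @param range Optional `c(lo, hi)` coefficient-index range to search.
#' @return A two-column matrix `(pos_idx, neg_idx)`; zero rows when nothing
#'   qualifies.
#' @export
find_maxima_pairs <- function(dec, thr, mono_tol = 0.1, range = NULL) {
  w <- dec$coefficients
  lo <- 1L; hi <- length(w)
  if (!is.null(range)) {
    lo <- max(1L, as.integer(range[1])); hi <- min(length(w), as.integer(range[2]))
    if (hi - lo < 2L) return(matrix(integer(0), ncol = 2,
                                    dimnames = list(NULL, c("pos_idx", "neg_idx"))))
  }
  seg <- w[lo:hi]
  ext <- .local_extrema(seg)
  pos <- ext$max[seg[ext$max] > thr$thp]
  neg <- ext$min[seg[ext$min] < thr$thn]
  events <- rbind(if (length(pos)) cbind(pos, 1L),
                  if (length(neg)) cbind(neg, -1L))
  out <- NULL
  if (!is.null(events) && nrow(events) > 1) {
    events <- events[order(events[, 1]), , drop = FALSE]
    i <- 1L
    while (i < nrow(events)) {
      if (events[i, 2] == 1L && events[i + 1, 2] == -1L) {
        pi <- events[i, 1]; ni <- events[i + 1, 1]
        path <- seg[pi:ni]
        tol <- mono_tol * (seg[pi] - seg[ni])
        if (all(diff(path) <= tol)) {
          out <- rbind(out, c(pi + lo - 1L, ni + lo - 1L))
          i <- i + 2L
          next
        }
      }
      i <- i + 1L  # orphan (or unpaired) extremum dropped
    }
  }
  if (is.null(out)) out <- matrix(integer(0), ncol = 2)
  dimnames(out) <- list(NULL, c("pos_idx", "neg_idx"))
  out
}

#' Locate pulse peaks at the zero-crossings of maxima pairs
#'
#' For each (positive, negative) pair, the coefficient zero-crossing between
#' the two extrema is found, linearly interpolated, alignment-corrected and
#' rounded to the nearest input sample. Pairs without a sign change are
#' skipped with a warning.
#'
#' @param pairs Matrix from [find_maxima_pairs()].
#' @param dec The matching [wavelet_scale3()] decomposition.
#' @return Integer vector of candidate peak sample indices.
#' @export
locate_peaks <- function(pairs, dec) {
  w <- dec$coefficients
  n <- length(w)
  out <- integer(0)
  for (k in seq_len(nrow(pairs))) {
    pi <- pairs[k, 1]; ni <- pairs[k, 2]
    seg <- w[pi:ni]
    cross <- which(seg[-length(seg)] > 0 & seg[-1] <= 0)
    if (length(cross) == 0) {
      warning("maxima pair without zero-crossing skipped")
      next
    }
    j <- cross[1]
    a <- seg[j]; b <- seg[j + 1]
    frac <- if (a == b) 0 else a / (a - b)
    pos <- (pi + j - 1) + frac - dec$alignment
    out <- c(out, as.integer(round(pos)))
  }
  out[out >= 1L & out <= n]
}

#' Enforce the 200 ms refractory period
#'
#' Greedy left-to-right suppression: any candidate closer than
#' `refractory_s` (default 0.2 s) after the last accepted peak is ignored,
#' matching normal cardiac refractoriness.
#'
#' @param candidates Sorted integer sample indices.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param refractory_s Minimum peak spacing in seconds.
#' @return Filtered integer vector.
#' @export
apply_refractory <- function(candidates, sampling_rate_hz, refractory_s = 0.2) {
  if (length(candidates) == 0) return(integer(0))
  candidates <- sort(unique(as.integer(candidates)))
  gap <- refractory_s * sampling_rate_hz
  keep <- candidates[1]
  for (c0 in candidates[-1]) {
    if (c0 - keep[length(keep)] >= gap) keep <- c(keep, c0)
  }
  keep
}

peak_train <- function(idx, rec) {
  idx <- sort(unique(as.integer(idx)))
  structure(list(peak_indices = idx,
                 peak_amplitudes = rec$samples[idx],
                 sampling_rate_hz = rec$sampling_rate_hz),
            class = "peak_train")
}

#' @export
print.peak_train <- function(x, ...) {
  cat(sprintf("<peak_train: %d peaks @ %g Hz>\n",
              length(x$peak_indices), x$sampling_rate_hz))
  invisible(x)
}

#' Recover missed beats in long inter-peak gaps
#'
#' Any gap longer than `gap_factor` (default 1.5) times the mean peak-to-peak
#' interval is re-searched with the thresholds relaxed to 4/5 of their
#' values; the search stays strictly inside the gap, excluding the 200 ms
#' refractory zones of the flanking peaks. Thresholds are restored afterward
#' and the refractory rule is re-enforced on the merged train. A single pass
#' over the gaps guarantees termination.
#'
#' @param train A `peak_train` with at least 2 peaks.
#' @param dec The [wavelet_scale3()] decomposition of the same record.
#' @param thr The original [wavelet_thresholds()].
#' @param rec The [ppg_record()] the train came from.
#' @param gap_factor Gap multiple of the mean PP interval triggering recovery.
#' @param relax Threshold relaxation factor (default 4/5).
#' @return A `peak_train` with recovered peaks merged in.
#' @export
recover_missed <- function(train, dec, thr, rec, gap_factor = 1.5, relax = 4 / 5) {
  idx <- train$peak_indices
  if (length(idx) < 2) return(train)
  fs <- train$sampling_rate_hz
  mean_pp <- mean(diff(idx))
  relaxed <- structure(list(thp = relax * thr$thp, thn = relax * thr$thn,
                            c_thr = thr$c_thr), class = "threshold_pair")
  refr <- round(0.2 * fs)
  extra <- integer(0)
  gaps <- which(diff(idx) > gap_factor * mean_pp)
  for (g in gaps) {
    lo <- idx[g] + refr
    hi <- idx[g + 1] - refr
    clo <- lo + dec$alignment; chi <- hi + dec$alignment
    pairs <- find_maxima_pairs(dec, relaxed, range = c(floor(clo), ceiling(chi)))
    cand <- locate_peaks(pairs, dec)
    cand <- cand[cand > lo & cand < hi]
    if (length(cand) == 0) {
      warning(sprintf("gap after peak %d: no recoverable beat found", idx[g]))
      next
    }
    extra <- c(extra, cand)
  }
  merged <- apply_refractory(c(idx, extra), fs)
  peak_train(merged, rec)
}

#' Detect pulse peaks in a preprocessed PPG signal
#'
#' Full modulus-maxima pipeline: level-3 dyadic wavelet transform, adaptive
#' thresholding, positive/negative extremum pairing with monotonicity and
#' orphan removal, zero-crossing peak localization, 200 ms refractory
#' suppression, and relaxed-threshold recovery of beats missed inside long
#' gaps.
#'
#' @param rec A preprocessed [ppg_record()] (see [preprocess_ppg()]).
#' @param c_thr Threshold multiplier for [wavelet_thresholds()].
#' @param mono_tol Monotonicity tolerance for [find_maxima_pairs()].
#' @param recover Run the missed-beat recovery pass (default TRUE)?
#' @return A `peak_train` with `peak_indices`, `peak_amplitudes` and the
#'   sampling rate. Consecutive peaks are always >= 200 ms apart.
#' @export
detect_peaks <- function(rec, c_thr = 1.5, mono_tol = 0.1, recover = TRUE) {
  rec <- as_ppg_record(rec)
  dec <- wavelet_scale3(rec)
  thr <- wavelet_thresholds(dec, c_thr)
  if (!is.finite(thr$thp)) return(peak_train(integer(0), rec))
  pairs <- find_maxima_pairs(dec, thr, mono_tol = mono_tol)
  cand <- locate_peaks(pairs, dec)
  kept <- apply_refractory(cand, rec$sampling_rate_hz)
  train <- peak_train(kept, rec)
  if (recover && length(kept) >= 2) {
    train <- recover_missed(train, dec, thr, rec)
  }
  train
}
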
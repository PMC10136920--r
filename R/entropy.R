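#' Coarse-grain a time series (traditional block means)
#'
#' Classical multiscale-entropy coarse-graining: non-overlapping blocks of
#' `scale` samples are averaged, `y_j = mean(x[(j-1)*tau+1 .. j*tau])`. The
#' series length becomes `floor(L / tau)`; up to `tau - 1` tail samples are
#' discarded, which is the accuracy defect the sliding-window variant
#' ([coarse_grain_improved()]) repairs.
#'
#' @param x Numeric vector.
#' @param scale Integer scale factor `tau >= 1`.
#' @return A `coarse_series` list: `values`, `scale`, `source_length`,
#'   `method`.
#' @examples
#' coarse_grain_traditional(1:6, 2)$values # 1.5 3.5 5.5
#' @export
coarse_grain_traditional <- function(x, scale) {
  scale <- as.integer(scale)
  if (scale < 1) stop("scale must be >= 1")
  L <- length(x)
  if (scale > L) stop("scale exceeds series length")
  if (scale == 1L) {
    vals <- as.numeric(x)
  } else {
    nb <- L %/% scale
    vals <- colMeans(matrix(x[seq_len(nb * scale)], nrow = scale))
  }
  structure(list(values = vals, scale = scale, source_length = L,
                 method = "traditional"),
            class = "coarse_series")
}

#' Coarse-grain a time series (sliding-window, 50% overlap)
#'
#' Overlap coarse-graining: a window of `scale` samples slides in steps of
#' half the window (`step = max(1, round(scale/2))`, ties rounded up) and each
#' full window contributes its mean. All samples are used whenever
#' `(L - tau)` is divisible by the step, so no tail data is lost at any scale,
#' and the coarse series is at least as long as the traditional one.
#'
#' @inheritParams coarse_grain_traditional
#' @return A `coarse_series` list (`method = "improved"`).
#' @examples
#' coarse_grain_improved(1:4, 2)$values # 1.5 2.5 3.5
#' @export
coarse_grain_improved <- function(x, scale) {
  scale <- as.integer(scale)
  if (scale < 1) stop("scale must be >= 1")
  L <- length(x)
  if (scale > L) stop("scale exceeds series length")
  if (scale == 1L) {
    vals <- as.numeric(x)
  } else {
    step <- max(1L, as.integer(floor(scale / 2 + 0.5)))
    starts <- seq(1L, L - scale + 1L, by = step)
    vals <- vapply(starts, function(s) mean(x[s:(s + scale - 1L)]), numeric(1))
  }
  structure(list(values = vals, scale = scale, source_length = L,
                 method = "improved"),
            class = "coarse_series")
}

#' Sample entropy of a series
#'
#' SampEn(m, r): the negative log of the conditional probability that two
#' subsequences matching for `m` points (Chebyshev distance within `r`,
#' self-matches excluded) also match at the `m+1`-th point. Template pairs are
#' counted over the first `N - m` positions at both dimensions, so a constant
#' series gives exactly 0 and the value is non-negative whenever defined.
#'
#' When no template pair matches at dimension `m+1` (or `m`) the quantity is
#' undefined; `NaN` is returned with attribute `undefined = TRUE` so callers
#' can impute explicitly.
#'
#' @param y Numeric vector, length > `m + 1`.
#' @param m Embedding dimension (default 2).
#' @param r Tolerance: a fraction of `sd(y)` when `r_type = "sd_fraction"`
#'   (default 0.2), or an absolute amplitude when `r_type = "absolute"`.
#' @param r_type How to interpret `r`.
#' @return A single number (possibly `NaN` flagged `undefined`).
#' @examples
#' sample_entropy(rep(1, 50)) # 0
#' @export
sample_entropy <- function(y, m = 2, r = 0.2, r_type = c("sd_fraction", "absolute")) {
  r_type <- match.arg(r_type)
  y <- as.numeric(y)
  m <- as.integer(m)
  if (m < 1) stop("m must be >= 1")
  if (length(y) <= m + 1) stop("series too short for sample entropy")
  r_abs <- if (r_type == "sd_fraction") {
    if (r <= 0 || r >= 1) stop("fractional r must lie in (0, 1)")
    s <- stats::sd(y)
    if (s == 0) 0 else r * s  # constant series: any tolerance matches
  } else {
    if (r <= 0) stop("absolute r must be positive")
    r
  }
  cnt <- sampen_counts(y, m, r_abs)
  B <- cnt[1]; A <- cnt[2]
  if (B == 0 || A == 0) {
    return(structure(NaN, undefined = TRUE))
  }
  -log(A / B)
}

#' Multiscale sample entropy vector
#'
#' Computes SampEn on coarse-grained versions of `x` for scale factors 1 to
#' `scale_max` (default 15). The tolerance is fixed once as `r` times `sd(x)` of the
#' original series and reused at every scale, the common multiscale-entropy
#' convention. At scale 1 both coarse-graining methods return the raw series,
#' so the first entry always equals `sample_entropy(x)`.
#'
#' @param x Numeric vector.
#' @param m Embedding dimension.
#' @param r Tolerance as a fraction of `sd(x)`.
#' @param scale_max Largest scale factor (default 15).
#' @param method `"improved"` (sliding-window coarse-graining, default) or
#'   `"traditional"`.
#' @return An `mse_vector`: named numeric vector `s1..s<scale_max>` with
#'   attributes `undefined` (logical vector) and `params`.
#' @export
mse_vector <- function(x, m = 2, r = 0.2, scale_max = 15,
                       method = c("improved", "traditional")) {
  method <- match.arg(method)
  x <- as.numeric(x)
  if (scale_max < 1) stop("scale_max must be >= 1")
  s <- stats::sd(x)
  r_abs <- if (s == 0) .Machine$double.eps else r * s
  cg <- if (method == "improved") coarse_grain_improved else coarse_grain_traditional
  vals <- numeric(scale_max)
  undef <- logical(scale_max)
  for (tau in seq_len(scale_max)) {
    y <- cg(x, tau)$values
    if (length(y) <= m + 1) {
      vals[tau] <- NaN; undef[tau] <- TRUE; next
    }
    e <- sample_entropy(y, m = m, r = r_abs, r_type = "absolute")
    vals[tau] <- as.numeric(e)
    undef[tau] <- isTRUE(attr(e, "undefined")) || !is.finite(vals[tau])
  }
  structure(vals, names = paste0("s", seq_len(scale_max)),
            undefined = undef,
            params = list(m = m, r = r, scale_max = scale_max, method = method),
            class = "mse_vector")
}

#' @export
print.mse_vector <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<mse_vector: scales 1..%d, m=%d, r=%.3g, %s coarse-graining>\n",
              p$scale_max, p$m, p$r, p$method))
  print(round(unclass(x)[seq_along(x)], 4))
  invisible(x)
}
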
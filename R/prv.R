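.prv_names <- c("pr", "pp_mean", "sdnn_pp", "pp_median", "nn50", "pnn50",
                "sdnn_aa", "aa_mean", "aa_median")

#' Pulse-rate-variability features of a peak train
#'
#' Time-domain PRV statistics over one analysis window: pulse rate (PR,
#' beats/min), mean / SD / median of the peak-to-peak intervals (ms), NN50
#' (count of successive interval differences exceeding 50 ms), PNN50 (NN50 as
#' a fraction of the successive differences), and SD / mean / median of the
#' peak amplitudes.
#'
#' Windows with fewer than 3 peaks are degenerate: PR is still computed from
#' the peak count, dispersion features are `NaN` and the result carries
#' attribute `degenerate = TRUE` (imputed downstream by
#' [assemble_features()]).
#'
#' @param train A `peak_train` from [detect_peaks()].
#' @param window_duration_s Duration the train was detected over, seconds.
#' @return Named numeric vector of the 9 features.
#' @examples
#' rec <- ppg_record(rep(0, 600), 100)
#' tr <- structure(list(peak_indices = seq(1, 501, by = 100),
#'                      peak_amplitudes = rep(1, 6), sampling_rate_hz = 100),
#'                 class = "peak_train")
#' compute_prv(tr, 6)
#' @export
compute_prv <- function(train, window_duration_s) {
  stopifnot(inherits(train, "peak_train"), window_duration_s > 0)
  idx <- train$peak_indices
  fs <- train$sampling_rate_hz
  p <- length(idx)
  pr <- p * 60 / window_duration_s
  if (p < 3) {
    out <- c(pr, rep(NaN, 8))
    names(out) <- .prv_names
    return(structure(out, degenerate = TRUE))
  }
  pp_ms <- diff(idx) / fs * 1000
  dpp <- diff(pp_ms)
  nn50 <- sum(abs(dpp) > 50)
  amps <- train$peak_amplitudes
  out <- c(pr,
           mean(pp_ms), stats::sd(pp_ms), stats::median(pp_ms),
           nn50, nn50 / length(dpp),
           stats::sd(amps), mean(amps), stats::median(amps))
  names(out) <- .prv_names
  structure(out, degenerate = FALSE)
}

#' Assemble the per-window feature matrix
#'
#' Binds the multiscale-entropy vectors and PRV feature sets of aligned
#' windows into one numeric matrix with a fixed column order:
#' `s1..s<scale_max>` followed by the 9 PRV features. Non-finite entries
#' (undefined entropies, degenerate PRV windows) are imputed with the column
#' median of the finite values (0 when a column has none); the returned mask
#' records which cells were imputed.
#'
#' @param entropy_vectors List of [mse_vector()]s (or a numeric matrix).
#' @param prv_sets List of [compute_prv()] vectors (or a numeric matrix).
#' @param labels Optional per-window 0/1 apnea labels.
#' @param window_starts Optional per-window start offsets (seconds).
#' @return A `feature_matrix` list: `features` (n x p matrix), `mask`
#'   (logical, `TRUE` where imputed), `labels`, `window_starts`, `medians`
#'   (the imputation constants, reusable at prediction time).
#' @export
assemble_features <- function(entropy_vectors, prv_sets, labels = NULL,
                              window_starts = NULL) {
  to_mat <- function(x) {
    if (is.matrix(x)) return(x)
    if (length(x) == 0) return(NULL)
    do.call(rbind, lapply(x, function(v) as.numeric(unclass(v))))
  }
  em <- to_mat(entropy_vectors)
  pm <- to_mat(prv_sets)
  if (is.null(em) || is.null(pm)) {
    feats <- matrix(numeric(0), nrow = 0, ncol = 0)
    return(structure(list(features = feats, mask = feats == 1,
                          labels = integer(0), window_starts = numeric(0),
                          medians = numeric(0)),
                     class = "feature_matrix"))
  }
  if (nrow(em) != nrow(pm)) stop("entropy and PRV inputs are misaligned")
  if (!is.null(labels) && length(labels) != nrow(em)) {
    stop("labels are misaligned with windows")
  }
  colnames(em) <- paste0("s", seq_len(ncol(em)))
  colnames(pm) <- .prv_names[seq_len(ncol(pm))]
  feats <- cbind(em, pm)
  mask <- !is.finite(feats)
  meds <- apply(feats, 2, function(col) {
    f <- col[is.finite(col)]
    if (length(f) == 0) 0 else stats::median(f)
  })
  for (j in which(colSums(mask) > 0)) feats[mask[, j], j] <- meds[j]
  structure(list(features = feats, mask = mask,
                 labels = if (is.null(labels)) NULL else as.integer(labels),
                 window_starts = window_starts,
                 medians = meds),
            class = "feature_matrix")
}

#' Embedded tree-importance feature selection
#'
#' Fits a random forest on the labelled feature matrix, ranks the columns by
#' impurity (Gini) importance and keeps those at or above the threshold
#' (default: the mean importance). The mask is reproducible under a fixed
#' seed.
#'
#' @param x Numeric feature matrix (imputed, no non-finite values).
#' @param labels Binary labels with both classes present.
#' @param importance_threshold Importance cutoff; `NULL` for the mean.
#' @param seed RNG seed.
#' @param ntree Forest size.
#' @return Logical column mask with the importances as attribute
#'   `importance`.
#' @export
select_features <- function(x, labels, importance_threshold = NULL,
                            seed = 1L, ntree = 200) {
  x <- as.matrix(x)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("feature selection needs both classes present")
  const <- apply(x, 2, function(col) diff(range(col)) == 0)
  if (all(const)) {
    warning("all feature columns are constant; empty selection")
    return(structure(stats::setNames(rep(FALSE, ncol(x)), colnames(x)),
                     importance = stats::setNames(rep(0, ncol(x)), colnames(x))))
  }
  fit <- with_seed(seed, randomForest::randomForest(x, labels, ntree = ntree))
  imp <- randomForest::importance(fit)[, 1]
  thr <- if (is.null(importance_threshold)) mean(imp) else importance_threshold
  structure(imp >= thr, importance = imp)
}
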
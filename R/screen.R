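#' Apnea-hypopnea index
#'
#' Events per hour of recording.
#'
#' @param event_count Number of confirmed apnea events.
#' @param recording_hours Recording duration in hours, > 0.
#' @return AHI in events/hour.
#' @examples
#' compute_ahi(10, 2) # 5
#' @export
compute_ahi <- function(event_count, recording_hours) {
  if (recording_hours <= 0) stop("recording_hours must be positive")
  event_count / recording_hours
}

#' Severity class from AHI
#'
#' Standard clinical cutoffs: `< 5` none, `5-15` mild, `15-30` moderate,
#' `> 30` severe.
#'
#' @param ahi AHI in events/hour.
#' @return One of `"none"`, `"mild"`, `"moderate"`, `"severe"`.
#' @export
severity_class <- function(ahi) {
  if (ahi < 5) "none" else if (ahi <= 15) "mild"
  else if (ahi <= 30) "moderate" else "severe"
}

.merge_positive_windows <- function(starts, window_s, min_event_s = 10) {
  if (length(starts) == 0) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  starts <- sort(starts)
  ev_start <- starts[1]; ev_end <- starts[1] + window_s
  out <- NULL
  for (s in starts[-1]) {
    if (s <= ev_end) {
      ev_end <- s + window_s
    } else {
      out <- rbind(out, c(ev_start, ev_end))
      ev_start <- s; ev_end <- s + window_s
    }
  }
  out <- rbind(out, c(ev_start, ev_end))
  out <- as.data.frame(out)
  names(out) <- c("start_s", "end_s")
  out[out$end_s - out$start_s >= min_event_s, , drop = FALSE]
}

#' Comprehensive apnea screening of a recording
#'
#' End-to-end pipeline: preprocess the raw PPG, cut it into 60 s windows,
#' classify each window from its multiscale-entropy + PRV features, gate the
#' PPG-positive windows against the SpO2 evidence, merge consecutive positive
#' windows into apnea events and report the AHI with a severity class.
#'
#' SpO2 gating: a PPG-positive window is *confirmed* when it overlaps a
#' pathological desaturation (< 90%); it is *rejected with a warning* when it
#' overlaps only artifact-flagged drops (probe loosening etc.); it is left
#' unconfirmed when SpO2 is available but shows no desaturation; without any
#' SpO2 channel all PPG-positive windows are accepted with a low-confidence
#' note.
#'
#' @param ppg Raw (or preprocessed, see `preprocessed`) [ppg_record()], at
#'   least 60 s.
#' @param model A trained [train_model()] `apnea_model`.
#' @param spo2 Optional [oximetry_series()] (or per-second numeric vector)
#'   aligned to the recording start.
#' @param step_s Window stride in seconds; default 60 (non-overlapping
#'   minutes, matching the one-minute label unit).
#' @param window_s Window length (default 60 s).
#' @param desat_threshold_pct Desaturation threshold (default 90).
#' @param preprocessed Set `TRUE` when `ppg` is already preprocessed.
#' @param design Optional [design_lowpass()] for preprocessing.
#' @return An `apnea_report`: per-window table, confirmed events, AHI,
#'   severity and accumulated warnings.
#' @export
diagnose <- function(ppg, model, spo2 = NULL, step_s = 60, window_s = 60,
                     desat_threshold_pct = 90, preprocessed = FALSE,
                     design = NULL) {
  stopifnot(inherits(model, "apnea_model"))
  ppg <- as_ppg_record(ppg)
  fs <- ppg$sampling_rate_hz
  if (duration_s(ppg) < window_s) stop("recording shorter than one window")
  rec_hours <- duration_s(ppg) / 3600
  warnings_log <- character(0)

  proc <- if (preprocessed) ppg else preprocess_ppg(ppg, design = design)
  wins <- segment_windows(proc, window_s = window_s, step_s = step_s)

  ents <- vector("list", length(wins))
  prvs <- vector("list", length(wins))
  for (i in seq_along(wins)) {
    f <- window_features(wins[[i]]$samples, fs, window_duration_s = window_s)
    ents[[i]] <- f$mse
    prvs[[i]] <- f$prv
  }
  starts <- vapply(wins, function(w) w$start_s, numeric(1))
  fm <- assemble_features(ents, prvs, window_starts = starts)
  feats <- fm$features
  # impute with the training medians the model carries, where available
  if (!is.null(model$impute_medians) && any(fm$mask)) {
    med <- model$impute_medians[colnames(feats)]
    for (j in which(colSums(fm$mask) > 0)) {
      if (is.finite(med[j])) feats[fm$mask[, j], j] <- med[j]
    }
  }
  ppg_pos <- predict(model, feats) == "1"

  # SpO2 evidence
  events <- NULL
  spo2_available <- !is.null(spo2)
  if (spo2_available) {
    if (!inherits(spo2, "oximetry_series")) spo2 <- oximetry_series(spo2)
    events <- detect_desaturation(spo2, desat_threshold_pct)
    events <- withCallingHandlers(
      classify_artifact(events, spo2),
      warning = function(w) {
        warnings_log <<- c(warnings_log, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  } else {
    warnings_log <- c(warnings_log,
                      "no SpO2 channel: PPG-only decisions, low confidence")
  }

  overlap_any <- function(a0, a1, ev) {
    if (is.null(ev) || nrow(ev) == 0) return(logical(0))
    ev$start_s < a1 & ev$end_s > a0
  }
  evidence <- character(length(wins))
  final <- logical(length(wins))
  for (i in seq_along(wins)) {
    a0 <- starts[i]; a1 <- starts[i] + window_s
    if (!ppg_pos[i]) {
      evidence[i] <- "none"; final[i] <- FALSE; next
    }
    if (!spo2_available) {
      evidence[i] <- "no_spo2"; final[i] <- TRUE; next
    }
    ov <- overlap_any(a0, a1, events)
    if (length(ov) && any(ov & events$pathological)) {
      evidence[i] <- "confirmed"; final[i] <- TRUE
    } else if (length(ov) && any(ov)) {
      evidence[i] <- "artifact"; final[i] <- FALSE
      warnings_log <- c(warnings_log, sprintf(
        "window at %g s excluded: SpO2 drop attributed to sensor artifact", a0))
    } else {
      evidence[i] <- "no_desat"; final[i] <- FALSE
    }
  }

  ev_tab <- .merge_positive_windows(starts[final], window_s)
  ahi <- compute_ahi(nrow(ev_tab), rec_hours)
  structure(list(
    per_window = data.frame(start_s = starts,
                            ppg_decision = as.integer(ppg_pos),
                            spo2_evidence = evidence,
                            final_decision = as.integer(final)),
    events = ev_tab,
    event_count = nrow(ev_tab),
    recording_hours = rec_hours,
    ahi = ahi,
    severity = severity_class(ahi),
    warnings = warnings_log),
    class = "apnea_report")
}

#' @export
print.apnea_report <- function(x, ...) {
  cat("Apnea screening report\n")
  cat(sprintf("  recording: %.2f h, %d windows analysed\n",
              x$recording_hours, nrow(x$per_window)))
  cat(sprintf("  confirmed apnea events: %d\n", x$event_count))
  cat(sprintf("  AHI: %.1f events/hour  (severity: %s)\n", x$ahi, x$severity))
  if (length(x$warnings)) {
    cat(sprintf("  warnings (%d):\n", length(x$warnings)))
    for (w in unique(x$warnings)) cat("   - ", w, "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.apnea_report <- function(object, ...) {
  cat(sprintf("AHI %.2f (%s); %d/%d windows PPG-positive, %d confirmed\n",
              object$ahi, object$severity,
              sum(object$per_window$ppg_decision),
              nrow(object$per_window),
              sum(object$per_window$final_decision)))
  invisible(object)
}

#' Serialize / restore an apnea report as JSON
#'
#' Round-trips losslessly: `report_from_json(report_to_json(x))` reproduces
#' every field.
#'
#' @param report An `apnea_report`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `report_to_json`: the JSON string (invisibly when written to
#'   file); `report_from_json`: the restored `apnea_report`.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "apnea_report"))
  j <- jsonlite::toJSON(unclass(report), digits = NA, auto_unbox = TRUE,
                        dataframe = "columns")
  if (!is.null(path)) {
    writeLines(j, path)
    return(invisible(j))
  }
  j
}

#' @param json JSON string or file path produced by [report_to_json()].
#' @rdname report_to_json
#' @export
report_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  x$per_window <- as.data.frame(x$per_window)
  x$events <- as.data.frame(x$events)
  if (nrow(x$events) == 0) {
    x$events <- data.frame(start_s = numeric(0), end_s = numeric(0))
  }
  x$warnings <- as.character(x$warnings)
  structure(x, class = "apnea_report")
}
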
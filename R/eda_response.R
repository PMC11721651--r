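#' Extract a gesture-aligned EDA window
#'
#' Skin-conductance responses follow their stimulus with a latency of
#' typically 1--3 s, so each gesture's window spans the gesture itself plus
#' `latency_pad` seconds (default 1.5 s) post-gesture. The window is the
#' half-open interval `[onset, offset + latency_pad)` so that at 4 Hz no
#' boundary sample is counted twice by adjacent windows. Windows that run
#' past either end of the trace are truncated and flagged; a window wholly
#' outside the sampled span is a coverage error.
#'
#' @param gesture_id gesture identifier
#' @param onset,offset gesture span, seconds
#' @param trace an [eda_trace()]
#' @param latency_pad post-gesture extension, seconds
#' @return object of class `response_window` with the selected samples;
#'   `amplitude` and `specific` unset until [classify_specific()]
#' @export
extract_window <- function(gesture_id, onset, offset, trace, latency_pad = 1.5) {
  stopifnot(inherits(trace, "eda_trace"), offset >= onset, latency_pad >= 0)
  w0 <- onset
  w1 <- offset + latency_pad
  tt <- trace_times(trace)
  sel <- tt >= w0 & tt < w1
  if (!any(sel)) {
    stop_ctx("window [%.2f, %.2f) of gesture %s not covered by trace of %s",
             w0, w1, gesture_id, trace$participant_id, class = "coverage_error")
  }
  structure(
    list(gesture_id = gesture_id, participant_id = trace$participant_id,
         window_start = w0, window_end = w1,
         times = tt[sel], samples = trace$values[sel],
         truncated = (w0 < trace$t0 - 1e-9) | (w1 > trace_end(trace) + 1e-9),
         amplitude = NA_real_, specific = NA),
    class = "response_window")
}

#' Classify a window as a specific EDA response
#'
#' The window's amplitude is the maximal trough-to-peak rise within it: the
#' maximum over ordered sample pairs i < j of `value[j] - value[i]`, floored
#' at 0. This reads the conventional skin-conductance response amplitude and
#' is robust to a declining tonic baseline. The response is *specific* --
#' taken to index stimulus-related arousal -- iff the amplitude strictly
#' exceeds `threshold` (default 0.05 uS).
#'
#' @param w a `response_window` from [extract_window()]
#' @param threshold specificity threshold in uS (strict inequality)
#' @return the window with `amplitude` and `specific` filled
#' @export
classify_specific <- function(w, threshold = 0.05) {
  stopifnot(inherits(w, "response_window"), threshold > 0)
  v <- w$samples
  if (length(v) < 2) {
    stop_ctx("window of gesture %s for %s has %d sample(s); need >= 2",
             w$gesture_id, w$participant_id, length(v),
             class = "insufficient_data_error")
  }
  # max over i<j of v[j]-v[i] == max_j (v[j] - running min); floor at 0
  w$amplitude <- max(0, max(v - cummin(v)))
  w$specific <- w$amplitude > threshold
  w
}

#' @export
print.response_window <- function(x, ...) {
  cat(sprintf("<response_window> gesture %s / %s [%.2f, %.2f) n=%d amp=%s specific=%s%s\n",
              x$gesture_id, x$participant_id, x$window_start, x$window_end,
              length(x$samples),
              ifelse(is.na(x$amplitude), "?", sprintf("%.3f", x$amplitude)),
              ifelse(is.na(x$specific), "?", x$specific),
              if (isTRUE(x$truncated)) " (truncated)" else ""))
  invisible(x)
}

#' Detect cross-participant resonance for one gesture
#'
#' A gesture is *resonating* iff at least `min_specific` participants
#' (default 2) show a specific EDA response within the gesture's window --
#' i.e. concurrent stimulus-related arousal. The narrator's own window counts
#' toward the tally; set `require_narrator = TRUE` to additionally demand
#' that the narrator is among the responders.
#'
#' @param windows list of classified `response_window`s, one per participant,
#'   all for the same gesture
#' @param min_specific minimum number of specific responses for resonance
#' @param narrator_id narrator's participant id (needed if `require_narrator`)
#' @param require_narrator logical; must the narrator respond?
#' @return list with `gesture_id`, `n_specific` and binary `EDA_G_resonance`
#' @export
detect_resonance <- function(windows, min_specific = 2, narrator_id = NULL,
                             require_narrator = FALSE) {
  stopifnot(length(windows) >= 1, min_specific >= 1)
  gids <- unique(vapply(windows, `[[`, character(1), "gesture_id"))
  if (length(gids) != 1) {
    stop_ctx("windows belong to different gestures: %s",
             paste(gids, collapse = ", "), class = "validation_error")
  }
  spec <- vapply(windows, `[[`, logical(1), "specific")
  if (anyNA(spec)) {
    stop_ctx("unclassified window(s) for gesture %s; run classify_specific first",
             gids, class = "validation_error")
  }
  n_specific <- sum(spec)
  res <- n_specific >= min_specific
  if (require_narrator) {
    if (is.null(narrator_id)) {
      stop_ctx("require_narrator = TRUE needs narrator_id", class = "validation_error")
    }
    pid <- vapply(windows, `[[`, character(1), "participant_id")
    res <- res && any(spec[pid == narrator_id])
  }
  list(gesture_id = gids, n_specific = n_specific,
       EDA_G_resonance = as.integer(res))
}

#' Append EDA outcomes to a feature table
#'
#' For every gesture and every participant of the gesture's recording,
#' extracts the gesture-aligned window, classifies it, and tallies
#' resonance. Gestures whose window is not covered by some participant's
#' trace are dropped from the outcome table and reported in the exclusion
#' log, so every input gesture is accounted for exactly once.
#'
#' @param features feature table from [build_features()]
#' @param gestures gesture annotation data frame (`id`, `onset`, `offset`),
#'   supplying the spans of the gestures in `features`
#' @param traces named list of [eda_trace()] objects (names or
#'   `participant_id`s identify participants)
#' @param participants data frame (`id`, `recording_id`) mapping participants
#'   to recordings
#' @param threshold specific-response threshold, uS
#' @param latency_pad post-gesture window extension, seconds
#' @param min_specific resonance tally threshold (>= 2 in the standard rule)
#' @param require_narrator see [detect_resonance()]
#' @return list with `features` (input plus `EDA_specific_narrator`,
#'   `n_specific`, `EDA_G_resonance`), `responses` (long table: one row per
#'   gesture x participant with `specific`, `amplitude`, `role`), and
#'   `excluded` (gesture id + reason)
#' @export
add_eda_outcomes <- function(features, gestures, traces, participants,
                             threshold = 0.05, latency_pad = 1.5,
                             min_specific = 2, require_narrator = FALSE) {
  stopifnot(nrow(features) > 0)
  idx <- match(features$gesture_id, gestures$id)
  if (anyNA(idx)) {
    stop_ctx("feature rows reference unknown gesture(s): %s",
             paste(features$gesture_id[is.na(idx)], collapse = ", "),
             class = "validation_error")
  }
  g_on <- gestures$onset[idx]
  g_off <- gestures$offset[idx]
  trace_ids <- vapply(traces, `[[`, character(1), "participant_id")
  names(traces) <- trace_ids
  resp <- list()
  excl <- list()
  features$EDA_specific_narrator <- NA_integer_
  features$n_specific <- NA_integer_
  features$EDA_G_resonance <- NA_integer_
  for (k in seq_len(nrow(features))) {
    frow <- features[k, ]
    pids <- participants$id[participants$recording_id == frow$recording_id]
    if (!length(pids) || !all(pids %in% trace_ids)) {
      excl[[length(excl) + 1]] <- data.frame(
        gesture_id = frow$gesture_id, stage = "eda",
        reason = "missing trace for some participant")
      next
    }
    wins <- vector("list", length(pids))
    failed <- NULL
    for (i in seq_along(pids)) {
      w <- tryCatch(
        extract_window(frow$gesture_id, g_on[k], g_off[k],
                       traces[[pids[i]]], latency_pad = latency_pad),
        error = function(e) e)
      if (inherits(w, "error")) { failed <- conditionMessage(w); break }
      w <- tryCatch(classify_specific(w, threshold = threshold),
                    error = function(e) e)
      if (inherits(w, "error")) { failed <- conditionMessage(w); break }
      wins[[i]] <- w
    }
    if (!is.null(failed)) {
      excl[[length(excl) + 1]] <- data.frame(
        gesture_id = frow$gesture_id, stage = "eda", reason = failed)
      next
    }
    rr <- detect_resonance(wins, min_specific = min_specific,
                           narrator_id = frow$narrator_id,
                           require_narrator = require_narrator)
    features$n_specific[k] <- rr$n_specific
    features$EDA_G_resonance[k] <- rr$EDA_G_resonance
    nar <- which(pids == frow$narrator_id)
    features$EDA_specific_narrator[k] <-
      if (length(nar)) as.integer(wins[[nar[1]]]$specific) else NA_integer_
    resp[[length(resp) + 1]] <- data.frame(
      gesture_id = frow$gesture_id, story_id = frow$story_id,
      recording_id = frow$recording_id,
      participant_id = pids,
      role = ifelse(pids == frow$narrator_id, "narrator", "recipient"),
      specific = vapply(wins, function(w) as.integer(w$specific), integer(1)),
      amplitude = vapply(wins, `[[`, numeric(1), "amplitude"),
      truncated = vapply(wins, `[[`, logical(1), "truncated"),
      stringsAsFactors = FALSE)
  }
  list(
    features = features,
    responses = if (length(resp)) do.call(rbind, resp) else NULL,
    excluded = if (length(excl)) do.call(rbind, excl) else
      data.frame(gesture_id = character(), stage = character(),
                 reason = character()))
}
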
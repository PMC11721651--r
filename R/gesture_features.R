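#' Hold-phase indicator (HO)
#'
#' A gesture carries the HO feature iff any of its phase segments is labeled
#' `hold` -- a momentary cessation of movement, which raises visual attention
#' to the gesture.
#'
#' @param gesture_id gesture identifier
#' @param phases phase data frame (`gesture_id`, `phase`, `start`, `end`)
#' @return 1 or 0
#' @export
derive_ho <- function(gesture_id, phases) {
  seg <- phases[phases$gesture_id == gesture_id, , drop = FALSE]
  as.integer(any(seg$phase == "hold"))
}

#' Total nucleus duration of a gesture
#'
#' Sum of the durations of segments labeled `nucleus` (preparation, hold and
#' retraction excluded).
#'
#' @inheritParams derive_ho
#' @return duration in seconds
#' @export
nucleus_duration <- function(gesture_id, phases) {
  seg <- phases[phases$gesture_id == gesture_id & phases$phase == "nucleus", ,
                drop = FALSE]
  if (!nrow(seg)) {
    stop_ctx("gesture %s has no nucleus phase", gesture_id,
             class = "validation_error")
  }
  sum(seg$end - seg$start)
}

#' Nucleus-duration indicator (ND)
#'
#' ND is coded yes iff the gesture's total nucleus duration strictly exceeds
#' the arithmetic mean of total nucleus durations across all gestures of the
#' same story. In a single-gesture story ND is therefore always no.
#'
#' @param gesture_id gesture identifier
#' @param story_gesture_ids ids of all gestures of the story (must include
#'   `gesture_id`)
#' @param phases phase data frame
#' @return 1 or 0
#' @export
derive_nd <- function(gesture_id, story_gesture_ids, phases) {
  if (!length(story_gesture_ids)) {
    stop_ctx("story has no gestures", class = "validation_error")
  }
  if (!gesture_id %in% story_gesture_ids) {
    stop_ctx("gesture %s is not among its story's gestures", gesture_id,
             class = "validation_error")
  }
  durs <- vapply(story_gesture_ids, nucleus_duration, numeric(1), phases = phases)
  as.integer(durs[[match(gesture_id, story_gesture_ids)]] > mean(durs))
}

#' Gesture Expressivity Index
#'
#' The GEI of a gesture is the mean of its seven binary expressivity
#' parameters: Size (SZ), Force (FO), Character viewpoint (CV), Silent
#' gesture (SL), Hold phase (HO), Multiple articulators (MA) and Nucleus
#' duration (ND). Its range is exactly \{0/7, ..., 7/7\}; a missing coding is
#' an error (no imputation).
#'
#' @param SZ,FO,CV,SL,HO,MA,ND binary codings (0/1, `"yes"`/`"no"` or logical)
#' @return GEI in \[0, 1\] (vectorized over gestures)
#' @export
compute_gei <- function(SZ, FO, CV, SL, HO, MA, ND) {
  args <- list(SZ = SZ, FO = FO, CV = CV, SL = SL, HO = HO, MA = MA, ND = ND)
  n <- unique(lengths(args))
  if (length(n) != 1) {
    stop_ctx("the seven codings must have equal length", class = "validation_error")
  }
  if (any(vapply(args, function(a) any(is.na(a)), logical(1)))) {
    stop_ctx("missing GEI coding; all seven parameters are required",
             class = "validation_error")
  }
  b <- lapply(names(args), function(nm) as_binary(args[[nm]], nm))
  Reduce(`+`, b) / 7
}

#' Relative positions of a story's gestures
#'
#' Gestures sorted by onset receive equi-distanced positions in \[0, 1\]:
#' gesture i of n gets (i-1)/(n-1), so the first gesture sits at 0 and the
#' last at 1. A single-gesture story gets the midpoint 0.5.
#'
#' @param onsets gesture onsets in seconds, sorted non-decreasingly
#' @return numeric vector of relative positions
#' @export
relative_positions <- function(onsets) {
  n <- length(onsets)
  if (n < 1) stop_ctx("need at least one gesture", class = "validation_error")
  if (is.unsorted(onsets)) {
    stop_ctx("gesture onsets must be sorted", class = "validation_error")
  }
  if (n == 1) return(0.5)
  (seq_len(n) - 1) / (n - 1)
}

#' Co-quote indicator (G_quote)
#'
#' Fuzzy assignment of gestures to direct-speech quotes: a gesture is a
#' co-quote gesture iff some quote's start time lies within `tolerance`
#' seconds (absolute difference, default 1.5 s) of the gesture's onset.
#'
#' @param gesture_onset gesture onset, seconds
#' @param quote_starts quote start times of the same story, seconds
#' @param tolerance allowed |quote start - gesture onset| in seconds
#' @return 1 or 0
#' @export
assign_quote <- function(gesture_onset, quote_starts, tolerance = 1.5) {
  as.integer(length(quote_starts) > 0 &&
             any(abs(quote_starts - gesture_onset) <= tolerance))
}

ipu_mean_score <- function(ipu_row) {
  if (is.na(ipu_row$word_sentiments) || !nzchar(ipu_row$word_sentiments)) return(0)
  mean(as.numeric(strsplit(ipu_row$word_sentiments, " ", fixed = TRUE)[[1]]))
}

#' Sentiment of the speech co-occurring with a gesture
#'
#' Each IPU's sentiment is the mean of its word-level composite scores
#' (in \[-1, 1\]). A gesture is assigned the score of the IPU with maximal
#' temporal overlap with its span; ties go to the earlier IPU, and a gesture
#' overlapping no IPU gets the neutral 0.
#'
#' @param gesture_onset,gesture_offset gesture span, seconds
#' @param ipus IPU data frame (`start`, `end`, `word_sentiments`)
#' @return sentiment score in \[-1, 1\]
#' @export
assign_sentiment <- function(gesture_onset, gesture_offset, ipus) {
  if (is.null(ipus) || !nrow(ipus)) return(0)
  ov <- pmin(ipus$end, gesture_offset) - pmax(ipus$start, gesture_onset)
  ov[ov < 0] <- 0
  if (all(ov <= 0)) return(0)
  ord <- order(-ov, ipus$start)  # max overlap, earlier IPU on ties
  ipu_mean_score(ipus[ord[1], , drop = FALSE])
}

#' Build the per-gesture feature table
#'
#' Derives, for every gesture of every story, the seven GEI components (HO
#' and ND computed from the phase tier), the GEI, the relative story
#' position, the co-quote flag, the co-occurring speech sentiment, and the
#' story/recording covariates. `ID` is the participant-by-recording grouping
#' factor used as random effect in the crescendo model.
#'
#' @param ann validated annotation list (see [read_annotations()])
#' @param quote_tolerance fuzzy quote-assignment distance, seconds
#' @return data frame with columns [FEATURE_COLUMNS], one row per gesture,
#'   ordered by story and onset
#' @export
build_features <- function(ann, quote_tolerance = 1.5) {
  ann <- validate_annotations(ann)
  st <- ann$stories
  rec <- ann$recordings
  out <- vector("list", nrow(st))
  for (k in seq_len(nrow(st))) {
    srow <- st[k, ]
    g <- ann$gestures[ann$gestures$story_id == srow$id, , drop = FALSE]
    if (!nrow(g)) next
    g <- g[order(g$onset), , drop = FALSE]
    HO <- vapply(g$id, derive_ho, integer(1), phases = ann$phases)
    ND <- vapply(g$id, derive_nd, integer(1), story_gesture_ids = g$id,
                 phases = ann$phases)
    qs <- ann$quotes$start[ann$quotes$story_id == srow$id]
    ip <- ann$ipus[ann$ipus$story_id == srow$id, , drop = FALSE]
    gs <- gc <- NA
    if (!is.null(rec) && nrow(rec) && srow$recording_id %in% rec$id) {
      rrow <- rec[rec$id == srow$recording_id, ]
      gs <- rrow$group_size
      gc <- rrow$group_compose
    }
    out[[k]] <- data.frame(
      gesture_id = g$id, story_id = srow$id,
      recording_id = srow$recording_id, narrator_id = srow$narrator_id,
      ID = paste(srow$narrator_id, srow$recording_id, sep = ":"),
      SZ = g$SZ, FO = g$FO, CV = g$CV, SL = g$SL, HO = HO, MA = g$MA, ND = ND,
      G_expressivity = compute_gei(g$SZ, g$FO, g$CV, g$SL, HO, g$MA, ND),
      G_position_rel = relative_positions(g$onset),
      G_quote = vapply(g$onset, assign_quote, integer(1), quote_starts = qs,
                       tolerance = quote_tolerance),
      Sentiment = mapply(assign_sentiment, g$onset, g$offset,
                         MoreArgs = list(ipus = ip)),
      protagonist = srow$protagonist, recency = srow$recency,
      group_size = gs, group_compose = gc,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, FEATURE_COLUMNS]
}
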
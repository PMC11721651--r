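#' Construct an EDA trace
#'
#' One participant's uniformly sampled skin-conductance series, in
#' microsiemens. Empatica-style wrist recordings sample at 4 Hz within a
#' hardware range of 0.01--100 uS; values outside that range are rejected.
#'
#' @param participant_id participant identifier
#' @param values numeric vector of conductance samples (uS), length >= 2
#' @param sampling_rate sampling frequency in Hz (default 4)
#' @param t0 time of the first sample, seconds on the recording clock
#' @return object of class `eda_trace`
#' @export
eda_trace <- function(participant_id, values, sampling_rate = 4, t0 = 0) {
  if (!is.numeric(values) || anyNA(values)) {
    stop_ctx("EDA values must be numeric and non-missing", class = "parse_error")
  }
  if (length(values) < 2) {
    stop_ctx("EDA trace for %s needs at least 2 samples", participant_id,
             class = "validation_error")
  }
  bad <- which(values < 0.01 | values > 100)
  if (length(bad)) {
    stop_ctx("EDA value %.4g at sample index %d of %s outside [0.01, 100] uS",
             values[bad[1]], bad[1], participant_id, class = "range_error")
  }
  stopifnot(sampling_rate > 0)
  structure(
    list(participant_id = as.character(participant_id),
         sampling_rate = as.numeric(sampling_rate),
         t0 = as.numeric(t0),
         values = as.numeric(values)),
    class = "eda_trace")
}

#' Sample timestamps of an EDA trace
#' @param trace an [eda_trace()]
#' @return numeric vector of times in seconds
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$values) - 1) / trace$sampling_rate
}

# half-open end of the sampled span
trace_end <- function(trace) {
  trace$t0 + length(trace$values) / trace$sampling_rate
}

#' @export
print.eda_trace <- function(x, ...) {
  cat(sprintf("<eda_trace> %s: %d samples @ %g Hz from t=%.2fs (%.1f s)\n",
              x$participant_id, length(x$values), x$sampling_rate, x$t0,
              length(x$values) / x$sampling_rate))
  invisible(x)
}

#' Read an EDA trace from CSV
#'
#' Expected columns: `participant`, `t0` (seconds), `rate` (Hz) -- constant
#' per file -- and `eda` with one conductance sample (uS) per row.
#'
#' @param path CSV file path
#' @return an [eda_trace()]
#' @export
read_eda <- function(path) {
  if (!file.exists(path)) stop_ctx("no such file: %s", path, class = "io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_cols(df, c("participant", "t0", "rate", "eda"), basename(path))
  if (!is.numeric(df$eda)) {
    stop_ctx("non-numeric EDA value in %s", path, class = "parse_error")
  }
  eda_trace(df$participant[1], df$eda, sampling_rate = df$rate[1], t0 = df$t0[1])
}

#' Write an EDA trace to CSV
#' @param trace an [eda_trace()]
#' @param path output CSV path
#' @export
write_eda <- function(trace, path) {
  stopifnot(inherits(trace, "eda_trace"))
  df <- data.frame(participant = trace$participant_id, t0 = trace$t0,
                   rate = trace$sampling_rate, eda = trace$values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Annotation tiers
# ---------------------------------------------------------------------------

ANNOTATION_TABLES <- c("recordings", "participants", "stories", "gestures",
                       "phases", "ipus", "quotes")
PHASE_LABELS <- c("preparation", "nucleus", "hold", "retraction")
CODED_PARAMS <- c("SZ", "FO", "CV", "SL", "MA")

#' Validate a set of annotation tables
#'
#' Checks the structural invariants of the corpus: story time ordering
#' (onset < climax onset <= climax offset <= offset), non-overlapping gesture
#' phases contained in the gesture span with at least one nucleus, binary
#' codings, IPU word/sentiment alignment, and referential integrity
#' (gesture -> story -> recording, quotes/IPUs -> story).
#'
#' @param ann a list of annotation data frames as returned by
#'   [read_annotations()]
#' @return `ann`, invisibly, if valid; otherwise an error naming the object
#' @export
validate_annotations <- function(ann) {
  st <- ann$stories
  assert_cols(st, c("id", "recording_id", "narrator_id", "onset", "offset",
                    "climax_onset", "climax_offset", "protagonist", "recency"),
              "stories")
  if (anyDuplicated(st$id)) {
    stop_ctx("duplicate story id(s): %s",
             paste(unique(st$id[duplicated(st$id)]), collapse = ", "),
             class = "validation_error")
  }
  bad <- which(!(st$onset < st$climax_onset &
                 st$climax_onset <= st$climax_offset &
                 st$climax_offset <= st$offset))
  if (length(bad)) {
    stop_ctx("story %s violates onset < climax_onset <= climax_offset <= offset",
             st$id[bad[1]], class = "validation_error")
  }

  g <- ann$gestures
  assert_cols(g, c("id", "story_id", "onset", "offset", CODED_PARAMS), "gestures")
  if (anyDuplicated(g$id)) {
    stop_ctx("duplicate gesture id(s): %s",
             paste(unique(g$id[duplicated(g$id)]), collapse = ", "),
             class = "validation_error")
  }
  for (p in CODED_PARAMS) g[[p]] <- as_binary(g[[p]], sprintf("gesture coding %s", p))
  orphan <- setdiff(g$story_id, st$id)
  if (length(orphan)) {
    stop_ctx("gesture(s) reference unknown story: %s",
             paste(orphan, collapse = ", "), class = "validation_error")
  }

  ph <- ann$phases
  assert_cols(ph, c("gesture_id", "phase", "start", "end"), "phases")
  if (!all(ph$phase %in% PHASE_LABELS)) {
    stop_ctx("unknown phase label(s): %s",
             paste(setdiff(unique(ph$phase), PHASE_LABELS), collapse = ", "),
             class = "validation_error")
  }
  tol <- 1e-6
  for (gid in unique(g$id)) {
    seg <- ph[ph$gesture_id == gid, , drop = FALSE]
    if (!any(seg$phase == "nucleus")) {
      stop_ctx("gesture %s has no nucleus phase", gid, class = "validation_error")
    }
    grow <- g[g$id == gid, ]
    if (any(seg$start < grow$onset - tol) || any(seg$end > grow$offset + tol)) {
      stop_ctx("phase segment outside gesture span for gesture %s", gid,
               class = "validation_error")
    }
    seg <- seg[order(seg$start), , drop = FALSE]
    if (nrow(seg) > 1 && any(seg$start[-1] < seg$end[-nrow(seg)] - tol)) {
      stop_ctx("overlapping phase segments in gesture %s", gid,
               class = "validation_error")
    }
  }

  ip <- ann$ipus
  assert_cols(ip, c("id", "story_id", "start", "end", "words", "word_sentiments"),
              "ipus")
  if (nrow(ip)) {
    if (any(ip$start >= ip$end)) {
      stop_ctx("IPU with start >= end: %s", ip$id[which(ip$start >= ip$end)[1]],
               class = "validation_error")
    }
    nw <- lengths(strsplit(ifelse(ip$words == "", NA, ip$words), " ", fixed = TRUE))
    ns <- lengths(strsplit(ifelse(ip$word_sentiments == "", NA, ip$word_sentiments),
                           " ", fixed = TRUE))
    nw[is.na(nw)] <- 0; ns[is.na(ns)] <- 0
    if (any(nw != ns)) {
      stop_ctx("IPU %s has %d words but %d sentiment scores",
               ip$id[which(nw != ns)[1]], nw[which(nw != ns)[1]],
               ns[which(nw != ns)[1]], class = "validation_error")
    }
  }

  qu <- ann$quotes
  assert_cols(qu, c("story_id", "start", "end"), "quotes")
  if (nrow(qu) && any(qu$start >= qu$end)) {
    stop_ctx("quote with start >= end in story %s",
             qu$story_id[which(qu$start >= qu$end)[1]], class = "validation_error")
  }

  if (!is.null(ann$recordings) && nrow(ann$recordings)) {
    rec <- ann$recordings
    assert_cols(rec, c("id", "group_size", "group_compose"), "recordings")
    orphan <- setdiff(st$recording_id, rec$id)
    if (length(orphan)) {
      stop_ctx("story references unknown recording: %s",
               paste(orphan, collapse = ", "), class = "validation_error")
    }
    if (!is.null(ann$participants) && nrow(ann$participants)) {
      pp <- ann$participants
      assert_cols(pp, c("id", "recording_id", "sex"), "participants")
      for (rid in rec$id) {
        n <- sum(pp$recording_id == rid)
        gs <- rec$group_size[rec$id == rid]
        if (n != gs) {
          stop_ctx("recording %s declares group_size %d but has %d participants",
                   rid, gs, n, class = "validation_error")
        }
      }
      # a sex label of diverse/NA is admitted; it maps the composition to mixed
      comp <- vapply(rec$id, function(rid) {
        sx <- tolower(pp$sex[pp$recording_id == rid])
        if (all(sx == "female")) "all-female"
        else if (all(sx == "male")) "all-male" else "mixed"
      }, character(1))
      mism <- which(comp != rec$group_compose)
      if (length(mism)) {
        stop_ctx("recording %s: group_compose '%s' inconsistent with participant sexes",
                 rec$id[mism[1]], rec$group_compose[mism[1]],
                 class = "validation_error")
      }
    }
  }
  ann$gestures <- g
  invisible(ann)
}

empty_annotations <- function() {
  list(
    recordings = data.frame(id = character(), group_size = integer(),
                            group_compose = character(), duration = numeric()),
    participants = data.frame(id = character(), recording_id = character(),
                              sex = character()),
    stories = data.frame(id = character(), recording_id = character(),
                         narrator_id = character(), onset = numeric(),
                         offset = numeric(), climax_onset = numeric(),
                         climax_offset = numeric(), protagonist = character(),
                         recency = character()),
    gestures = data.frame(id = character(), story_id = character(),
                          onset = numeric(), offset = numeric(),
                          SZ = integer(), FO = integer(), CV = integer(),
                          SL = integer(), MA = integer(),
                          description = character()),
    phases = data.frame(gesture_id = character(), phase = character(),
                        start = numeric(), end = numeric()),
    ipus = data.frame(id = character(), story_id = character(),
                      start = numeric(), end = numeric(), words = character(),
                      word_sentiments = character()),
    quotes = data.frame(story_id = character(), start = numeric(),
                        end = numeric())
  )
}

MS_COLS <- list(
  recordings = "duration", stories = c("onset", "offset", "climax_onset",
                                       "climax_offset"),
  gestures = c("onset", "offset"), phases = c("start", "end"),
  ipus = c("start", "end"), quotes = c("start", "end"))

#' Read multi-tier annotations
#'
#' Two dialects are supported, both carrying times in *milliseconds* which
#' are converted to seconds on load.
#'
#' `tabular`: `path` is a directory of per-tier CSVs (`stories.csv`,
#' `gestures.csv`, `phases.csv`, `ipus.csv`, `quotes.csv`, optionally
#' `recordings.csv` and `participants.csv`). Time columns carry an `_ms`
#' suffix; gesture codings are `yes`/`no`; IPU `words` and `word_sentiments`
#' are space-separated lists.
#'
#' `eaf`: `path` is an ELAN EAF (XML) file following a documented tier
#' convention: alignable annotations on tiers `GE_STORY`
#' (value `id;narrator_id;climax_onset_ms;climax_offset_ms;protagonist;recency`),
#' `GE_GESTURE` (`id;story_id;SZ;FO;CV;SL;MA;description`), `GE_PHASE`
#' (`gesture_id;label`), `GE_IPU` (`id;story_id;words;scores`) and `GE_QUOTE`
#' (`story_id`), with boundaries taken from the EAF time order (ms).
#'
#' @param path directory (tabular) or EAF file
#' @param dialect `"tabular"` or `"eaf"`
#' @return validated list of annotation data frames (times in seconds):
#'   `recordings`, `participants`, `stories`, `gestures`, `phases`, `ipus`,
#'   `quotes`
#' @export
read_annotations <- function(path, dialect = c("tabular", "eaf")) {
  dialect <- match.arg(dialect)
  ann <- if (dialect == "tabular") read_annotations_tabular(path)
         else read_annotations_eaf(path)
  validate_annotations(ann)
}

read_annotations_tabular <- function(path) {
  if (!dir.exists(path)) stop_ctx("no such directory: %s", path, class = "io_error")
  ann <- empty_annotations()
  for (tab in ANNOTATION_TABLES) {
    f <- file.path(path, paste0(tab, ".csv"))
    if (!file.exists(f)) {
      if (tab %in% c("recordings", "participants")) next
      stop_ctx("missing tier file %s", f, class = "parse_error")
    }
    df <- utils::read.csv(f, stringsAsFactors = FALSE)
    for (cc in intersect(c("words", "word_sentiments", "description"), names(df))) {
      df[[cc]] <- as.character(df[[cc]])
      df[[cc]][is.na(df[[cc]])] <- ""
    }
    for (col in MS_COLS[[tab]] %||% character()) {
      mscol <- paste0(col, "_ms")
      if (!mscol %in% names(df)) {
        stop_ctx("tier %s lacks column %s", tab, mscol, class = "parse_error")
      }
      df[[col]] <- df[[mscol]] / 1000
      df[[mscol]] <- NULL
    }
    if (tab == "gestures" && !"description" %in% names(df)) df$description <- ""
    if (tab == "gestures") {
      for (p in CODED_PARAMS) {
        if (!p %in% names(df)) {
          stop_ctx("tier gestures lacks coding column %s", p, class = "parse_error")
        }
        df[[p]] <- as_binary(df[[p]], sprintf("gesture coding %s", p))
      }
    }
    canon <- names(empty_annotations()[[tab]])  # stable column order
    df <- df[, c(intersect(canon, names(df)), setdiff(names(df), canon)),
             drop = FALSE]
    ann[[tab]] <- df
  }
  ann
}

#' Write annotations in the tabular dialect
#'
#' Inverse of [read_annotations()] for `dialect = "tabular"`; seconds are
#' serialized back to integer milliseconds so a read/write round trip
#' preserves boundaries exactly at ms resolution.
#'
#' @param ann annotation list (times in seconds)
#' @param path output directory (created if needed)
#' @export
write_annotations <- function(ann, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (tab in ANNOTATION_TABLES) {
    df <- ann[[tab]]
    if (is.null(df)) next
    for (col in MS_COLS[[tab]] %||% character()) {
      df[[paste0(col, "_ms")]] <- as.integer(round(df[[col]] * 1000))
      df[[col]] <- NULL
    }
    if (tab == "gestures") {
      for (p in CODED_PARAMS) df[[p]] <- ifelse(df[[p]] == 1, "yes", "no")
    }
    utils::write.csv(df, file.path(path, paste0(tab, ".csv")), row.names = FALSE)
  }
  invisible(path)
}

# -- EAF dialect ------------------------------------------------------------

eaf_tier_rows <- function(doc, tier_id, slots) {
  ns <- xml2::xml_find_all(
    doc, sprintf(".//TIER[@TIER_ID='%s']//ALIGNABLE_ANNOTATION", tier_id))
  if (!length(ns)) return(NULL)
  t1 <- slots[xml2::xml_attr(ns, "TIME_SLOT_REF1")]
  t2 <- slots[xml2::xml_attr(ns, "TIME_SLOT_REF2")]
  if (anyNA(t1) || anyNA(t2)) {
    stop_ctx("tier %s references undefined time slots", tier_id,
             class = "parse_error")
  }
  val <- vapply(ns, function(n)
    xml2::xml_text(xml2::xml_find_first(n, ".//ANNOTATION_VALUE")), character(1))
  data.frame(start = unname(t1) / 1000, end = unname(t2) / 1000, value = val,
             stringsAsFactors = FALSE)
}

split_fields <- function(x, n, tier) {
  parts <- strsplit(x, ";", fixed = TRUE)
  bad <- which(lengths(parts) != n)
  if (length(bad)) {
    stop_ctx("tier %s: annotation '%s' does not have %d ;-separated fields",
             tier, x[bad[1]], n, class = "parse_error")
  }
  as.data.frame(matrix(unlist(parts), ncol = n, byrow = TRUE),
                stringsAsFactors = FALSE)
}

read_annotations_eaf <- function(path) {
  if (!file.exists(path)) stop_ctx("no such file: %s", path, class = "io_error")
  doc <- xml2::read_xml(path)
  ts <- xml2::xml_find_all(doc, ".//TIME_ORDER/TIME_SLOT")
  slots <- as.numeric(xml2::xml_attr(ts, "TIME_VALUE"))
  names(slots) <- xml2::xml_attr(ts, "TIME_SLOT_ID")

  ann <- empty_annotations()
  st <- eaf_tier_rows(doc, "GE_STORY", slots)
  if (is.null(st)) stop_ctx("EAF lacks required tier GE_STORY", class = "parse_error")
  f <- split_fields(st$value, 6, "GE_STORY")
  ann$stories <- data.frame(
    id = f[[1]], recording_id = "eaf", narrator_id = f[[2]],
    onset = st$start, offset = st$end,
    climax_onset = as.numeric(f[[3]]) / 1000,
    climax_offset = as.numeric(f[[4]]) / 1000,
    protagonist = f[[5]], recency = f[[6]], stringsAsFactors = FALSE)

  ge <- eaf_tier_rows(doc, "GE_GESTURE", slots)
  if (!is.null(ge)) {
    f <- split_fields(ge$value, 8, "GE_GESTURE")
    ann$gestures <- data.frame(
      id = f[[1]], story_id = f[[2]], onset = ge$start, offset = ge$end,
      SZ = as_binary(f[[3]], "SZ"), FO = as_binary(f[[4]], "FO"),
      CV = as_binary(f[[5]], "CV"), SL = as_binary(f[[6]], "SL"),
      MA = as_binary(f[[7]], "MA"), description = f[[8]],
      stringsAsFactors = FALSE)
  }
  phx <- eaf_tier_rows(doc, "GE_PHASE", slots)
  if (!is.null(phx)) {
    f <- split_fields(phx$value, 2, "GE_PHASE")
    ann$phases <- data.frame(gesture_id = f[[1]], phase = f[[2]],
                             start = phx$start, end = phx$end,
                             stringsAsFactors = FALSE)
  }
  ipx <- eaf_tier_rows(doc, "GE_IPU", slots)
  if (!is.null(ipx)) {
    f <- split_fields(ipx$value, 4, "GE_IPU")
    ann$ipus <- data.frame(id = f[[1]], story_id = f[[2]], start = ipx$start,
                           end = ipx$end, words = f[[3]],
                           word_sentiments = f[[4]], stringsAsFactors = FALSE)
  }
  qx <- eaf_tier_rows(doc, "GE_QUOTE", slots)
  if (!is.null(qx)) {
    ann$quotes <- data.frame(story_id = qx$value, start = qx$start,
                             end = qx$end, stringsAsFactors = FALSE)
  }
  ann$recordings <- NULL
  ann$participants <- NULL
  ann
}

# ---------------------------------------------------------------------------
# Feature table I/O
# ---------------------------------------------------------------------------

#' Stable column order of the per-gesture feature table
#' @export
FEATURE_COLUMNS <- c(
  "gesture_id", "story_id", "recording_id", "narrator_id", "ID",
  "SZ", "FO", "CV", "SL", "HO", "MA", "ND",
  "G_expressivity", "G_position_rel", "G_quote", "Sentiment",
  "protagonist", "recency", "group_size", "group_compose")

OUTCOME_COLUMNS <- c("EDA_specific_narrator", "n_specific", "EDA_G_resonance")

#' Write the per-gesture feature table to CSV
#'
#' Columns are emitted in the documented stable order ([FEATURE_COLUMNS],
#' then any EDA outcome columns present). Round-trips losslessly through
#' [read_feature_table()].
#'
#' @param records feature data frame (one row per gesture)
#' @param path output CSV path
#' @export
write_feature_table <- function(records, path) {
  if (is.null(records) || !nrow(records)) {
    stop_ctx("refusing to write an empty feature table", class = "validation_error")
  }
  if (anyDuplicated(records$gesture_id)) {
    stop_ctx("duplicate gesture id(s) in feature table: %s",
             paste(unique(records$gesture_id[duplicated(records$gesture_id)]),
                   collapse = ", "), class = "validation_error")
  }
  assert_cols(records, FEATURE_COLUMNS, "feature table")
  cols <- c(FEATURE_COLUMNS, intersect(OUTCOME_COLUMNS, names(records)))
  utils::write.csv(records[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path
#' @return feature data frame
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_cols(df, FEATURE_COLUMNS, "feature table")
  df
}
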
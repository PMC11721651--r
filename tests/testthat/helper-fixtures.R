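# Fixtures are built in code; no binary files.

# A response window over given raw sample values (4 Hz, starting at t = 0);
# the gesture span is chosen so the window covers exactly those samples.
window_from_values <- function(values, rate = 4) {
  trace <- eda_trace("p", values, sampling_rate = rate, t0 = 0)
  extract_window("g", 0, length(values) / rate, trace, latency_pad = 0)
}

# brute-force trough-to-peak amplitude: max over ordered pairs i < j
brute_force_amplitude <- function(v) {
  m <- 0
  n <- length(v)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) m <- max(m, v[j] - v[i])
  }
  max(0, m)
}

# compact phase-table builder: segs is a list of c(label, start, end)
make_phases <- function(gesture_id, segs) {
  do.call(rbind, lapply(segs, function(s) {
    data.frame(gesture_id = gesture_id, phase = s[[1]],
               start = as.numeric(s[[2]]), end = as.numeric(s[[3]]),
               stringsAsFactors = FALSE)
  }))
}

# minimal in-memory annotation set: one dyadic recording, one story with
# three gestures of known timing/codings, IPUs and one quote
make_tiny_ann <- function() {
  ann <- list(
    recordings = data.frame(id = "r1", group_size = 2L,
                            group_compose = "mixed", duration = 120,
                            stringsAsFactors = FALSE),
    participants = data.frame(id = c("p1", "p2"), recording_id = "r1",
                              sex = c("female", "male"),
                              stringsAsFactors = FALSE),
    stories = data.frame(id = "s1", recording_id = "r1", narrator_id = "p1",
                         onset = 0, offset = 60, climax_onset = 40,
                         climax_offset = 60, protagonist = "narrator",
                         recency = "recent", stringsAsFactors = FALSE),
    gestures = data.frame(
      id = c("g1", "g2", "g3"), story_id = "s1",
      onset = c(5, 20, 42), offset = c(8, 24, 47),
      SZ = c(1L, 0L, 1L), FO = c(0L, 0L, 1L), CV = c(0L, 0L, 1L),
      SL = c(0L, 0L, 0L), MA = c(0L, 1L, 0L), description = "",
      stringsAsFactors = FALSE),
    phases = rbind(
      make_phases("g1", list(list("preparation", 5, 5.5),
                             list("nucleus", 5.5, 7),
                             list("retraction", 7, 8))),
      make_phases("g2", list(list("preparation", 20, 20.5),
                             list("nucleus", 20.5, 21.5),
                             list("hold", 21.5, 23),
                             list("retraction", 23, 24))),
      make_phases("g3", list(list("preparation", 42, 42.5),
                             list("nucleus", 42.5, 46),
                             list("retraction", 46, 47)))),
    ipus = data.frame(
      id = c("i1", "i2"), story_id = "s1", start = c(4, 41), end = c(9, 48),
      words = c("good bad ok", "wow"),
      word_sentiments = c("0.5 -0.1 0.2", "0.9"), stringsAsFactors = FALSE),
    quotes = data.frame(story_id = "s1", start = 42.4, end = 44,
                        stringsAsFactors = FALSE))
  ann
}

# hand-built EAF fixture: 1 story, 2 gestures with phases, 1 IPU, 1 quote
write_eaf_fixture <- function(path, include_gestures = TRUE) {
  slot <- function(id, ms) sprintf('<TIME_SLOT TIME_SLOT_ID="%s" TIME_VALUE="%d"/>', id, ms)
  alig <- function(aid, t1, t2, value) {
    sprintf(paste0('<ANNOTATION><ALIGNABLE_ANNOTATION ANNOTATION_ID="%s" ',
                   'TIME_SLOT_REF1="%s" TIME_SLOT_REF2="%s">',
                   '<ANNOTATION_VALUE>%s</ANNOTATION_VALUE>',
                   '</ALIGNABLE_ANNOTATION></ANNOTATION>'), aid, t1, t2, value)
  }
  slots <- c(ts1 = 1000L, ts2 = 12000L,    # story
             ts3 = 2000L, ts4 = 4000L,     # g1
             ts5 = 8200L, ts6 = 10700L,    # g2
             ts7 = 2000L, ts8 = 2500L, ts9 = 2500L, ts10 = 3500L,
             ts11 = 3500L, ts12 = 4000L,   # g1 phases
             ts13 = 8200L, ts14 = 8600L, ts15 = 8600L, ts16 = 9800L,
             ts17 = 9800L, ts18 = 10200L, ts19 = 10200L, ts20 = 10700L,
             ts21 = 1000L, ts22 = 5000L,   # ipu
             ts23 = 8300L, ts24 = 9000L)   # quote
  xml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<ANNOTATION_DOCUMENT AUTHOR="" DATE="2024-01-01T00:00:00Z" FORMAT="3.0" VERSION="3.0">',
    '<HEADER MEDIA_FILE="" TIME_UNITS="milliseconds"/>',
    '<TIME_ORDER>',
    mapply(slot, names(slots), slots),
    '</TIME_ORDER>',
    '<TIER LINGUISTIC_TYPE_REF="default" TIER_ID="GE_STORY">',
    alig("a1", "ts1", "ts2", "s1;p1;8000;12000;narrator;recent"),
    '</TIER>',
    if (include_gestures) c(
      '<TIER LINGUISTIC_TYPE_REF="default" TIER_ID="GE_GESTURE">',
      alig("a2", "ts3", "ts4", "g1;s1;yes;no;no;no;no;right hand sweep"),
      alig("a3", "ts5", "ts6", "g2;s1;no;no;yes;no;no;character X"),
      '</TIER>',
      '<TIER LINGUISTIC_TYPE_REF="default" TIER_ID="GE_PHASE">',
      alig("a4", "ts7", "ts8", "g1;preparation"),
      alig("a5", "ts9", "ts10", "g1;nucleus"),
      alig("a6", "ts11", "ts12", "g1;retraction"),
      alig("a7", "ts13", "ts14", "g2;preparation"),
      alig("a8", "ts15", "ts16", "g2;nucleus"),
      alig("a9", "ts17", "ts18", "g2;hold"),
      alig("a10", "ts19", "ts20", "g2;retraction"),
      '</TIER>'),
    '<TIER LINGUISTIC_TYPE_REF="default" TIER_ID="GE_IPU">',
    alig("a11", "ts21", "ts22", "i1;s1;good bad ok;0.5 -0.1 0.2"),
    '</TIER>',
    '<TIER LINGUISTIC_TYPE_REF="default" TIER_ID="GE_QUOTE">',
    alig("a12", "ts23", "ts24", "s1"),
    '</TIER>',
    '</ANNOTATION_DOCUMENT>')
  writeLines(unlist(xml), path)
  path
}

# simulate a corpus and assemble the analysis tables in one go
sim_analysis_tables <- function(cfg, ...) {
  sim <- simulate_corpus(cfg)
  f <- build_features(sim$ann)
  eda <- add_eda_outcomes(f, sim$ann$gestures, sim$traces,
                          sim$ann$participants, ...)
  rq2 <- merge(eda$responses,
               eda$features[, c("gesture_id", "G_expressivity")],
               by = "gesture_id")
  list(sim = sim, features = eda$features, responses = eda$responses,
       rq2_records = rq2, excluded = eda$excluded)
}
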
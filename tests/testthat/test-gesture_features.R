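test_that("hold-phase indicator reads the phase tier", {
  ph <- rbind(
    make_phases("a", list(list("preparation", 0, 1), list("nucleus", 1, 2),
                          list("retraction", 2, 3))),
    make_phases("b", list(list("nucleus", 0, 1), list("hold", 1, 2))),
    make_phases("c", list(list("nucleus", 0, 1), list("hold", 1, 2),
                          list("hold", 2.5, 3))))
  expect_equal(derive_ho("a", ph), 0L)
  expect_equal(derive_ho("b", ph), 1L)
  expect_equal(derive_ho("c", ph), 1L)  # idempotent over repeated holds
})

test_that("nucleus-duration indicator uses a strict story-mean comparison", {
  ph <- rbind(
    make_phases("a", list(list("nucleus", 0, 1))),
    make_phases("b", list(list("nucleus", 10, 11))),
    make_phases("c", list(list("nucleus", 20, 24))))
  ids <- c("a", "b", "c")  # durations 1, 1, 4; mean 2
  expect_equal(vapply(ids, derive_nd, integer(1), story_gesture_ids = ids,
                      phases = ph), c(a = 0L, b = 0L, c = 1L))
  # all equal -> strictly greater never holds
  ph_eq <- rbind(make_phases("a", list(list("nucleus", 0, 2))),
                 make_phases("b", list(list("nucleus", 5, 7))))
  expect_equal(derive_nd("a", c("a", "b"), ph_eq), 0L)
  expect_equal(derive_nd("b", c("a", "b"), ph_eq), 0L)
  # single-gesture story cannot exceed its own mean
  expect_equal(derive_nd("a", "a", ph_eq), 0L)
  # split nuclei are summed
  ph_split <- rbind(make_phases("a", list(list("nucleus", 0, 1),
                                          list("nucleus", 2, 4))),
                    make_phases("b", list(list("nucleus", 5, 6))))
  expect_equal(derive_nd("a", c("a", "b"), ph_split), 1L)
  expect_error(derive_nd("z", character(0), ph_eq), class = "validation_error")
})

test_that("GEI is the exact mean of the seven binaries", {
  expect_equal(compute_gei(0, 0, 0, 0, 0, 0, 0), 0)
  expect_equal(compute_gei(1, 1, 1, 1, 1, 1, 1), 1)
  # printed observed median (two features) and maximum (six features)
  expect_equal(round_half_up(compute_gei(1, 1, 0, 0, 0, 0, 0), 3), 0.286)
  expect_equal(round_half_up(compute_gei(1, 1, 1, 1, 1, 1, 0), 3), 0.857)
  expect_equal(compute_gei("yes", "no", "no", "no", "no", "no", "no"), 1 / 7)
  expect_error(compute_gei(1, 1, NA, 0, 0, 0, 0), class = "validation_error")
})

test_that("GEI is permutation-invariant with range {0/7..7/7}", {
  set.seed(42)
  for (k in 1:25) {
    bits <- sample(0:1, 7, replace = TRUE)
    g <- do.call(compute_gei, as.list(bits))
    expect_equal(g, sum(bits) / 7)
    perm <- sample(bits)
    expect_equal(do.call(compute_gei, as.list(perm)), sum(bits) / 7)
    expect_true(g %in% ((0:7) / 7))
  }
})

test_that("relative positions are equi-distanced from 0 to 1", {
  expect_equal(relative_positions(c(1, 4, 9, 12, 30)), c(0, .25, .5, .75, 1))
  expect_equal(relative_positions(c(0, 10)), c(0, 1))
  expect_equal(relative_positions(c(2, 3, 8, 9)), c(0, 1 / 3, 2 / 3, 1))
  expect_equal(relative_positions(5), 0.5)
  expect_error(relative_positions(c(3, 1)), class = "validation_error")
})

test_that("relative positions are invariant under uniform time shifts", {
  set.seed(7)
  for (k in 1:10) {
    on <- sort(runif(sample(2:20, 1), 0, 100))
    expect_equal(relative_positions(on), relative_positions(on + runif(1, -50, 50)))
  }
})

test_that("co-quote assignment uses the symmetric 1.5 s fuzzy rule", {
  expect_equal(assign_quote(10, 10), 1L)          # exact co-onset
  expect_equal(assign_quote(10, 8.6), 1L)         # 1.4 s before
  expect_equal(assign_quote(10, 12.0), 0L)        # 2.0 s after
  expect_equal(assign_quote(10, c(20, 11.5)), 1L) # boundary inclusive
  expect_equal(assign_quote(10, numeric(0)), 0L)
})

test_that("sentiment comes from the maximally overlapping IPU", {
  ipus <- data.frame(
    id = c("i1", "i2"), story_id = "s", start = c(0, 4), end = c(5, 10),
    words = c("a b c", "d"), word_sentiments = c("0.5 -0.1 0.2", "-0.8"),
    stringsAsFactors = FALSE)
  expect_equal(assign_sentiment(1, 3, ipus), 0.2)    # fully inside i1
  expect_equal(assign_sentiment(3.9, 9, ipus), -0.8) # mostly i2
  expect_equal(assign_sentiment(20, 22, ipus), 0)    # silent gesture fallback
  # 80/20 overlap picks the 80% IPU
  expect_equal(assign_sentiment(0, 5 + 1.25, ipus), 0.2)
})

test_that("feature table assembles GEI, position, quote and sentiment", {
  ann <- make_tiny_ann()
  f <- build_features(ann)
  expect_equal(f$gesture_id, c("g1", "g2", "g3"))
  expect_equal(f$HO, c(0L, 1L, 0L))
  # nucleus durations 1.5, 1, 3.5 -> mean 2 -> only g3 exceeds it
  expect_equal(f$ND, c(0L, 0L, 1L))
  expect_equal(f$G_expressivity, c(1 / 7, 2 / 7, 4 / 7))
  expect_equal(f$G_position_rel, c(0, 0.5, 1))
  expect_equal(f$G_quote, c(0L, 0L, 1L))  # quote at 42.4, g3 onset 42
  expect_equal(f$Sentiment, c(0.2, 0, 0.9))
  expect_equal(f$group_size, rep(2L, 3))
  expect_equal(names(f), FEATURE_COLUMNS)
})

test_that("expressivity correlates positively with position under a crescendo", {
  signs <- vapply(1:5, function(s) {
    sim <- simulate_corpus(sim_config(
      n_recordings = 1, stories_per_recording = 4,
      gestures_per_story = c(10, 25), crescendo_slope = 2, seed = 100 + s))
    f <- build_features(sim$ann)
    sign(cor(f$G_position_rel, f$G_expressivity))
  }, numeric(1))
  expect_true(all(signs > 0))
})
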
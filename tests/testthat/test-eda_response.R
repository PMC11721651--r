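test_that("windows are half-open [onset, offset + pad) in trace time", {
  trace <- eda_trace("p1", rep(2, 40), sampling_rate = 4, t0 = 0)
  w <- extract_window("g", 2.0, 3.0, trace)
  # t in [2.0, 4.5) at 4 Hz: 2.00, 2.25, ..., 4.25 -> 10 samples
  expect_length(w$samples, 10)
  expect_equal(w$times[1], 2.0)
  expect_equal(w$times[10], 4.25)
  expect_false(w$truncated)
})

test_that("truncated and uncovered windows are flagged or rejected", {
  trace <- eda_trace("p1", rep(2, 40), sampling_rate = 4, t0 = 0)  # spans 10 s
  w <- extract_window("g", 8.0, 9.0, trace)  # window end 10.5 > 10
  expect_true(w$truncated)
  expect_error(extract_window("g", 12, 13, trace), "not covered",
               class = "coverage_error")
})

test_that("amplitude is the maximal trough-to-peak rise, threshold strict", {
  expect_equal(classify_specific(window_from_values(rep(2, 12)))$amplitude, 0)
  expect_false(classify_specific(window_from_values(rep(2, 12)))$specific)
  w <- classify_specific(window_from_values(c(0.32, 0.30, 0.33, 0.37, 0.35)))
  expect_equal(w$amplitude, 0.07)
  expect_true(w$specific)
  # a rise of exactly 0.05 is NOT specific ("larger than")
  w2 <- classify_specific(window_from_values(c(0.30, 0.33, 0.35)))
  expect_equal(w2$amplitude, 0.05)
  expect_false(w2$specific)
  # declining baseline with an embedded rise is still caught
  w3 <- classify_specific(window_from_values(c(1.0, 0.8, 0.87, 0.6, 0.5)))
  expect_equal(w3$amplitude, 0.07)
  one <- window_from_values(rep(2, 4))
  one$samples <- one$samples[1]
  expect_error(classify_specific(one), class = "insufficient_data_error")
})

test_that("window amplitude equals the brute-force pairwise maximum", {
  set.seed(11)
  for (k in 1:20) {
    v <- 2 + cumsum(rnorm(sample(5:100, 1), 0, 0.05))
    v <- pmin(100, pmax(0.01, v))
    expect_equal(classify_specific(window_from_values(v))$amplitude,
                 brute_force_amplitude(v))
  }
})

test_that("amplitude is monotone in added SCRs and count in the threshold", {
  set.seed(5)
  v <- 2 + cumsum(rnorm(40, 0, 0.01))
  base_amp <- classify_specific(window_from_values(v))$amplitude
  tt <- (seq_along(v) - 1) / 4
  for (k in 1:10) {
    # SCR onset late enough that only its (non-decreasing) rise phase falls
    # inside the window; such an addition can never lower the amplitude
    v2 <- v + scr_kernel(tt - runif(1, 8.7, 9.7), runif(1, 0.05, 0.5))
    expect_gte(classify_specific(window_from_values(v2))$amplitude, base_amp)
  }
  # lowering the threshold never decreases the specific tally
  wins <- lapply(1:6, function(i) {
    w <- window_from_values(2 + cumsum(rnorm(20, 0, 0.02)))
    w
  })
  n_at <- function(th) sum(vapply(wins, function(w)
    classify_specific(w, threshold = th)$specific, logical(1)))
  ths <- c(0.2, 0.1, 0.05, 0.02, 0.005)
  counts <- vapply(ths, n_at, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("resonance requires two or more concurrent specific responses", {
  mkw <- function(pid, specific) {
    w <- window_from_values(if (specific) c(2, 2.1, 2.3) else c(2, 2.01, 2.02))
    w$participant_id <- pid
    classify_specific(w)
  }
  # triad: narrator plus one recipient -> resonating
  r <- detect_resonance(list(mkw("nar", TRUE), mkw("b", TRUE), mkw("c", FALSE)))
  expect_equal(r$n_specific, 2)
  expect_equal(r$EDA_G_resonance, 1L)
  # only the narrator -> not resonating
  r2 <- detect_resonance(list(mkw("nar", TRUE), mkw("b", FALSE), mkw("c", FALSE)))
  expect_equal(r2$EDA_G_resonance, 0L)
  # dyad, both specific -> resonating
  r3 <- detect_resonance(list(mkw("nar", TRUE), mkw("b", TRUE)))
  expect_equal(r3$EDA_G_resonance, 1L)
  # narrator requirement flag
  r4 <- detect_resonance(list(mkw("nar", FALSE), mkw("b", TRUE), mkw("c", TRUE)),
                         narrator_id = "nar", require_narrator = TRUE)
  expect_equal(r4$EDA_G_resonance, 0L)
  # mismatched gesture ids are rejected
  wa <- mkw("a", TRUE); wb <- mkw("b", TRUE); wb$gesture_id <- "other"
  expect_error(detect_resonance(list(wa, wb)), class = "validation_error")
})

test_that("per-gesture indicators recover simulator ground truth at high SNR", {
  cfg <- sim_config(n_recordings = 2, stories_per_recording = 5,
                    gestures_per_story = c(10, 20),
                    scr_amplitude_range = c(0.2, 0.4), noise_sd = 0.005,
                    seed = 21)
  tabs <- sim_analysis_tables(cfg)
  m <- merge(tabs$responses, tabs$sim$truth,
             by = c("gesture_id", "participant_id"))
  expect_gt(nrow(m), 300)
  sens <- with(m, sum(specific == 1 & responded == 1) / sum(responded == 1))
  spec <- with(m, sum(specific == 0 & responded == 0) / sum(responded == 0))
  expect_gte(sens, 0.95)
  expect_gte(spec, 0.95)
})
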
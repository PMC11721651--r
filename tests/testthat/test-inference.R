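make_crescendo_tables <- function(seed, crescendo = 2, arousal = 2) {
  sim_analysis_tables(sim_config(
    n_recordings = 2, stories_per_recording = 6,
    gestures_per_story = c(8, 18), crescendo_slope = crescendo,
    arousal_slope = arousal, seed = seed))
}

test_that("the crescendo model recovers a planted positive position effect", {
  tabs <- make_crescendo_tables(301)
  r <- fit_rq1(tabs$features)
  est <- r$fixed$estimate[r$fixed$term == "G_position_rel"]
  expect_gt(est, 0)
  expect_lt(r$lrt$p, 0.05)
  expect_gte(r$lrt$chisq, 0)
  expect_true(is.na(r$r2_conditional) ||
              (r$r2_conditional >= 0 && r$r2_conditional <= 1))
  if (!r$fallback) expect_gte(r$prop_positive, 0.5)
})

test_that("the LRT statistic is invariant to affine rescaling of position", {
  tabs <- make_crescendo_tables(302)
  r1 <- fit_rq1(tabs$features)
  resc <- tabs$features
  resc$G_position_rel <- 10 * resc$G_position_rel - 3
  r2 <- fit_rq1(resc)
  expect_equal(r1$lrt$chisq, r2$lrt$chisq, tolerance = 1e-4)
})

test_that("full-model log-likelihood dominates the nested null", {
  tabs <- make_crescendo_tables(303)
  r <- fit_rq1(tabs$features)
  expect_gte(as.numeric(logLik(lme4::refitML(r$model))),
             as.numeric(logLik(r$null_model)) - 1e-6)
  r2 <- fit_rq2(tabs$rq2_records)
  expect_gte(as.numeric(logLik(r2$model)),
             as.numeric(logLik(r2$null_model)) - 1e-6)
})

test_that("degenerate inputs are flagged, not mis-fitted", {
  tabs <- make_crescendo_tables(304)
  const <- tabs$features
  const$G_expressivity <- 0.25
  r <- fit_rq1(const)
  expect_true(r$degenerate)
  expect_equal(r$fixed$estimate[r$fixed$term == "G_position_rel"], 0)
  expect_true(is.na(r$r2_conditional))
  one_class <- tabs$rq2_records
  one_class$specific <- 0L
  expect_error(fit_rq2(one_class), class = "fit_error")
  expect_error(fit_rq1(tabs$features[1:5, ]), class = "fit_error")
})

test_that("the arousal model recovers the planted expressivity effect", {
  tabs <- make_crescendo_tables(305)
  r <- fit_rq2(tabs$rq2_records)
  est <- r$fixed$estimate[r$fixed$term == "G_expressivity"]
  expect_gt(est, 0)
  expect_lt(r$lrt$p, 0.05)
  expect_true(r$r2_conditional >= 0 && r$r2_conditional <= 1)
})

planted_records <- function(n = 240, seed = 1) {
  set.seed(seed)
  rec <- data.frame(
    SZ = rbinom(n, 1, 0.5), FO = rbinom(n, 1, 0.4), CV = rbinom(n, 1, 0.1),
    SL = rbinom(n, 1, 0.05), HO = rbinom(n, 1, 0.33), MA = rbinom(n, 1, 0.05),
    ND = rbinom(n, 1, 0.25), G_quote = rbinom(n, 1, 0.2),
    Sentiment = runif(n, -1, 1),
    protagonist = sample(c("narrator", "third-person"), n, TRUE),
    recency = sample(c("recent", "distant"), n, TRUE),
    group_size = sample(c(2L, 3L), n, TRUE),
    group_compose = sample(c("mixed", "all-female", "all-male"), n, TRUE))
  rec
}

test_that("the forest is reproducible and validates its inputs", {
  rec <- planted_records()
  rec$EDA_G_resonance <- rec$SZ
  r1 <- fit_rq3_rf(rec, seed = 5, ntree = 101)
  r2 <- fit_rq3_rf(rec, seed = 5, ntree = 101)
  expect_identical(r1$oob_votes, r2$oob_votes)
  expect_identical(permutation_importance(r1, reps = 3, seed = 2),
                   permutation_importance(r2, reps = 3, seed = 2))
  expect_error(fit_rq3_rf(rec[, setdiff(names(rec), "Sentiment")]),
               "Sentiment", class = "missing_column_error")
})

test_that("a deterministic single-predictor outcome tops the importance ranking", {
  rec <- planted_records(seed = 8)
  rec$EDA_G_resonance <- rec$SZ
  rf <- fit_rq3_rf(rec, seed = 3, ntree = 200)
  imp <- permutation_importance(rf, reps = 5, seed = 3)
  expect_equal(imp$predictor[1], "SZ")
  # importance of the perfect predictor approaches accuracy - baseline
  met <- fit_metrics(rf)
  expect_gt(imp$importance[1], 0.5 * (met$accuracy - met$baseline))
})

test_that("permuting a constant column changes nothing", {
  rec <- planted_records(seed = 9)
  rec$EDA_G_resonance <- rec$SZ
  rec$Sentiment <- 0.5  # constant
  rf <- fit_rq3_rf(rec, seed = 3, ntree = 101)
  imp <- permutation_importance(rf, reps = 3, seed = 1)
  expect_equal(imp$importance[imp$predictor == "Sentiment"], 0)
})

test_that("a pure-noise outcome stays at the baseline accuracy", {
  rec <- planted_records(n = 300, seed = 10)
  set.seed(1)
  rec$EDA_G_resonance <- rbinom(nrow(rec), 1, 0.3)  # independent of predictors
  rf <- fit_rq3_rf(rec, seed = 4, ntree = 200)
  met <- fit_metrics(rf)
  expect_lt(abs(met$accuracy - met$baseline), 0.1)
  expect_gt(met$binomial_p, 0.01)
  imp <- permutation_importance(rf, reps = 5, seed = 4)
  # every importance small: |imp| < 2 SE over permutations (plus slack for 0 sd)
  expect_true(all(abs(imp$importance) <= pmax(2 * imp$sd, 0.02)))
})

test_that("fit metrics match closed forms on hand-built OOB predictions", {
  mk_rf <- function(p, y) {
    pred <- factor(ifelse(p > 0.5, "yes", "no"), levels = c("no", "yes"))
    structure(list(oob_votes = cbind(no = 1 - p, yes = p),
                   oob_pred = pred,
                   y = factor(ifelse(y == 1, "yes", "no"),
                              levels = c("no", "yes"))),
              class = "rf_result")
  }
  y <- c(1, 1, 1, 0, 0, 0, 1, 0, 1, 0)
  # perfect probabilistic prediction
  m <- fit_metrics(mk_rf(y, y))
  expect_equal(m$r2_traditional, 1)
  # constant base-rate prediction -> McFadden exactly 0
  m0 <- fit_metrics(mk_rf(rep(mean(y), 10), y))
  expect_equal(m0$r2_mcfadden, 0, tolerance = 1e-9)
  # binomial p equals the exact tail sum
  p <- c(.9, .8, .9, .2, .4, .1, .6, .3, .7, .6)  # 10 correct of 10? no:
  correct <- sum((p > 0.5) == (y == 1))
  base <- max(mean(y), 1 - mean(y))
  m1 <- fit_metrics(mk_rf(p, y))
  expect_equal(m1$binomial_p,
               sum(dbinom(correct:10, 10, base)))
})

test_that("ICE curves reproduce direct predictions and average to the PDP", {
  rec <- planted_records(n = 150, seed = 12)
  rec$EDA_G_resonance <- as.integer(rec$SZ == 1 | rec$ND == 1)
  rf <- fit_rq3_rf(rec, seed = 6, ntree = 101)
  ic <- ice_curves(rf, "SZ")
  direct <- predict(rf$forest, newdata = rf$x, type = "prob")[, "yes"]
  own <- ic$curves[cbind(seq_len(nrow(rf$x)),
                         match(as.character(rf$x$SZ), colnames(ic$curves)))]
  expect_equal(unname(own), unname(direct))
  expect_equal(partial_dependence(ic), colMeans(ic$curves))
  # grouped means of ICE equal the stratified PDP (algebraic identity)
  g <- rf$x$group_size == "2"
  expect_equal(colMeans(ic$curves[g, ]), partial_dependence(
    structure(list(curves = ic$curves[g, ]), class = "ice_curves")))
  expect_error(ice_curves(rf, "nope"), class = "validation_error")
})

test_that("curves are flat for an ignored predictor and stepped for a stump", {
  rec <- planted_records(n = 150, seed = 13)
  rec$EDA_G_resonance <- rec$SZ
  rec$Sentiment <- 0.1  # constant -> never split on
  rf <- fit_rq3_rf(rec, seed = 7, ntree = 101)
  ic <- ice_curves(rf, "Sentiment", grid = c(-1, 0, 1))
  expect_true(all(apply(ic$curves, 1, function(r) diff(range(r)) == 0)))
  # near-stump forest on a numeric threshold rule: curves are monotone steps
  rec2 <- planted_records(n = 200, seed = 14)
  set.seed(2); rec2$Sentiment <- runif(200, -1, 1)
  rec2$EDA_G_resonance <- as.integer(rec2$Sentiment > 0)
  rf2 <- fit_rq3_rf(rec2, predictors = "Sentiment", seed = 8, ntree = 1,
                    mtry = 1)
  ic2 <- ice_curves(rf2, "Sentiment", grid = seq(-0.9, 0.9, by = 0.2))
  for (i in sample(nrow(ic2$curves), 10)) {
    expect_lte(length(unique(ic2$curves[i, ])), 2)   # a single split
    expect_true(all(diff(ic2$curves[i, ]) >= 0))     # step upward at it
  }
})

test_that("triadic coupling amplifies the ICE response to gesture kinematics", {
  cfg <- sim_config(n_recordings = 6, group_size = c(2, 3),
                    stories_per_recording = 5, gestures_per_story = c(10, 20),
                    arousal_slope = 2.5, coupling = 0.15, coupling_triad = 0.7,
                    seed = 404)
  tabs <- sim_analysis_tables(cfg)
  rf <- fit_rq3_rf(tabs$features, seed = 11, ntree = 300)
  ic <- ice_curves(rf, "ND")
  slope <- ic$curves[, "yes"] - ic$curves[, "no"]
  triad <- tabs$features$group_size == 3
  expect_gt(mean(slope[triad]), mean(slope[!triad]))
})
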
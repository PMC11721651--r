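#' Nakagawa conditional pseudo-R-squared for a merMod fit
#'
#' R2c = (var_fixed + var_random) / (var_fixed + var_random + var_residual),
#' with var_fixed the variance of the fixed-effect linear predictor,
#' var_random the mean diagonal of Z Sigma Z' over observations, and the
#' residual variance taken as sigma^2 for Gaussian fits and the logit-link
#' distribution-specific pi^2/3 for binomial fits.
#'
#' @param model a fitted `lmerMod` or `glmerMod`
#' @return conditional pseudo-R2 in \[0, 1\] (NA if undefined)
#' @export
r2_conditional <- function(model) {
  X <- lme4::getME(model, "X")
  vf <- stats::var(as.vector(X %*% lme4::fixef(model)))
  Z <- lme4::getME(model, "Z")
  Lt <- lme4::getME(model, "Lambdat")
  s2 <- stats::sigma(model)^2
  Sig <- s2 * Matrix::crossprod(Lt)          # covariance of the random effects
  vr <- mean(Matrix::rowSums((Z %*% Sig) * Z))
  ve <- if (isTRUE(lme4::isLMM(model))) s2 else pi^2 / 3
  tot <- vf + vr + ve
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  (vf + vr) / tot
}

mixed_model_result <- function(model, null_model, fixed, lrt, r2c,
                               group_slopes = NULL, prop_positive = NA_real_,
                               fallback = FALSE, degenerate = FALSE,
                               note = NULL) {
  structure(list(model = model, null_model = null_model, fixed = fixed,
                 loglik = if (!is.null(model)) as.numeric(stats::logLik(model))
                          else NA_real_,
                 lrt = lrt, r2_conditional = r2c,
                 group_slopes = group_slopes, prop_positive = prop_positive,
                 fallback = fallback, degenerate = degenerate, note = note),
            class = "mixed_model_result")
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat("<mixed_model_result>\n")
  print(x$fixed)
  cat(sprintf("LRT: chisq = %.3f, df = %d, p = %.4g\n",
              x$lrt$chisq, x$lrt$df, x$lrt$p))
  cat(sprintf("conditional pseudo-R2 = %s\n",
              ifelse(is.na(x$r2_conditional), "undefined",
                     sprintf("%.3f", x$r2_conditional))))
  if (!is.na(x$prop_positive)) {
    cat(sprintf("groups with positive slope: %.0f%%\n", 100 * x$prop_positive))
  }
  if (x$fallback) cat("note: fell back to random intercepts (singular fit)\n")
  invisible(x)
}

fixed_table <- function(model) {
  cc <- summary(model)$coefficients
  data.frame(term = rownames(cc), estimate = cc[, 1], se = cc[, 2],
             statistic = cc[, 3], row.names = NULL)
}

#' Crescendo model: does expressivity rise toward the climax?
#'
#' Fits the linear mixed model `G_expressivity ~ G_position_rel` with a
#' random slope for position per narrator-by-recording `ID` (falling back to
#' random intercepts when the slope model is singular or fails). Significance
#' is a likelihood-ratio test of ML refits against the same model without
#' `G_position_rel`; effect size is the Nakagawa conditional pseudo-R2 of the
#' REML fit. Per-group random slope coefficients give the share of speakers
#' with a positive position-expressivity association.
#'
#' @param records feature table with `G_expressivity`, `G_position_rel`, `ID`
#' @return a `mixed_model_result`
#' @export
fit_rq1 <- function(records) {
  assert_cols(records, c("G_expressivity", "G_position_rel", "ID"), "records")
  if (nrow(records) < 10 || length(unique(records$ID)) < 2) {
    stop_ctx("need >= 10 records over >= 2 groups", class = "fit_error")
  }
  if (stats::var(records$G_expressivity) == 0) {
    return(mixed_model_result(
      NULL, NULL,
      fixed = data.frame(term = c("(Intercept)", "G_position_rel"),
                         estimate = c(records$G_expressivity[1], 0),
                         se = NA_real_, statistic = NA_real_),
      lrt = list(chisq = 0, df = 1L, p = 1), r2c = NA_real_,
      degenerate = TRUE, note = "constant response; pseudo-R2 undefined"))
  }
  slope_f <- G_expressivity ~ G_position_rel + (1 + G_position_rel | ID)
  int_f <- G_expressivity ~ G_position_rel + (1 | ID)
  fit_quiet <- function(f, reml) {
    suppressWarnings(suppressMessages(
      tryCatch(lme4::lmer(f, data = records, REML = reml),
               error = function(e) e)))
  }
  m <- fit_quiet(slope_f, TRUE)
  fallback <- inherits(m, "error") || lme4::isSingular(m, tol = 1e-4)
  used_f <- if (fallback) int_f else slope_f
  if (fallback) m <- fit_quiet(int_f, TRUE)
  if (inherits(m, "error")) {
    stop_ctx("crescendo model failed to fit: %s", conditionMessage(m),
             class = "fit_error")
  }
  null_f <- stats::update(stats::formula(used_f), . ~ . - G_position_rel)
  m_full <- fit_quiet(used_f, FALSE)
  m_null <- suppressWarnings(suppressMessages(
    tryCatch(lme4::lmer(null_f, data = records, REML = FALSE),
             error = function(e) e)))
  if (inherits(m_full, "error") || inherits(m_null, "error")) {
    stop_ctx("crescendo model LRT fits failed", class = "fit_error")
  }
  chisq <- max(0, 2 * (as.numeric(stats::logLik(m_full)) -
                       as.numeric(stats::logLik(m_null))))
  df <- attr(stats::logLik(m_full), "df") - attr(stats::logLik(m_null), "df")
  slopes <- NULL
  prop_pos <- NA_real_
  if (!fallback) {
    slopes <- stats::coef(m)$ID[, "G_position_rel"]
    prop_pos <- mean(slopes > 0)
  }
  mixed_model_result(m, m_null, fixed_table(m),
                     lrt = list(chisq = chisq, df = df,
                                p = stats::pchisq(chisq, df, lower.tail = FALSE)),
                     r2c = r2_conditional(m), group_slopes = slopes,
                     prop_positive = prop_pos, fallback = fallback)
}

#' Arousal model: does expressivity predict specific EDA responses?
#'
#' Fits the mixed logistic model `specific ~ G_expressivity` with crossed
#' random intercepts for participant and recording, over all gesture x
#' participant response rows. Significance is a likelihood-ratio test
#' against the null without `G_expressivity`; effect size is the Nakagawa
#' conditional pseudo-R2 with logit-link residual variance pi^2/3.
#'
#' @param records long response table with `specific` (0/1),
#'   `G_expressivity`, `participant_id`, `recording_id`
#' @return a `mixed_model_result`
#' @export
fit_rq2 <- function(records) {
  assert_cols(records, c("specific", "G_expressivity", "participant_id",
                         "recording_id"), "records")
  y <- as_binary(records$specific, "specific")
  if (length(unique(y)) < 2) {
    stop_ctx("outcome has a single class; cannot fit logistic model",
             class = "fit_error")
  }
  records$specific <- y
  fit_quiet <- function(f) {
    suppressWarnings(suppressMessages(
      tryCatch(lme4::glmer(f, data = records, family = stats::binomial(),
                           control = lme4::glmerControl(calc.derivs = FALSE)),
               error = function(e) e)))
  }
  m <- fit_quiet(specific ~ G_expressivity + (1 | participant_id) + (1 | recording_id))
  m0 <- fit_quiet(specific ~ 1 + (1 | participant_id) + (1 | recording_id))
  if (inherits(m, "error") || inherits(m0, "error")) {
    stop_ctx("arousal model failed to fit: %s",
             conditionMessage(if (inherits(m, "error")) m else m0),
             class = "fit_error")
  }
  chisq <- max(0, 2 * (as.numeric(stats::logLik(m)) -
                       as.numeric(stats::logLik(m0))))
  df <- attr(stats::logLik(m), "df") - attr(stats::logLik(m0), "df")
  mixed_model_result(m, m0, fixed_table(m),
                     lrt = list(chisq = chisq, df = df,
                                p = stats::pchisq(chisq, df, lower.tail = FALSE)),
                     r2c = r2_conditional(m))
}

#' The 13 standard resonance-forest predictors
#' @export
RF_PREDICTORS <- c("SZ", "FO", "CV", "SL", "HO", "MA", "ND",
                   "G_quote", "Sentiment", "protagonist", "recency",
                   "group_size", "group_compose")

rf_design <- function(records, predictors) {
  miss <- setdiff(predictors, names(records))
  if (length(miss)) {
    stop_ctx("missing predictor column(s): %s", paste(miss, collapse = ", "),
             class = "missing_column_error")
  }
  x <- records[, predictors, drop = FALSE]
  for (p in predictors) {
    if (p %in% c("SZ", "FO", "CV", "SL", "HO", "MA", "ND", "G_quote")) {
      x[[p]] <- factor(ifelse(as_binary(x[[p]], p) == 1, "yes", "no"),
                       levels = c("no", "yes"))
    } else if (p == "Sentiment") {
      x[[p]] <- as.numeric(x[[p]])
    } else {
      x[[p]] <- factor(x[[p]])
    }
  }
  x
}

#' Resonance Random Forest
#'
#' Grows a classification forest for the binary resonance outcome
#' `EDA_G_resonance` from the seven GEI components plus six story/situation
#' covariates (13 predictors; unordered factors are split natively by subset
#' membership). Defaults follow the analysis design: 1,500 trees and 3
#' candidate predictors per split. The fit is reproducible given `seed`, and
#' in-bag membership is retained for out-of-bag permutation importance.
#'
#' @param records feature table including `EDA_G_resonance` and the
#'   predictors
#' @param predictors predictor names (default [RF_PREDICTORS])
#' @param seed integer seed
#' @param ntree number of trees
#' @param mtry candidate predictors per split
#' @return object of class `rf_result`
#' @export
fit_rq3_rf <- function(records, predictors = RF_PREDICTORS, seed = 1,
                       ntree = 1500, mtry = 3) {
  assert_cols(records, "EDA_G_resonance", "records")
  y <- factor(ifelse(as_binary(records$EDA_G_resonance, "EDA_G_resonance") == 1,
                     "yes", "no"), levels = c("no", "yes"))
  x <- rf_design(records, predictors)
  set.seed(seed)
  forest <- randomForest::randomForest(
    x = x, y = y, ntree = ntree, mtry = mtry,
    keep.forest = TRUE, keep.inbag = TRUE, importance = TRUE)
  oob_pred <- forest$predicted
  structure(list(forest = forest, x = x, y = y,
                 predictors = predictors, ntree = ntree, mtry = mtry,
                 seed = seed, oob_pred = oob_pred,
                 oob_votes = forest$votes,
                 accuracy = mean(oob_pred == y, na.rm = TRUE)),
            class = "rf_result")
}

#' @export
print.rf_result <- function(x, ...) {
  cat(sprintf("<rf_result> ntree=%d mtry=%d n=%d OOB accuracy=%.3f\n",
              x$ntree, x$mtry, length(x$y), x$accuracy))
  invisible(x)
}

# majority vote over the trees for which each observation is out of bag;
# ties break toward the first class level ("no")
oob_vote_accuracy <- function(rf, x) {
  ind <- stats::predict(rf$forest, newdata = x, predict.all = TRUE)$individual
  oob <- rf$forest$inbag == 0
  yes <- rowSums((ind == "yes") & oob)
  tot <- rowSums(oob)
  keep <- tot > 0
  pred <- ifelse(yes[keep] > tot[keep] / 2, "yes", "no")
  mean(pred == as.character(rf$y)[keep])
}

#' Out-of-bag permutation importance
#'
#' For each predictor, the importance is the mean decrease in out-of-bag
#' accuracy when that predictor's column is permuted: baseline OOB accuracy
#' minus the mean OOB accuracy over `reps` independent permutations. OOB
#' predictions are majority votes over the trees in which an observation was
#' not sampled. Optionally permutes within strata of a declared covariate to
#' blunt confounding with a correlated predictor.
#'
#' @param rf an `rf_result`
#' @param reps permutations per predictor (default 10)
#' @param seed integer seed for the permutations
#' @param within optional name of a column of the design to stratify
#'   permutations by
#' @return data frame `predictor`, `importance`, `sd` (over permutations),
#'   sorted by decreasing importance; baseline accuracy as attribute
#' @export
permutation_importance <- function(rf, reps = 10, seed = 1, within = NULL) {
  stopifnot(inherits(rf, "rf_result"))
  set.seed(seed)
  base_acc <- oob_vote_accuracy(rf, rf$x)
  strata <- if (is.null(within)) rep(1L, nrow(rf$x))
            else as.integer(factor(rf$x[[within]]))
  res <- lapply(rf$predictors, function(p) {
    col <- rf$x[[p]]
    accs <- vapply(seq_len(reps), function(r) {
      xp <- rf$x
      perm <- col
      for (s in unique(strata)) {
        i <- which(strata == s)
        perm[i] <- col[sample(i)]
      }
      xp[[p]] <- perm
      oob_vote_accuracy(rf, xp)
    }, numeric(1))
    data.frame(predictor = p, importance = base_acc - mean(accs),
               sd = stats::sd(accs))
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  attr(out, "baseline_accuracy") <- base_acc
  attr(out, "method") <- paste0(
    "OOB permutation (mean decrease in accuracy), ",
    if (is.null(within)) "unstratified" else paste("stratified by", within))
  out
}

#' Random-forest fit metrics
#'
#' Computed on the out-of-bag class probabilities (vote fractions): the
#' traditional R2 (`1 - SSE/SST` against the 0/1 outcome), McFadden's R2
#' (`1 - ll_model/ll_null` with Bernoulli log-likelihoods, probabilities
#' clipped to \[1e-6, 1-1e-6\]), and an exact one-tailed binomial test of the
#' OOB correct-classification count against the majority-class baseline rate.
#'
#' @param rf an `rf_result`
#' @return list with `r2_traditional`, `r2_mcfadden`, `binomial_p`,
#'   `accuracy`, `baseline` (majority-class rate)
#' @export
fit_metrics <- function(rf) {
  stopifnot(inherits(rf, "rf_result"))
  keep <- !is.na(rf$oob_votes[, "yes"]) & !is.na(rf$oob_pred)
  p <- rf$oob_votes[keep, "yes"]
  y <- as.integer(rf$y[keep] == "yes")
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) NA_real_ else 1 - sum((y - p)^2) / sst
  pc <- pmin(1 - 1e-6, pmax(1e-6, p))
  ll_m <- sum(y * log(pc) + (1 - y) * log(1 - pc))
  p0 <- pmin(1 - 1e-6, pmax(1e-6, mean(y)))
  ll_0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  mcf <- if (ll_0 == 0) NA_real_ else 1 - ll_m / ll_0
  correct <- sum(rf$oob_pred[keep] == rf$y[keep])
  baseline <- max(mean(y), 1 - mean(y))
  bt <- stats::binom.test(correct, sum(keep), p = baseline,
                          alternative = "greater")
  list(r2_traditional = r2, r2_mcfadden = mcf, binomial_p = bt$p.value,
       accuracy = correct / sum(keep), baseline = baseline,
       sst_zero = sst == 0)
}

#' Individual conditional expectation curves
#'
#' For one predictor, each record yields a curve of the predicted resonance
#' probability over a grid of predictor values, holding every other field at
#' the record's observed value. Factor predictors use their levels as the
#' grid; numeric predictors an equi-spaced grid over the observed range. The
#' column-wise mean of the curves is the partial-dependence curve.
#'
#' @param rf an `rf_result`
#' @param predictor one of the forest's predictors
#' @param grid optional grid of values (defaults as above)
#' @param grid_n grid size for numeric predictors
#' @return object of class `ice_curves`: list with `predictor`, `grid`,
#'   `curves` (records x grid matrix of P(resonance)), `pdp`
#' @export
ice_curves <- function(rf, predictor, grid = NULL, grid_n = 20) {
  stopifnot(inherits(rf, "rf_result"))
  if (!predictor %in% rf$predictors) {
    stop_ctx("unknown predictor '%s'", predictor, class = "validation_error")
  }
  col <- rf$x[[predictor]]
  if (is.null(grid)) {
    grid <- if (is.factor(col)) levels(col)
            else seq(min(col), max(col), length.out = grid_n)
  }
  curves <- vapply(grid, function(v) {
    xg <- rf$x
    xg[[predictor]] <- if (is.factor(col)) factor(rep(v, nrow(xg)),
                                                  levels = levels(col))
                       else as.numeric(v)
    stats::predict(rf$forest, newdata = xg, type = "prob")[, "yes"]
  }, numeric(nrow(rf$x)))
  curves <- matrix(curves, nrow = nrow(rf$x))
  colnames(curves) <- as.character(grid)
  structure(list(predictor = predictor, grid = grid, curves = curves,
                 pdp = colMeans(curves)),
            class = "ice_curves")
}

#' Partial-dependence curve (mean of the ICE curves)
#' @param ice an `ice_curves` object
#' @return named numeric vector over the grid
#' @export
partial_dependence <- function(ice) {
  stopifnot(inherits(ice, "ice_curves"))
  colMeans(ice$curves)
}

#' @export
print.ice_curves <- function(x, ...) {
  cat(sprintf("<ice_curves> %s over %d grid values x %d records\n",
              x$predictor, length(x$grid), nrow(x$curves)))
  invisible(x)
}
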
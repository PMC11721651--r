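#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: multiparty
#' recordings (dyads/triads) of conversational stories, narrators gesturing
#' in streams whose expressivity optionally ramps toward the climax, 4 Hz
#' skin-conductance traces built as tonic level + Gaussian noise + phasic
#' SCRs, and a logistic link from gesture expressivity to the narrator's SCR
#' probability with configurable cross-participant coupling.
#'
#' Defaults mirror the corpus shape the analysis is designed for: nine
#' recordings alternating dyads and triads, about six stories each with 4-40
#' gestures, component base rates loosely matching the observed marginal
#' frequencies (HO ~ 0.33, CV ~ 0.06, MA ~ 0.04, SL ~ 0.02), an arousal
#' logistic with intercept -0.95 and slope 1.43, and SCR latency drawn
#' uniformly from 1-3 s.
#'
#' @param n_recordings number of recordings
#' @param group_size 2 or 3 (recycled over recordings)
#' @param group_compose "all-female", "all-male" or "mixed" (recycled)
#' @param stories_per_recording stories per recording
#' @param gestures_per_story integer range `c(min, max)` of gestures per story
#' @param crescendo_slope logit-scale effect of relative story position on
#'   the GEI component probabilities (and on log nucleus duration); 0 = flat
#' @param arousal_intercept,arousal_slope logistic link from GEI to the
#'   narrator's per-gesture SCR probability
#' @param coupling probability a recipient fires given the narrator fired
#' @param coupling_triad optional coupling override for triads
#' @param scr_amplitude_range SCR amplitude range, uS
#' @param latency_range SCR latency after gesture onset, seconds (within 0-5)
#' @param tonic_level tonic skin-conductance level, uS
#' @param noise_sd Gaussian measurement noise SD, uS
#' @param component_base_rates named base probabilities for SZ, FO, CV, SL,
#'   HO, MA at mid-story position (ND emerges from nucleus durations)
#' @param sampling_rate EDA sampling rate, Hz
#' @param recording_duration optional fixed recording duration, seconds; an
#'   error is raised if the generated stories do not fit
#' @param seed integer random seed
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_recordings = 9,
                       group_size = c(2, 3),
                       group_compose = c("mixed", "all-female", "all-male"),
                       stories_per_recording = 6,
                       gestures_per_story = c(4, 40),
                       crescendo_slope = 0.2,
                       arousal_intercept = -0.95,
                       arousal_slope = 1.43,
                       coupling = 0.3,
                       coupling_triad = NULL,
                       scr_amplitude_range = c(0.1, 0.5),
                       latency_range = c(1, 3),
                       tonic_level = 2,
                       noise_sd = 0.005,
                       component_base_rates = c(SZ = 0.45, FO = 0.35,
                                                CV = 0.06, SL = 0.02,
                                                HO = 0.33, MA = 0.04),
                       sampling_rate = 4,
                       recording_duration = NULL,
                       seed = 1L) {
  cfg <- list(n_recordings = as.integer(n_recordings),
              group_size = as.integer(group_size),
              group_compose = group_compose,
              stories_per_recording = as.integer(stories_per_recording),
              gestures_per_story = as.integer(gestures_per_story),
              crescendo_slope = crescendo_slope,
              arousal_intercept = arousal_intercept,
              arousal_slope = arousal_slope,
              coupling = coupling, coupling_triad = coupling_triad,
              scr_amplitude_range = scr_amplitude_range,
              latency_range = latency_range,
              tonic_level = tonic_level, noise_sd = noise_sd,
              component_base_rates = component_base_rates,
              sampling_rate = sampling_rate,
              recording_duration = recording_duration,
              seed = as.integer(seed))
  with(cfg, {
    if (n_recordings < 1 || stories_per_recording < 1) {
      stop_ctx("counts must be >= 1", class = "config_error")
    }
    if (!all(group_size %in% c(2L, 3L))) {
      stop_ctx("group_size must be 2 or 3", class = "config_error")
    }
    if (!all(group_compose %in% c("all-female", "all-male", "mixed"))) {
      stop_ctx("unknown group_compose level", class = "config_error")
    }
    if (length(gestures_per_story) != 2 || any(gestures_per_story < 1) ||
        gestures_per_story[1] > gestures_per_story[2]) {
      stop_ctx("gestures_per_story must be an increasing range >= 1",
               class = "config_error")
    }
    if (coupling < 0 || coupling > 1) {
      stop_ctx("coupling must be a probability", class = "config_error")
    }
    if (any(latency_range < 0) || any(latency_range > 5) ||
        latency_range[1] > latency_range[2]) {
      stop_ctx("latency_range must lie within [0, 5]", class = "config_error")
    }
    if (noise_sd < 0 || tonic_level < 0.01) {
      stop_ctx("invalid trace parameters", class = "config_error")
    }
    if (any(component_base_rates <= 0) || any(component_base_rates >= 1)) {
      stop_ctx("component base rates must lie in (0, 1)", class = "config_error")
    }
  })
  structure(cfg, class = "sim_config")
}

#' Peak-normalized Bateman SCR kernel
#'
#' Difference-of-exponentials model of a phasic skin-conductance response,
#' scaled so that its maximum equals `amplitude`:
#' `a * (exp(-t/tau_decay) - exp(-t/tau_rise)) / peak` for `t >= 0`, 0 before
#' the response onset (causality).
#'
#' @param t_rel time since SCR onset, seconds (vectorized)
#' @param amplitude peak amplitude, uS
#' @param tau_rise,tau_decay rise and decay time constants, seconds
#'   (`0 < tau_rise < tau_decay`)
#' @return conductance contribution in uS
#' @export
scr_kernel <- function(t_rel, amplitude, tau_rise = 0.7, tau_decay = 3) {
  if (tau_rise <= 0 || tau_decay <= 0) {
    stop_ctx("time constants must be positive", class = "parameter_error")
  }
  if (tau_rise >= tau_decay) {
    stop_ctx("tau_rise must be smaller than tau_decay", class = "parameter_error")
  }
  t_peak <- log(tau_decay / tau_rise) * tau_rise * tau_decay / (tau_decay - tau_rise)
  peak <- exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise)
  out <- numeric(length(t_rel))
  pos <- t_rel >= 0
  out[pos] <- amplitude * (exp(-t_rel[pos] / tau_decay) -
                           exp(-t_rel[pos] / tau_rise)) / peak
  out
}

# one recording's annotations, traces and ground truth (uses current RNG state)
sim_recording_impl <- function(cfg, recording_id, group_size, group_compose) {
  pids <- sprintf("%s_p%d", recording_id, seq_len(group_size))
  sexes <- switch(group_compose,
                  "all-female" = rep("female", group_size),
                  "all-male" = rep("male", group_size),
                  "mixed" = c("female", "male",
                              sample(c("female", "male", "diverse/NA"),
                                     max(0, group_size - 2), replace = TRUE)))

  stories <- gestures <- phases <- ipus <- quotes <- truth <- list()
  cursor <- 20
  base <- cfg$component_base_rates
  for (j in seq_len(cfg$stories_per_recording)) {
    sid <- sprintf("%s_s%d", recording_id, j)
    narrator <- pids[(j - 1) %% group_size + 1]
    n_rng <- seq(cfg$gestures_per_story[1], cfg$gestures_per_story[2])
    n_g <- n_rng[sample.int(length(n_rng), 1)]
    pos <- if (n_g == 1) 0.5 else (seq_len(n_g) - 1) / (n_g - 1)
    s_on <- cursor
    g_t <- s_on + stats::runif(1, 1, 3)
    for (i in seq_len(n_g)) {
      gid <- sprintf("%s_g%d", sid, i)
      shift <- cfg$crescendo_slope * (pos[i] - 0.5)
      p <- stats::plogis(stats::qlogis(base) + shift)
      code <- stats::rbinom(length(p), 1, p)
      names(code) <- names(base)
      d_prep <- stats::runif(1, 0.3, 0.6)
      d_nuc <- min(3.5, max(1.2, stats::rlnorm(1, log(1.5) + 0.35 * shift, 0.45)))
      d_hold <- if (code[["HO"]] == 1) stats::runif(1, 0.3, 1.0) else 0
      d_ret <- stats::runif(1, 0.3, 0.6)
      t0 <- g_t
      seg <- data.frame(
        gesture_id = gid,
        phase = c("preparation", "nucleus", if (d_hold > 0) "hold", "retraction"),
        start = t0 + cumsum(c(0, d_prep, d_nuc, if (d_hold > 0) d_hold))[
          seq_len(3 + (d_hold > 0))],
        stringsAsFactors = FALSE)
      seg$end <- seg$start + c(d_prep, d_nuc, if (d_hold > 0) d_hold, d_ret)
      phases[[length(phases) + 1]] <- seg
      gestures[[length(gestures) + 1]] <- data.frame(
        id = gid, story_id = sid, onset = t0, offset = seg$end[nrow(seg)],
        SZ = code[["SZ"]], FO = code[["FO"]], CV = code[["CV"]],
        SL = code[["SL"]], MA = code[["MA"]],
        description = "", stringsAsFactors = FALSE)
      g_t <- seg$end[nrow(seg)] + stats::runif(1, 1.5, 4)
    }
    s_off <- g_t - stats::runif(1, 0, 1)  # shortly after the last gesture
    c_on <- s_on + 0.7 * (s_off - s_on)
    stories[[j]] <- data.frame(
      id = sid, recording_id = recording_id, narrator_id = narrator,
      onset = s_on, offset = s_off, climax_onset = c_on, climax_offset = s_off,
      protagonist = sample(c("narrator", "third-person"), 1),
      recency = sample(c("recent", "distant"), 1), stringsAsFactors = FALSE)

    # IPUs tile the story span; word sentiments are uniform in [-1, 1]
    t <- s_on
    ki <- 1
    while (t < s_off - 1) {
      dur <- min(stats::runif(1, 1, 3), s_off - t)
      nw <- max(1, round(dur * 2.5))
      ipus[[length(ipus) + 1]] <- data.frame(
        id = sprintf("%s_i%d", sid, ki), story_id = sid, start = t, end = t + dur,
        words = paste0("w", seq_len(nw), collapse = " "),
        word_sentiments = paste(round(stats::runif(nw, -1, 1), 4), collapse = " "),
        stringsAsFactors = FALSE)
      t <- t + dur + stats::runif(1, 0.1, 0.5)
      ki <- ki + 1
    }

    # direct speech clusters at the climax: quotes are placed inside it
    for (q in seq_len(sample.int(2, 1))) {
      q_on <- stats::runif(1, c_on, max(c_on, s_off - 0.6))
      quotes[[length(quotes) + 1]] <- data.frame(
        story_id = sid, start = q_on,
        end = min(s_off, q_on + stats::runif(1, 0.5, 1.5)),
        stringsAsFactors = FALSE)
    }
    cursor <- s_off + stats::runif(1, 5, 15)
  }

  duration <- cursor + 5
  if (!is.null(cfg$recording_duration)) {
    if (duration > cfg$recording_duration) {
      stop_ctx("generated stories (%.0f s) exceed recording_duration (%.0f s)",
               duration, cfg$recording_duration, class = "config_error")
    }
    duration <- cfg$recording_duration
  }

  stories <- do.call(rbind, stories)
  gestures <- do.call(rbind, gestures)
  phases <- do.call(rbind, phases)
  ipus <- do.call(rbind, ipus)
  quotes <- do.call(rbind, quotes)

  # ground truth SCRs: narrator fires with logistic probability in the
  # realized GEI; recipients fire with the coupling probability given the
  # narrator fired
  coup <- if (group_size == 3 && !is.null(cfg$coupling_triad))
    cfg$coupling_triad else cfg$coupling
  scrs <- stats::setNames(vector("list", group_size), pids)
  for (k in seq_len(nrow(gestures))) {
    g <- gestures[k, ]
    sid <- g$story_id
    story_g <- gestures$id[gestures$story_id == sid]
    HO <- derive_ho(g$id, phases)
    ND <- derive_nd(g$id, story_g, phases)
    gei <- (g$SZ + g$FO + g$CV + g$SL + HO + g$MA + ND) / 7
    p_nar <- stats::plogis(cfg$arousal_intercept + cfg$arousal_slope * gei)
    narrator <- stories$narrator_id[stories$id == sid]
    fired_nar <- stats::rbinom(1, 1, p_nar) == 1
    for (pid in pids) {
      fired <- if (pid == narrator) fired_nar
               else fired_nar && stats::rbinom(1, 1, coup) == 1
      lat <- stats::runif(1, cfg$latency_range[1], cfg$latency_range[2])
      amp <- stats::runif(1, cfg$scr_amplitude_range[1],
                          cfg$scr_amplitude_range[2])
      if (fired) {
        scrs[[pid]] <- c(scrs[[pid]], stats::setNames(amp, g$onset + lat))
      }
      truth[[length(truth) + 1]] <- data.frame(
        recording_id = recording_id, gesture_id = g$id, story_id = sid,
        participant_id = pid,
        role = ifelse(pid == narrator, "narrator", "recipient"),
        responded = as.integer(fired),
        scr_onset = if (fired) g$onset + lat else NA_real_,
        scr_amplitude = if (fired) amp else NA_real_,
        true_gei = gei, stringsAsFactors = FALSE)
    }
  }

  n <- ceiling(duration * cfg$sampling_rate)
  tt <- (seq_len(n) - 1) / cfg$sampling_rate
  traces <- lapply(pids, function(pid) {
    v <- cfg$tonic_level + stats::rnorm(n, 0, cfg$noise_sd)
    ev <- scrs[[pid]]
    for (i in seq_along(ev)) {
      on <- as.numeric(names(ev)[i])
      idx <- which(tt >= on & tt <= on + 25)
      v[idx] <- v[idx] + scr_kernel(tt[idx] - on, ev[[i]])
    }
    eda_trace(pid, pmin(100, pmax(0.01, v)),
              sampling_rate = cfg$sampling_rate, t0 = 0)
  })
  names(traces) <- pids

  list(
    recording = data.frame(id = recording_id, group_size = group_size,
                           group_compose = group_compose, duration = duration,
                           stringsAsFactors = FALSE),
    participants = data.frame(id = pids, recording_id = recording_id,
                              sex = sexes, stringsAsFactors = FALSE),
    stories = stories, gestures = gestures, phases = phases, ipus = ipus,
    quotes = quotes, traces = traces, truth = do.call(rbind, truth))
}

#' Simulate a single recording
#'
#' Seeds the RNG from `cfg$seed` and generates one recording (the first
#' entry of the `group_size` / `group_compose` cycles).
#'
#' @param cfg a [sim_config()]
#' @param recording_id identifier for the recording
#' @return list with `recording`, `participants`, `stories`, `gestures`,
#'   `phases`, `ipus`, `quotes`, `traces` and ground-truth `truth`
#' @export
simulate_recording <- function(cfg, recording_id = "r1") {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  sim_recording_impl(cfg, recording_id, cfg$group_size[1], cfg$group_compose[1])
}

#' Simulate a full multi-recording corpus
#'
#' @param cfg a [sim_config()]
#' @return object of class `sim_corpus`: `ann` (validated annotation tables),
#'   `traces` (named list of [eda_trace()]), `truth` (per gesture x
#'   participant ground truth) and `config`
#' @export
simulate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  gs <- rep_len(cfg$group_size, cfg$n_recordings)
  gc <- rep_len(cfg$group_compose, cfg$n_recordings)
  recs <- lapply(seq_len(cfg$n_recordings), function(r) {
    sim_recording_impl(cfg, sprintf("r%d", r), gs[r], gc[r])
  })
  bind <- function(el) do.call(rbind, lapply(recs, `[[`, el))
  ann <- list(recordings = bind("recording"), participants = bind("participants"),
              stories = bind("stories"), gestures = bind("gestures"),
              phases = bind("phases"), ipus = bind("ipus"),
              quotes = bind("quotes"))
  rownames(ann$gestures) <- NULL
  ann <- validate_annotations(ann)
  traces <- do.call(c, lapply(recs, `[[`, "traces"))
  structure(list(ann = ann, traces = traces, truth = bind("truth"),
                 config = cfg),
            class = "sim_corpus")
}

#' @export
print.sim_corpus <- function(x, ...) {
  cat(sprintf("<sim_corpus> %d recording(s), %d stories, %d gestures, %d traces\n",
              nrow(x$ann$recordings), nrow(x$ann$stories),
              nrow(x$ann$gestures), length(x$traces)))
  invisible(x)
}

#' Write a simulated corpus to disk
#'
#' Emits the same formats the readers consume: tier CSVs (tabular dialect),
#' one EDA CSV per participant, and the ground truth as JSON.
#'
#' @param sim a `sim_corpus`
#' @param path output directory
#' @export
write_sim_corpus <- function(sim, path) {
  stopifnot(inherits(sim, "sim_corpus"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_annotations(sim$ann, path)
  for (tr in sim$traces) {
    write_eda(tr, file.path(path, sprintf("eda_%s.csv", tr$participant_id)))
  }
  jsonlite::write_json(sim$truth, file.path(path, "truth.json"),
                       dataframe = "rows", digits = NA, na = "null")
  invisible(path)
}
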
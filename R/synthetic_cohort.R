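#' Population configuration for the synthetic cohort
#'
#' Hyperparameters of the generative population. Working-memory capacity
#' (`wm`) lives on the OSPAN scale (0-75). The cohort is a mixture of
#' learners, whose correct-accumulator (response = stimulus) log drifts
#' rise within and across sessions with a slope that increases with WM,
#' and disengaged non-learners with flat, low, WM-independent drifts and
#' lower boundaries (so their choices sit exactly at chance and their
#' responses are fast). All drift/boundary parameters are on the log
#' scale (log link keeps them strictly positive); gains are total
#' log-scale changes across the six blocks of a session.
#'
#' @param wm_mean,wm_sd truncated-normal moments of latent WM on `[0, 75]`.
#' @param learner_rate marginal probability of being a learner at
#'   `wm = wm_mean`.
#' @param learner_wm_slope logit-scale increase in learner probability per
#'   OSPAN point.
#' @param drift_correct_base learner correct log drift, session 1 block 1.
#' @param drift_incorrect learner incorrect log drift (flat).
#' @param session_gain per-session additive gain on correct log drift.
#' @param block_gain per-session total within-session rise of correct
#'   log drift (block 1 to block 6).
#' @param wm_block_gain extra within-session rise per OSPAN point above
#'   `wm_mean` (the WM-to-learning coupling; set 0 for a null cohort).
#' @param wm_session_gain extra per-session gain per OSPAN point.
#' @param boundary_learner,boundary_nonlearner log boundaries.
#' @param drift_nonlearner non-learner log drift, all accumulators.
#' @param sd_intercept,sd_block_gain,sd_incorrect,sd_boundary participant
#'   SDs of the corresponding log-scale parameters.
#' @param delta_meanlog,delta_sdlog log-normal non-decision offset, per
#'   participant x stimulus category, seconds.
#' @param math_accuracy_learner,math_accuracy_nonlearner probability of a
#'   correct answer on each OSPAN arithmetic problem.
#' @param ospan_recall_slope logistic slope of perfect span recall vs the
#'   gap between latent WM and a span-specific difficulty threshold; the
#'   thresholds are spaced so the expected OSPAN score tracks latent WM.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(wm_mean = 45, wm_sd = 15,
                          learner_rate = 0.68, learner_wm_slope = 0.03,
                          drift_correct_base = log(0.85),
                          drift_incorrect = log(0.55),
                          session_gain = c(0, 0.35, 0.55),
                          block_gain = c(0.45, 0.30, 0.25),
                          wm_block_gain = 0.006,
                          wm_session_gain = c(0, 0.004, 0.003),
                          boundary_learner = log(1.6),
                          boundary_nonlearner = log(1.0),
                          drift_nonlearner = log(0.5),
                          sd_intercept = 0.15, sd_block_gain = 0.08,
                          sd_incorrect = 0.10, sd_boundary = 0.10,
                          delta_meanlog = log(0.35), delta_sdlog = 0.10,
                          math_accuracy_learner = 0.90,
                          math_accuracy_nonlearner = 0.79,
                          ospan_recall_slope = 0.2) {
  cfg <- as.list(environment())
  if (cfg$wm_sd <= 0 || cfg$sd_intercept < 0 || cfg$sd_block_gain < 0 ||
      cfg$sd_incorrect < 0 || cfg$sd_boundary < 0 || cfg$delta_sdlog < 0) {
    stop("population SDs must be positive", call. = FALSE)
  }
  if (cfg$learner_rate < 0 || cfg$learner_rate > 1 ||
      cfg$math_accuracy_learner < 0 || cfg$math_accuracy_learner > 1 ||
      cfg$math_accuracy_nonlearner < 0 || cfg$math_accuracy_nonlearner > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

#' @export
`[.cohort` <- function(x, i) {
  structure(unclass(x)[i], class = "cohort", config = attr(x, "config"))
}

rtruncnorm01 <- function(n, mean, sd, lo, hi) {
  # inverse-CDF truncated normal
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Sample a synthetic participant cohort
#'
#' Draws latent WM, learner status, and per-participant drift/boundary
#' trajectories and non-decision offsets for three sessions and six
#' blocks. Trajectories are stored at block resolution (one value per
#' block); the fitted model's smoothness assumption lives in the
#' inference module, not in the generator.
#'
#' @param n_participants cohort size.
#' @param config a [cohort_config()].
#' @param rng_seed integer seed; identical (config, seed) pairs give
#'   byte-identical cohorts.
#' @return A list of class `cohort`; each element holds `participant_id`,
#'   `wm_latent`, `learner_flag`, `log_mu` (session x response x stimulus
#'   x block array), `log_b` (session x response x block), and `delta`
#'   (one offset per stimulus category, seconds).
#' @export
sample_cohort <- function(n_participants, config = cohort_config(),
                          rng_seed = 1L) {
  stopifnot(inherits(config, "cohort_config"), n_participants >= 1)
  with_seed(rng_seed, {
    n <- as.integer(n_participants)
    wm <- rtruncnorm01(n, config$wm_mean, config$wm_sd, 0, 75)
    wmc <- wm - config$wm_mean
    p_learn <- stats::plogis(stats::qlogis(config$learner_rate) +
                               config$learner_wm_slope * wmc)
    learner <- stats::runif(n) < p_learn
    out <- vector("list", n)
    for (i in seq_len(n)) {
      log_mu <- array(NA_real_, c(3, 4, 4, 6))
      log_b <- array(NA_real_, c(3, 4, 6))
      frac <- (0:5) / 5
      if (learner[i]) {
        icpt <- stats::rnorm(1, 0, config$sd_intercept)
        slope_dev <- stats::rnorm(1, 0, config$sd_block_gain)
        off_drift <- stats::rnorm(1, 0, config$sd_incorrect)
        bnd <- config$boundary_learner + stats::rnorm(1, 0, config$sd_boundary)
        for (ses in 1:3) {
          rise <- (config$block_gain[ses] + config$wm_block_gain * wmc[i] +
                     slope_dev) * frac
          corr <- config$drift_correct_base + icpt +
            config$session_gain[ses] + config$wm_session_gain[ses] * wmc[i] +
            rise
          for (d in 1:4) for (s in 1:4) {
            log_mu[ses, d, s, ] <-
              if (d == s) corr else config$drift_incorrect + off_drift
          }
          log_b[ses, , ] <- bnd
        }
      } else {
        lev <- config$drift_nonlearner + stats::rnorm(1, 0, config$sd_incorrect)
        bnd <- config$boundary_nonlearner +
          stats::rnorm(1, 0, config$sd_boundary)
        log_mu[] <- lev
        log_b[] <- bnd
      }
      delta <- stats::rlnorm(4, config$delta_meanlog, config$delta_sdlog)
      out[[i]] <- list(participant_id = sprintf("P%03d", i),
                       wm_latent = wm[i], learner_flag = learner[i],
                       log_mu = log_mu, log_b = log_b, delta = delta)
    }
    structure(out, class = "cohort", config = config)
  })
}

#' Simulate one categorization trial batch from latent parameters
#'
#' Runs the four-accumulator race for a set of (session, block, stimulus)
#' slots of one participant. Generalization blocks (block >
#' `blocks_per_session`) reuse the final training block's parameters:
#' trajectories are block-resolution and no within-block learning is
#' modelled.
#'
#' @param latent one element of a [sample_cohort()] cohort.
#' @param session session index (scalar).
#' @param block integer vector of block indices.
#' @param tone_category integer vector of stimulus categories.
#' @return list with `response` and `rt` vectors.
#' @export
simulate_trial <- function(latent, session, block, tone_category) {
  n <- length(tone_category)
  blk <- pmin(block, dim(latent$log_mu)[4])
  mu <- matrix(NA_real_, n, 4)
  b <- matrix(NA_real_, n, 4)
  for (d in 1:4) {
    mu[, d] <- exp(latent$log_mu[cbind(session, d, tone_category, blk)])
    b[, d] <- exp(latent$log_b[cbind(session, d, blk)])
  }
  simulate_race(mu, b, delta = latent$delta[tone_category])
}

#' Simulate the full three-session experiment for a cohort
#'
#' Generates a seeded per-participant, per-session trial order and runs
#' the race simulator for every scheduled slot, including the
#' feedback-free generalization block.
#'
#' @param cohort from [sample_cohort()].
#' @param design a [session_design()].
#' @param rng_seed integer seed.
#' @param grid stimulus grid; defaults to [make_stimulus_grid()].
#' @return A tibble of trial records: `participant_id`, `session`,
#'   `block`, `phase`, `trial_index`, `tone_category`, `speaker_id`,
#'   `syllable`, `response`, `rt`, `feedback`, `correct`.
#' @export
simulate_experiment <- function(cohort, design = session_design(),
                                rng_seed = 1L,
                                grid = make_stimulus_grid()) {
  stopifnot(inherits(cohort, "cohort"))
  seeds <- child_seeds(rng_seed, length(cohort) * design$n_sessions + 1L)
  with_seed(seeds[length(seeds)], {
    res <- vector("list", length(cohort) * design$n_sessions)
    k <- 0L
    for (i in seq_along(cohort)) {
      for (ses in seq_len(design$n_sessions)) {
        k <- k + 1L
        sq <- make_trial_sequence(design, grid, session = ses,
                                  rng_seed = seeds[k])
        sim <- simulate_trial(cohort[[i]], ses, sq$block, sq$tone_category)
        res[[k]] <- tibble::tibble(
          participant_id = cohort[[i]]$participant_id,
          session = ses, block = sq$block, phase = sq$phase,
          trial_index = sq$trial_index,
          tone_category = sq$tone_category, speaker_id = sq$speaker_id,
          syllable = sq$syllable, response = sim$response, rt = sim$rt,
          feedback = sq$feedback,
          correct = sim$response == sq$tone_category)
      }
    }
    dplyr::bind_rows(res)
  })
}

#' Simulate one participant's operation-span task
#'
#' Fifteen complex-span trials, three at each span length 3-7. Each trial
#' is recalled perfectly with probability
#' `plogis(a * (wm - c))`, where the difficulty threshold `c` of the t-th
#' easiest trial sits at the midpoint of the score that trial adds, so
#' that with a steep slope the expected score equals the latent WM value
#' and at the default slope the two remain strongly correlated. Imperfect
#' recall corrupts one letter (the scoring rule is all-or-nothing, so any
#' corruption suffices). Arithmetic accuracy is simulated per problem and
#' recorded but never used for filtering.
#'
#' @param latent one cohort element.
#' @param config the [cohort_config()] used to build the cohort.
#' @param rng_seed integer seed.
#' @return list with `records` (a tibble of 15 `OspanRecord` rows with
#'   list-columns `presented_letters` / `recalled_letters`) and the
#'   integer `score`.
#' @export
simulate_ospan <- function(latent, config = cohort_config(), rng_seed = 1L) {
  pool <- c("B", "C", "D", "F", "G", "H", "J", "K", "L", "N", "P", "R")
  with_seed(rng_seed, {
    len <- rep(3:7, each = 3)
    thr <- cumsum(len) - len / 2
    a <- config$ospan_recall_slope
    p_recall <- stats::plogis(a * (latent$wm_latent - thr))
    p_math <- if (latent$learner_flag) config$math_accuracy_learner
              else config$math_accuracy_nonlearner
    ord <- sample.int(15)  # presentation order of the difficulty levels
    rec <- vector("list", 15)
    for (t in seq_len(15)) {
      j <- ord[t]
      L <- len[j]
      presented <- sample(pool, L)
      if (stats::runif(1) < p_recall[j]) {
        recalled <- presented
      } else {
        recalled <- presented
        pos <- sample.int(L, 1)
        recalled[pos] <- sample(setdiff(pool, presented), 1)
      }
      rec[[t]] <- tibble::tibble(
        trial_index = t, span_length = L,
        presented_letters = list(presented),
        recalled_letters = list(recalled),
        n_math_correct = stats::rbinom(1, L, p_math))
    }
    records <- dplyr::bind_rows(rec)
    list(records = records, score = ospan_score(records))
  })
}

#' OSPAN scores for a whole cohort
#'
#' @param cohort from [sample_cohort()].
#' @param config the matching [cohort_config()].
#' @param rng_seed integer seed.
#' @return tibble with `participant_id`, `ospan_score`.
#' @export
simulate_cohort_ospan <- function(cohort, config = cohort_config(),
                                  rng_seed = 1L) {
  seeds <- child_seeds(rng_seed, length(cohort))
  tibble::tibble(
    participant_id = vapply(cohort, `[[`, "", "participant_id"),
    ospan_score = vapply(seq_along(cohort), function(i) {
      simulate_ospan(cohort[[i]], config, seeds[i])$score
    }, 0))
}
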
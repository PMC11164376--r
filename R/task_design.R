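#' Session design for the three-session tone-learning task
#'
#' Encodes the scaffolding shared by the simulator and the analysis code:
#' three sessions, each with six feedback training blocks of 40 trials
#' (every training stimulus once per block) followed by one feedback-free
#' generalization block of 40 held-out stimuli. The inter-session gaps
#' (about one month, then about two months) are carried as metadata only.
#'
#' @param n_sessions number of training sessions.
#' @param blocks_per_session feedback training blocks per session.
#' @param trials_per_block trials per training block; must equal the
#'   number of training stimuli.
#' @param generalization_trials trials in the generalization block; must
#'   equal the number of held-out stimuli.
#' @param intersession_gaps_days metadata: days between adjacent sessions.
#' @return An object of class `session_design` (a list).
#' @export
session_design <- function(n_sessions = 3L, blocks_per_session = 6L,
                           trials_per_block = 40L,
                           generalization_trials = 40L,
                           intersession_gaps_days = c(31, 61)) {
  stopifnot(n_sessions >= 1, blocks_per_session >= 1,
            trials_per_block >= 1, generalization_trials >= 0)
  structure(
    list(n_sessions = as.integer(n_sessions),
         blocks_per_session = as.integer(blocks_per_session),
         trials_per_block = as.integer(trials_per_block),
         generalization_trials = as.integer(generalization_trials),
         chance_probability = 0.25,
         intersession_gaps_days = intersession_gaps_days),
    class = "session_design")
}

# Speaker sexes for the four Mandarin speakers: two female, two male.
speaker_sexes <- c("F", "F", "M", "M")

#' Build the full 80-stimulus grid
#'
#' Four tone categories (1 high-flat, 2 low-rising, 3 low-dipping,
#' 4 high-falling) crossed with four native speakers and five syllable
#' contexts give 80 natural-speech stimuli, 20 per category. Two speakers
#' (one per sex) are used in training; the other two are withheld for the
#' feedback-free generalization block. All stimuli are duration-normalized
#' to 440 ms and RMS-normalized to 70 dB; those constants are carried as
#' metadata and never enter any computation.
#'
#' @param training_speakers integer vector of exactly two speaker ids from
#'   1:4, one female (1 or 2) and one male (3 or 4).
#' @return A tibble with one row per stimulus: `stimulus_id`,
#'   `tone_category`, `speaker_id`, `speaker_sex`, `syllable`, `role`,
#'   `duration_ms`, `level_db`.
#' @export
make_stimulus_grid <- function(training_speakers = c(1L, 3L)) {
  training_speakers <- sort(unique(as.integer(training_speakers)))
  if (length(training_speakers) != 2L ||
      !all(training_speakers %in% 1:4) ||
      length(unique(speaker_sexes[training_speakers])) != 2L) {
    stop("`training_speakers` must be two speaker ids from 1:4, one per sex",
         call. = FALSE)
  }
  syllables <- c("bu", "di", "lu", "ma", "mi")
  grid <- expand.grid(tone_category = 1:4, speaker_id = 1:4,
                      syllable = syllables, stringsAsFactors = FALSE)
  grid <- grid[order(grid$tone_category, grid$speaker_id, grid$syllable), ]
  tibble::tibble(
    stimulus_id = sprintf("T%d_S%d_%s", grid$tone_category,
                          grid$speaker_id, grid$syllable),
    tone_category = as.integer(grid$tone_category),
    speaker_id = as.integer(grid$speaker_id),
    speaker_sex = speaker_sexes[grid$speaker_id],
    syllable = grid$syllable,
    role = ifelse(grid$speaker_id %in% training_speakers,
                  "training", "generalization"),
    duration_ms = 440,
    level_db = 70)
}

#' Schedule one session's trials
#'
#' Lays out the trial slots for a single session: each training block is an
#' independent seeded uniform permutation of the 40 training stimuli (with
#' feedback), and the final generalization block is a permutation of the 40
#' held-out stimuli (no feedback). The generalization block is numbered
#' `blocks_per_session + 1` and tagged with `phase = "generalization"`.
#'
#' @param design a [session_design()].
#' @param grid stimulus grid from [make_stimulus_grid()].
#' @param session session number (metadata column only).
#' @param rng_seed integer seed; identical seeds give identical sequences.
#' @return A tibble with columns `session`, `block`, `phase`,
#'   `trial_index`, `feedback` and the stimulus columns.
#' @export
make_trial_sequence <- function(design, grid, session = 1L, rng_seed = 1L) {
  stopifnot(inherits(design, "session_design"))
  train <- grid[grid$role == "training", ]
  gen <- grid[grid$role == "generalization", ]
  if (nrow(train) != design$trials_per_block ||
      nrow(gen) != design$generalization_trials) {
    stop("stimulus grid is inconsistent with the session design",
         call. = FALSE)
  }
  with_seed(rng_seed, {
    blocks <- lapply(seq_len(design$blocks_per_session), function(b) {
      out <- train[sample.int(nrow(train)), ]
      out$block <- b
      out$phase <- "training"
      out$feedback <- TRUE
      out
    })
    gb <- gen[sample.int(nrow(gen)), ]
    gb$block <- design$blocks_per_session + 1L
    gb$phase <- "generalization"
    gb$feedback <- FALSE
    seq_tbl <- dplyr::bind_rows(c(blocks, list(gb)))
    seq_tbl$session <- as.integer(session)
    seq_tbl$trial_index <- seq_len(nrow(seq_tbl))
    dplyr::select(tibble::as_tibble(seq_tbl),
                  "session", "block", "phase", "trial_index", "feedback",
                  dplyr::everything())
  })
}
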
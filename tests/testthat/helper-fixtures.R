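# Shared fixtures. The MCMC fits are the expensive pieces of the suite,
# so they are built once on first use and cached for every test file.
fixture_env <- new.env(parent = emptyenv())

get_fixture <- function(name, build) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, build(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

# 20-participant single-session recovery fit at reduced MCMC length.
recovery_fixture <- function() {
  get_fixture("recovery", function() {
    ch <- sample_cohort(20, cohort_config(), rng_seed = 11)
    trials <- trim_rt(simulate_experiment(ch, rng_seed = 12))
    s1 <- trials[trials$session == 1, ]
    cfg <- ddm_model_config(iterations = 1500, burn_in = 500,
                            thinning = 2)
    fit <- fit_session(s1, cfg, rng_seed = 13)
    true_log_drift <- function(sm) {
      ids <- vapply(ch, `[[`, "", "participant_id")
      vapply(seq_len(nrow(sm)), function(k) {
        i <- match(sm$participant_id[k], ids)
        mean(diag(ch[[i]]$log_mu[1, , , sm$block[k]]))
      }, 0)
    }
    list(cohort = ch, trials = trials, s1 = s1, cfg = cfg, fit = fit,
         true_log_drift = true_log_drift)
  })
}

# Small cohort simulated with flat (block-constant) drift trajectories.
flat_fit_fixture <- function() {
  get_fixture("flat_fit", function() {
    cfgc <- cohort_config(block_gain = c(0, 0, 0),
                          wm_block_gain = 0, wm_session_gain = c(0, 0, 0))
    ch <- sample_cohort(10, cfgc, rng_seed = 21)
    trials <- trim_rt(simulate_experiment(ch, rng_seed = 22))
    s1 <- trials[trials$session == 1, ]
    cfg <- ddm_model_config(iterations = 800, burn_in = 300,
                            thinning = 2)
    list(cohort = ch, s1 = s1,
         fit = fit_session(s1, cfg, rng_seed = 23))
  })
}

# One end-to-end run (simulate -> trim -> fit -> drift summary ->
# association model) at demo scale, for a given WM-drift coupling.
run_drift_pipeline <- function(seed, wm_coupling, n = 10) {
  cc <- cohort_config(learner_rate = 1, wm_block_gain = wm_coupling,
                      wm_session_gain = c(0, 0, 0))
  ch <- sample_cohort(n, cc, rng_seed = seed)
  trials <- trim_rt(simulate_experiment(ch, rng_seed = seed + 1000L))
  s1 <- trials[trials$session == 1, ]
  cfg <- ddm_model_config(iterations = 600, burn_in = 250, thinning = 2)
  fit <- fit_session(s1, cfg, rng_seed = seed + 2000L)
  sm <- correct_drift_summary(fit)
  ospan <- simulate_cohort_ospan(ch, cc, rng_seed = seed + 3000L)
  metrics <- behavior_metrics(trials, ospan)
  res <- ddm_parameter_model(sm, metrics$participants, "drift",
                             learners_only = FALSE)
  co <- res$coefficients
  co[co$term == "ospan:block", ]
}
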
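#' Pipeline configuration
#'
#' Bundles every knob of an end-to-end run: design, cohort
#' hyperparameters, MCMC settings, metric constants, which sessions to
#' fit, and one explicit seed per stochastic stage. The object is a plain
#' nested list so it round-trips losslessly through YAML
#' ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param n_participants cohort size.
#' @param rng_seed master seed; per-stage seeds are derived from it once
#'   at construction and stored explicitly.
#' @param design a [session_design()].
#' @param cohort a [cohort_config()].
#' @param mcmc a [ddm_model_config()].
#' @param tail RT trimming tail fraction.
#' @param learner_cutoff learner classification cutoff, percent.
#' @param fit_sessions sessions to fit with the race model (empty vector
#'   to skip DDM fitting).
#' @param learners_only_associations fit the maintenance, generalization
#'   and decision-parameter models on learners only.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_participants = 20L, rng_seed = 1L,
                            design = session_design(),
                            cohort = cohort_config(),
                            mcmc = ddm_model_config(iterations = 1500L,
                                                    burn_in = 500L,
                                                    thinning = 2L),
                            tail = 0.01,
                            learner_cutoff = LEARNER_CUTOFF_PCT,
                            fit_sessions = 1L,
                            learners_only_associations = TRUE) {
  sd4 <- child_seeds(rng_seed, 4L)
  structure(list(
    n_participants = as.integer(n_participants),
    design = unclass(design), cohort = unclass(cohort),
    mcmc = c(unclass(mcmc)[setdiff(names(mcmc), "basis")],
             list(basis = unclass(mcmc$basis))),
    tail = tail, learner_cutoff = learner_cutoff,
    fit_sessions = as.integer(fit_sessions),
    learners_only_associations = learners_only_associations,
    seeds = list(cohort = sd4[1], experiment = sd4[2], ospan = sd4[3],
                 mcmc = sd4[4])),
    class = "pipeline_config")
}

validate_pipeline_config <- function(config) {
  need <- c("n_participants", "design", "cohort", "mcmc", "tail",
            "learner_cutoff", "fit_sessions", "seeds")
  miss <- setdiff(need, names(config))
  if (length(miss)) {
    stop("invalid pipeline config; missing fields: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  sneed <- c("cohort", "experiment", "ospan", "mcmc")
  smiss <- sneed[!vapply(sneed, function(s) {
    !is.null(config$seeds[[s]]) && is.numeric(config$seeds[[s]])
  }, TRUE)]
  if (length(smiss)) {
    stop("every stochastic stage needs an explicit seed; missing: ",
         paste(smiss, collapse = ", "), call. = FALSE)
  }
  invisible(config)
}

rebuild_config <- function(config) {
  config$design <- do.call(session_design,
                           config$design[names(formals(session_design))[
                             names(formals(session_design)) %in%
                               names(config$design)]])
  config$cohort <- do.call(cohort_config, config$cohort[
    names(config$cohort) %in% names(formals(cohort_config))])
  mc <- config$mcmc
  mc$basis <- do.call(basis_spec, mc$basis[
    names(mc$basis) %in% names(formals(basis_spec))])
  config$mcmc <- do.call(ddm_model_config, mc[
    names(mc) %in% names(formals(ddm_model_config))])
  config
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(rapply(unclass(config), identity, how = "replace"),
                   path, precision = 15L)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$fit_sessions <- as.integer(unlist(cfg$fit_sessions) %||% integer())
  cfg$mcmc$basis$interior_knots <-
    as.numeric(unlist(cfg$mcmc$basis$interior_knots))
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> trim -> metrics -> fit (per configured session)
#' -> associate on a synthetic cohort, writing every stage output and a
#' machine-readable manifest to `output_dir`. The run is a pure function
#' of (config, seeds): rerunning with an identical config reproduces
#' identical tables and, with identical seeds, identical MCMC output, so
#' the manifest checksums match across reruns.
#'
#' @param config a [pipeline_config()].
#' @param output_dir run directory (created if needed).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, output_dir, quiet = FALSE) {
  validate_pipeline_config(config)
  cfg <- rebuild_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  files <- character()
  put_csv <- function(x, name) {
    path <- file.path(output_dir, name)
    utils::write.csv(x, path, row.names = FALSE)
    files[[name]] <<- path
    path
  }
  stage <- function(name, expr) {
    say("[", name, "] ...")
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      partial <- list(config = unclass(config), failed_stage = name,
                      error = conditionMessage(e))
      jsonlite::write_json(partial,
                           file.path(output_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      stop("pipeline stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE)
    })
    say(sprintf("[%s] done (%.1fs)", name,
                proc.time()[["elapsed"]] - t0))
    out
  }

  cohort <- stage("simulate", {
    ch <- sample_cohort(cfg$n_participants, cfg$cohort,
                        cfg$seeds$cohort)
    ch
  })
  trials <- stage("experiment", {
    tr <- simulate_experiment(cohort, cfg$design, cfg$seeds$experiment)
    put_csv(tr, "trials.csv")
    tr
  })
  ospan <- stage("ospan", {
    os <- simulate_cohort_ospan(cohort, cfg$cohort, cfg$seeds$ospan)
    put_csv(os, "ospan.csv")
    os
  })
  trimmed <- stage("trim", {
    tt <- trim_rt(trials, cfg$tail)
    put_csv(tt, "trials_trimmed.csv")
    tt
  })
  metrics <- stage("metrics", {
    m <- behavior_metrics(trials, ospan)
    put_csv(m$blocks, "blocks.csv")
    put_csv(m$participants, "participants.csv")
    put_csv(m$maintenance, "maintenance.csv")
    put_csv(m$generalization, "generalization.csv")
    m
  })
  fits <- list()
  summaries <- NULL
  if (length(cfg$fit_sessions)) {
    mseeds <- child_seeds(cfg$seeds$mcmc, max(cfg$fit_sessions))
    for (ses in cfg$fit_sessions) {
      fits[[as.character(ses)]] <- stage(paste0("fit-ddm-s", ses), {
        fit <- fit_session(trimmed[trimmed$session == ses, ],
                           cfg$mcmc, mseeds[ses])
        jsonlite::write_json(
          list(session = ses,
               geweke = fit$diagnostics$geweke,
               acceptance = fit$diagnostics$acceptance),
          file.path(output_dir, sprintf("diagnostics_s%d.json", ses)),
          auto_unbox = TRUE, digits = NA, dataframe = "rows")
        files[[sprintf("diagnostics_s%d.json", ses)]] <-
          file.path(output_dir, sprintf("diagnostics_s%d.json", ses))
        fit
      })
    }
    summaries <- dplyr::bind_rows(lapply(fits, correct_drift_summary))
    put_csv(summaries, "drift_summary.csv")
  }
  assoc <- stage("associate", {
    lo <- isTRUE(cfg$learners_only_associations)
    out <- list(accuracy = accuracy_model(metrics, learners_only = lo),
                maintenance = maintenance_model(metrics),
                generalization = generalization_model(metrics))
    if (!is.null(summaries)) {
      out$drift <- ddm_parameter_model(summaries, metrics$participants,
                                       "drift")
      out$boundary <- ddm_parameter_model(summaries,
                                          metrics$participants,
                                          "boundary")
    }
    for (nm in names(out)) {
      put_csv(out[[nm]]$coefficients, sprintf("model_%s.csv", nm))
    }
    out
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("tonerace")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = rapply(unclass(config), identity, how = "replace"),
    seeds = config$seeds,
    outputs = lapply(files, function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = cohort, trials = trials, ospan = ospan,
                 trimmed = trimmed, metrics = metrics, fits = fits,
                 drift_summaries = summaries, associations = assoc,
                 manifest = manifest))
}
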
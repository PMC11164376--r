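#' Random-intercept linear mixed model by profiled REML
#'
#' Fits `y = X beta + z_participant + e` with a single participant
#' random intercept, `z ~ N(0, sigma_b^2)`, `e ~ N(0, sigma_e^2)`.
#' The variance ratio `lambda = sigma_b^2 / sigma_e^2` is profiled out of
#' the restricted likelihood and optimized on the log scale (with the
#' `lambda = 0` boundary checked explicitly); beta and its covariance come
#' from the generalized-least-squares solve at the optimum. P-values use
#' the normal approximation to the t-statistic, which is noted in the
#' result; with hundreds of residual degrees of freedom the difference
#' from a Satterthwaite-style correction is negligible.
#'
#' @param outcome numeric response vector.
#' @param fixed_design numeric design matrix with named columns
#'   (including the intercept column).
#' @param participant_ids grouping vector, one entry per observation.
#' @param pin_intercept_variance if non-`NULL`, fix `sigma_b^2` at this
#'   value instead of estimating it; `0` reproduces ordinary least
#'   squares exactly.
#' @return An object of class `lmm_result`: `coefficients` (tibble with
#'   `term`, `beta`, `se`, `p`), `varcomp` (participant-intercept and
#'   residual variances), `n_obs`, `n_participants`, `converged`,
#'   `lambda`, `p_method`.
#' @export
fit_random_intercept_lmm <- function(outcome, fixed_design,
                                     participant_ids,
                                     pin_intercept_variance = NULL) {
  y <- as.numeric(outcome)
  X <- as.matrix(fixed_design)
  g <- factor(participant_ids)
  n <- length(y)
  p <- ncol(X)
  stopifnot(nrow(X) == n, length(g) == n)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("singular fixed-effect design; aliased terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  idx <- split(seq_len(n), g)
  ng <- lengths(idx)
  XtX_g <- lapply(idx, function(r) crossprod(X[r, , drop = FALSE]))
  Xty_g <- lapply(idx, function(r) crossprod(X[r, , drop = FALSE], y[r]))
  sx_g <- lapply(idx, function(r) colSums(X[r, , drop = FALSE]))
  sy_g <- vapply(idx, function(r) sum(y[r]), 0)
  yty_g <- vapply(idx, function(r) sum(y[r]^2), 0)

  gls_parts <- function(lambda) {
    cg <- lambda / (1 + lambda * ng)
    A <- matrix(0, p, p)
    cvec <- numeric(p)
    ywy <- 0
    for (k in seq_along(idx)) {
      A <- A + XtX_g[[k]] - cg[k] * tcrossprod(sx_g[[k]])
      cvec <- cvec + Xty_g[[k]] - cg[k] * sx_g[[k]] * sy_g[k]
      ywy <- ywy + yty_g[k] - cg[k] * sy_g[k]^2
    }
    beta <- solve(A, cvec)
    rwr <- max(ywy - sum(beta * cvec), 0)
    list(A = A, beta = beta, rwr = rwr,
         logdetV = sum(log1p(lambda * ng)))
  }
  reml_ll <- function(loglambda) {
    pp <- gls_parts(exp(loglambda))
    if (pp$rwr <= 0) return(-1e300)  # degenerate (zero residual) fit
    sigma2 <- pp$rwr / (n - p)
    -0.5 * ((n - p) * log(sigma2) + pp$logdetV +
              determinant(pp$A, logarithm = TRUE)$modulus)
  }

  converged <- TRUE
  if (!is.null(pin_intercept_variance)) {
    if (pin_intercept_variance < 0) {
      stop("pinned intercept variance must be >= 0", call. = FALSE)
    }
    pp0 <- gls_parts(0)
    sigma2 <- pp0$rwr / (n - p)
    lambda <- if (sigma2 > 0) pin_intercept_variance / sigma2 else 0
    pp <- gls_parts(lambda)
  } else {
    opt <- stats::optimize(reml_ll, c(-12, 12), maximum = TRUE)
    lambda <- exp(opt$maximum)
    if (reml_ll(log(1e-12)) >= opt$objective) lambda <- 0
    if (abs(opt$maximum - 12) < 1e-6) converged <- FALSE
    pp <- gls_parts(lambda)
  }
  sigma2 <- pp$rwr / (n - p)
  covb <- sigma2 * solve(pp$A)
  se <- unname(sqrt(pmax(diag(covb), 0)))
  z <- ifelse(se > 0, pp$beta / se, sign(pp$beta) * Inf)
  pv <- 2 * stats::pnorm(-abs(z))
  pv[pp$beta == 0 & se == 0] <- NA_real_
  structure(list(
    coefficients = tibble::tibble(
      term = colnames(X) %||% paste0("x", seq_len(p)),
      beta = as.numeric(pp$beta), se = se, p = pv),
    varcomp = c(participant_intercept = lambda * sigma2,
                residual = sigma2),
    n_obs = n, n_participants = nlevels(g), converged = converged,
    lambda = lambda, p_method = "normal approximation"),
    class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat("Random-intercept LMM (REML), ", x$n_obs, " obs / ",
      x$n_participants, " participants\n", sep = "")
  print(as.data.frame(x$coefficients), digits = 3)
  cat("Variance components: intercept ",
      signif(x$varcomp[["participant_intercept"]], 3), ", residual ",
      signif(x$varcomp[["residual"]], 3),
      " (p-values: ", x$p_method, ")\n", sep = "")
  invisible(x)
}

# Build a treatment-contrast design matrix; drops the session factor when
# the data hold a single session so single-session pipelines still fit.
association_design <- function(data, with_block = TRUE) {
  data$session <- factor(data$session)
  f <- if (nlevels(data$session) > 1) {
    if (with_block) ~ ospan * block * session else ~ ospan * session
  } else {
    if (with_block) ~ ospan * block else ~ospan
  }
  stats::model.matrix(f, data)
}

filter_learners <- function(data, participants, learners_only) {
  data <- dplyr::inner_join(
    data, participants[, c("participant_id", "ospan_score", "learner")],
    by = "participant_id")
  if (learners_only) data <- data[data$learner == "learner", ]
  data$ospan <- data$ospan_score
  data
}

#' Accuracy association model
#'
#' Random-intercept LMM of per-block training accuracy (percent) on
#' OSPAN score (raw, continuous), block (numeric 1-6), session
#' (categorical, baseline session 1) and all interactions. Coefficient
#' units: percentage points per OSPAN unit.
#'
#' @param metrics output of [behavior_metrics()].
#' @param learners_only restrict to classified learners.
#' @return an `lmm_result`.
#' @export
accuracy_model <- function(metrics, learners_only = FALSE) {
  d <- metrics$blocks[metrics$blocks$phase == "training", ]
  d <- filter_learners(d, metrics$participants, learners_only)
  X <- association_design(d)
  fit_random_intercept_lmm(d$accuracy_pct, X, d$participant_id)
}

#' Maintenance association model
#'
#' LMM of the adjacent-block accuracy deltas on time (transition, 1-to-2
#' baseline), delay (delay baseline), OSPAN and all interactions, with a
#' participant random intercept. Learners only by default.
#'
#' @param metrics output of [behavior_metrics()].
#' @param learners_only restrict to classified learners.
#' @return an `lmm_result`.
#' @export
maintenance_model <- function(metrics, learners_only = TRUE) {
  d <- filter_learners(metrics$maintenance, metrics$participants,
                       learners_only)
  d <- d[!is.na(d$delta_pct), ]
  d$time <- factor(d$transition)
  d$delay <- factor(d$delay, levels = c("delay", "no_delay"))
  X <- stats::model.matrix(~ ospan * time * delay, d)
  fit_random_intercept_lmm(d$delta_pct, X, d$participant_id)
}

#' Generalization association model
#'
#' LMM of the generalization score (test accuracy minus final-block
#' accuracy, percentage points) on session (baseline 1), OSPAN and their
#' interaction, with a participant random intercept. Learners only by
#' default.
#'
#' @param metrics output of [behavior_metrics()].
#' @param learners_only restrict to classified learners.
#' @return an `lmm_result`.
#' @export
generalization_model <- function(metrics, learners_only = TRUE) {
  d <- filter_learners(metrics$generalization, metrics$participants,
                       learners_only)
  d <- d[!is.na(d$generalization_score_pct), ]
  X <- association_design(d, with_block = FALSE)
  fit_random_intercept_lmm(d$generalization_score_pct, X,
                           d$participant_id)
}

#' Decision-parameter association model
#'
#' LMM of posterior-mean decision parameters (correct-accumulator drift
#' or boundary, from [correct_drift_summary()]) on OSPAN, block, session
#' and all interactions, with a participant random intercept. Learners
#' only by default, matching the behavioural analyses.
#'
#' @param summaries (possibly row-bound over sessions) output of
#'   [correct_drift_summary()].
#' @param participants participant table from [behavior_metrics()].
#' @param parameter `"drift"` or `"boundary"`.
#' @param learners_only restrict to classified learners.
#' @return an `lmm_result`.
#' @export
ddm_parameter_model <- function(summaries, participants,
                                parameter = c("drift", "boundary"),
                                learners_only = TRUE) {
  parameter <- match.arg(parameter)
  d <- filter_learners(summaries, participants, learners_only)
  X <- association_design(d)
  fit_random_intercept_lmm(d[[parameter]], X, d$participant_id)
}
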
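#' B-spline basis specification over training blocks
#'
#' The drift and boundary trajectories are modelled as smooth functions
#' of training block, represented in a B-spline basis over the block axis
#' (1 to 6 by default). The default is a cubic basis with interior knots
#' at blocks 2-5. Degree 0 yields an indicator (one-basis-per-interval)
#' representation, with `interior_knots` acting as left interval edges.
#'
#' @param degree spline degree (default cubic).
#' @param interior_knots interior knot positions on the block axis. The
#'   default (none) gives a cubic polynomial trend over the six blocks:
#'   with only six support points, denser knot grids over-parameterize
#'   the trajectories and measurably degrade parameter recovery.
#' @param n_blocks number of training blocks.
#' @return list of class `basis_spec` with an `n_basis` field.
#' @export
basis_spec <- function(degree = 3L, interior_knots = numeric(0),
                       n_blocks = 6L) {
  degree <- as.integer(degree)
  stopifnot(degree >= 0, n_blocks >= 2)
  if (length(interior_knots) &&
      (any(interior_knots < 1) || any(interior_knots > n_blocks))) {
    stop("interior knots must lie on the block axis", call. = FALSE)
  }
  n_basis <- if (degree == 0L) length(interior_knots) + 1L
             else degree + 1L + length(interior_knots)
  structure(list(degree = degree, interior_knots = interior_knots,
                 n_blocks = as.integer(n_blocks), n_basis = n_basis),
            class = "basis_spec")
}

#' Evaluate the block basis matrix
#'
#' Returns the `n_blocks x n_basis` matrix of basis functions evaluated at
#' blocks `1:n_blocks`. B-spline bases form a partition of unity (each row
#' sums to 1) and are non-negative, so a constant coefficient vector gives
#' a constant trajectory.
#'
#' @param spec a [basis_spec()].
#' @return numeric matrix.
#' @export
build_basis <- function(spec) {
  stopifnot(inherits(spec, "basis_spec"))
  x <- seq_len(spec$n_blocks)
  if (spec$degree == 0L) {
    breaks <- c(1, sort(spec$interior_knots), Inf)
    idx <- findInterval(x, breaks)
    B <- matrix(0, length(x), spec$n_basis)
    B[cbind(seq_along(x), idx)] <- 1
    return(B)
  }
  ord <- spec$degree + 1L
  knots <- c(rep(1, ord), sort(spec$interior_knots), rep(spec$n_blocks, ord))
  if (length(knots) < 2L * ord) {
    stop("too few knots for the requested degree", call. = FALSE)
  }
  splines::splineDesign(knots, x, ord = ord)
}

#' MCMC configuration for the race-model fit
#'
#' @param iterations total MCMC iterations.
#' @param burn_in initial iterations discarded.
#' @param thinning keep every `thinning`-th post-burn-in draw.
#' @param basis a [basis_spec()] for the block trajectories.
#' @param pop_prior_sd prior SD of population spline coefficients
#'   (log scale).
#' @param smooth_sd SD of the first-difference smoothing prior on
#'   adjacent population coefficients; smaller values give flatter
#'   trajectories.
#' @param dev_a0,dev_b0 inverse-gamma hyperprior on the participant
#'   coefficient-deviation variances.
#' @param target_accept Metropolis target acceptance rate (proposal
#'   scales adapt toward it during burn-in).
#' @param init_prop_sd initial random-walk proposal SD.
#' @param delta_frac upper bound of the uniform non-decision-offset prior
#'   as a fraction of the minimum observed RT per participant x stimulus.
#' @param monitor_participant_frac fraction of participant-level drift
#'   chains monitored by the Geweke diagnostic.
#' @param include_generalization include feedback-free generalization
#'   trials in the fit (excluded by default).
#' @return list of class `ddm_model_config`.
#' @export
ddm_model_config <- function(iterations = 6000L, burn_in = 2000L,
                             thinning = 5L, basis = basis_spec(),
                             pop_prior_sd = 2, smooth_sd = 1,
                             dev_a0 = 1, dev_b0 = 2,
                             target_accept = 0.3, init_prop_sd = 0.15,
                             delta_frac = 0.995,
                             monitor_participant_frac = 0.1,
                             include_generalization = FALSE) {
  stopifnot(iterations > burn_in, thinning >= 1,
            inherits(basis, "basis_spec"))
  structure(as.list(environment()), class = "ddm_model_config")
}

#' Retained draw count implied by an MCMC configuration
#' @param config a [ddm_model_config()].
#' @return integer, `(iterations - burn_in) / thinning` (floored).
#' @export
n_retained <- function(config) {
  as.integer((config$iterations - config$burn_in) %/% config$thinning)
}

#' Fit the hierarchical race model to one session
#'
#' Metropolis-within-Gibbs sampler for the four-alternative
#' inverse-Gaussian race model with longitudinal structure: log drifts
#' `mu[d, s](block)` (one trajectory per response x stimulus pair) and
#' log boundaries `b[d](block)` (response only) are population B-spline
#' curves plus zero-mean Gaussian participant deviations whose variances
#' carry inverse-gamma hyperpriors; non-decision offsets `delta[i, s]`
#' have uniform priors on `(0, delta_frac * min observed RT)` per
#' participant x stimulus category. All participants (learners and
#' non-learners) are fit jointly; sessions are fit separately.
#'
#' Coefficient blocks are updated by adaptive random-walk Metropolis
#' (scales tuned toward `target_accept` during burn-in); the deviation
#' variances are conjugate Gibbs updates.
#'
#' @param trials trimmed trial table for a single session (columns
#'   `participant_id`, `session`, `block`, `phase`, `tone_category`,
#'   `response`, `rt`).
#' @param model_config a [ddm_model_config()].
#' @param rng_seed integer seed.
#' @return An object of class `ddm_fit`: retained draws, posterior means,
#'   pointwise 95% credible intervals, Geweke diagnostics, acceptance
#'   rates, and the configuration.
#' @export
fit_session <- function(trials, model_config = ddm_model_config(),
                        rng_seed = 1L) {
  cfg <- model_config
  stopifnot(inherits(cfg, "ddm_model_config"))
  if (!cfg$include_generalization && "phase" %in% names(trials)) {
    trials <- trials[trials$phase == "training", ]
  }
  ses <- unique(trials$session)
  if (length(ses) != 1L) {
    stop("`fit_session` expects trials from exactly one session",
         call. = FALSE)
  }
  pid <- factor(trials$participant_id)
  ii <- as.integer(pid)
  n <- nlevels(pid)
  sv <- as.integer(trials$tone_category)
  dv <- as.integer(trials$response)
  blk <- as.integer(trials$block)
  rt <- as.numeric(trials$rt)
  ntr <- length(rt)
  nblk <- cfg$basis$n_blocks
  if (any(blk < 1 | blk > nblk)) {
    stop("block indices exceed the basis range", call. = FALSE)
  }

  B <- build_basis(cfg$basis)
  K <- ncol(B)
  Btr <- B[blk, , drop = FALSE]

  # uniform prior upper bounds for delta, per participant x stimulus
  ub <- matrix(NA_real_, n, 4)
  for (i in seq_len(n)) for (s in 1:4) {
    r <- rt[ii == i & sv == s]
    ub[i, s] <- if (length(r)) cfg$delta_frac * min(r) else NA_real_
  }
  if (anyNA(ub)) {
    warning("empty participant x stimulus cells: prior-only updates used")
    ub[is.na(ub)] <- cfg$delta_frac * min(rt)
  }

  # smoothing + ridge prior precision for population coefficients
  D <- diff(diag(K))
  P0 <- diag(1 / cfg$pop_prior_sd^2, K) + crossprod(D) / cfg$smooth_sd^2

  nret <- n_retained(cfg)

  with_seed(rng_seed, {
    # ---- moment-based initialization ----------------------------------
    # Crude per-participant estimates put the chain near the data before
    # sampling starts: choice fractions set the relative drifts (in a
    # race, win probability grows with an accumulator's drift share) and
    # the mean decision time sets the overall speed scale b / sum(mu).
    # Since the basis is a partition of unity, a constant coefficient
    # vector encodes a block-constant trajectory.
    b_init <- 1.2
    delta <- 0.9 * ub
    est_cell <- function(r, i, s) {
      p_hat <- (tabulate(dv[r], 4) + 0.5) / (length(r) + 2)
      tau_bar <- max(mean(rt[r] - delta[i, s]), 0.05)
      log(pmin(pmax((b_init / tau_bar) * p_hat, 0.15), 6))
    }
    mid <- nblk / 2
    lmu_hat <- array(log(0.8), c(4, 4, nblk, n))  # [d, s, block, i]
    for (i in seq_len(n)) for (s in 1:4) {
      r <- which(ii == i & sv == s)
      if (!length(r)) next
      re <- r[blk[r] <= mid]
      rl <- r[blk[r] > mid]
      if (length(re) >= 10 && length(rl) >= 10) {
        # early/late split gives each trajectory a linear starting trend
        le <- est_cell(re, i, s)
        ll0 <- est_cell(rl, i, s)
        t_e <- mean(blk[re]); t_l <- mean(blk[rl])
        for (t in seq_len(nblk)) {
          lmu_hat[, s, t, i] <- le + (ll0 - le) * (t - t_e) / (t_l - t_e)
        }
      } else {
        lmu_hat[, s, , i] <- est_cell(r, i, s)
      }
    }
    lmu_hat <- pmin(pmax(lmu_hat, log(0.1)), log(8))
    # project curves onto the basis (exact for trends inside its span)
    th_mu <- array(0, c(K, 4, 4))     # population log-drift coefficients
    u_mu <- array(0, c(K, 4, 4, n))
    for (d in 1:4) for (s in 1:4) {
      popc <- rowMeans(matrix(lmu_hat[d, s, , ], nblk))
      th_mu[, d, s] <- qr.solve(B, popc)
      for (i in seq_len(n)) {
        u_mu[, d, s, i] <- pmin(pmax(qr.solve(B, lmu_hat[d, s, , i] -
                                                popc), -1.5), 1.5)
      }
    }
    th_b <- matrix(log(b_init), K, 4) # population log-boundary coefficients
    u_b <- array(0, c(K, 4, n))
    # local (participant x cell) deviation variances: a disengaged
    # participant deviates hugely in a few cells (the correct-response
    # accumulators) while matching the population elsewhere, so global or
    # participant-level variances over-shrink exactly those cells; the
    # cell-level inverse-gamma mixture gives the deviations heavy-tailed
    # marginals that let outlying cells escape
    sig2_mu <- array(0.25, c(4, 4, n))
    sig2_b <- matrix(0.25, 4, n)

    # per-row linear-predictor caches
    lpP_mu <- matrix(0, ntr, 4); lpU_mu <- matrix(0, ntr, 4)
    lpP_b <- matrix(0, ntr, 4); lpU_b <- matrix(0, ntr, 4)
    for (d in 1:4) {
      for (s in 1:4) {
        r <- which(sv == s)
        lpP_mu[r, d] <- Btr[r, , drop = FALSE] %*% th_mu[, d, s]
      }
      lpP_b[, d] <- Btr %*% th_b[, d]
    }
    mu_mat <- exp(lpP_mu + lpU_mu)
    b_mat <- exp(lpP_b + lpU_b)
    dt <- rt - delta[cbind(ii, sv)]
    ll <- as.numeric(race_ll_rows(mu_mat, b_mat, dt, dv))

    rows_s <- lapply(1:4, function(s) which(sv == s))
    rows_i <- lapply(seq_len(n), function(i) which(ii == i))
    rows_is <- lapply(seq_len(n), function(i) {
      lapply(1:4, function(s) which(ii == i & sv == s))
    })

    # adaptive proposal log-scales and acceptance counters
    ls_popmu <- matrix(log(cfg$init_prop_sd), 4, 4)
    ls_popb <- rep(log(cfg$init_prop_sd), 4)
    ls_devmu <- array(log(cfg$init_prop_sd * 2), c(4, 4, n))
    ls_devb <- matrix(log(cfg$init_prop_sd * 2), 4, n)
    ls_popmu2 <- ls_popmu; ls_popb2 <- ls_popb
    ls_devmu2 <- ls_devmu; ls_devb2 <- ls_devb
    ls_delta <- matrix(log(0.02), n, 4)
    ls_joint <- matrix(c(log(0.08), log(0.08), log(0.01)), 3, n)
    acc_cnt <- c(popmu = 0, popb = 0, devmu = 0, devb = 0, delta = 0,
                 joint = 0)
    try_cnt <- acc_cnt

    # draw storage
    mu_draws <- array(NA_real_, c(nret, n, 4, 4, nblk))
    b_draws <- array(NA_real_, c(nret, n, 4, nblk))
    delta_draws <- array(NA_real_, c(nret, n, 4))
    mu_pop_draws <- array(NA_real_, c(nret, 4, 4, nblk))
    b_pop_draws <- array(NA_real_, c(nret, 4, nblk))
    sig_draws <- array(NA_real_, c(nret, n, 2))  # [, , drift | boundary]

    kr <- 0L
    for (it in seq_len(cfg$iterations)) {
      adapting <- it <= cfg$burn_in
      gam <- min(0.2, 2 / sqrt(it))

      # -- population drift coefficients, one (d, s) block at a time.
      # Each block gets a K-dimensional random-walk proposal plus a
      # scalar proposal along the constant direction (a uniform shift of
      # the whole trajectory), which mixes the overall level much faster
      # than coordinate-wise moves alone.
      for (d in 1:4) for (s in 1:4) {
        r <- rows_s[[s]]
        for (mv in 1:2) {
          th <- th_mu[, d, s]
          step <- if (mv == 1) exp(ls_popmu[d, s]) * stats::rnorm(K)
                  else rep(exp(ls_popmu2[d, s]) * stats::rnorm(1), K)
          prop <- th + step
          newlp <- as.numeric(Btr[r, , drop = FALSE] %*% prop)
          mu_sub <- mu_mat[r, , drop = FALSE]
          mu_sub[, d] <- exp(newlp + lpU_mu[r, d])
          newll <- race_ll_rows(mu_sub, b_mat[r, , drop = FALSE],
                                dt[r], dv[r])
          lr <- sum(newll) - sum(ll[r]) -
            0.5 * (crossprod(prop, P0 %*% prop) - crossprod(th, P0 %*% th))
          acc <- is.finite(lr) && log(stats::runif(1)) < lr
          if (acc) {
            th_mu[, d, s] <- prop
            lpP_mu[r, d] <- newlp
            mu_mat[r, d] <- mu_sub[, d]
            ll[r] <- newll
          }
          try_cnt["popmu"] <- try_cnt["popmu"] + 1
          acc_cnt["popmu"] <- acc_cnt["popmu"] + acc
          if (adapting) {
            if (mv == 1) ls_popmu[d, s] <- ls_popmu[d, s] +
                gam * (acc - cfg$target_accept)
            else ls_popmu2[d, s] <- ls_popmu2[d, s] +
                gam * (acc - cfg$target_accept)
          }
        }
      }

      # -- population boundary coefficients, one response at a time ------
      for (d in 1:4) {
        for (mv in 1:2) {
          th <- th_b[, d]
          step <- if (mv == 1) exp(ls_popb[d]) * stats::rnorm(K)
                  else rep(exp(ls_popb2[d]) * stats::rnorm(1), K)
          prop <- th + step
          newlp <- as.numeric(Btr %*% prop)
          b_sub <- b_mat
          b_sub[, d] <- exp(newlp + lpU_b[, d])
          newll <- race_ll_rows(mu_mat, b_sub, dt, dv)
          lr <- sum(newll) - sum(ll) -
            0.5 * (crossprod(prop, P0 %*% prop) - crossprod(th, P0 %*% th))
          acc <- is.finite(lr) && log(stats::runif(1)) < lr
          if (acc) {
            th_b[, d] <- prop
            lpP_b[, d] <- newlp
            b_mat[, d] <- b_sub[, d]
            ll <- as.numeric(newll)
          }
          try_cnt["popb"] <- try_cnt["popb"] + 1
          acc_cnt["popb"] <- acc_cnt["popb"] + acc
          if (adapting) {
            if (mv == 1) ls_popb[d] <- ls_popb[d] +
                gam * (acc - cfg$target_accept)
            else ls_popb2[d] <- ls_popb2[d] +
                gam * (acc - cfg$target_accept)
          }
        }
      }

      # -- participant deviations (same two-move scheme) ----------------
      for (i in seq_len(n)) {
        for (d in 1:4) {
          for (s in 1:4) {
            r <- rows_is[[i]][[s]]
            for (mv in 1:2) {
              u <- u_mu[, d, s, i]
              step <- if (mv == 1) exp(ls_devmu[d, s, i]) * stats::rnorm(K)
                      else rep(exp(ls_devmu2[d, s, i]) * stats::rnorm(1), K)
              prop <- u + step
              lprior <- -0.5 * (sum(prop^2) - sum(u^2)) / sig2_mu[d, s, i]
              if (length(r)) {
                newlp <- as.numeric(Btr[r, , drop = FALSE] %*% prop)
                mu_sub <- mu_mat[r, , drop = FALSE]
                mu_sub[, d] <- exp(lpP_mu[r, d] + newlp)
                newll <- race_ll_rows(mu_sub, b_mat[r, , drop = FALSE],
                                      dt[r], dv[r])
                lr <- sum(newll) - sum(ll[r]) + lprior
              } else {
                lr <- lprior  # prior-only update for empty cells
              }
              acc <- is.finite(lr) && log(stats::runif(1)) < lr
              if (acc) {
                u_mu[, d, s, i] <- prop
                if (length(r)) {
                  lpU_mu[r, d] <- newlp
                  mu_mat[r, d] <- mu_sub[, d]
                  ll[r] <- newll
                }
              }
              try_cnt["devmu"] <- try_cnt["devmu"] + 1
              acc_cnt["devmu"] <- acc_cnt["devmu"] + acc
              if (adapting) {
                if (mv == 1) ls_devmu[d, s, i] <- ls_devmu[d, s, i] +
                    gam * (acc - cfg$target_accept)
                else ls_devmu2[d, s, i] <- ls_devmu2[d, s, i] +
                    gam * (acc - cfg$target_accept)
              }
            }
          }
          # boundary deviation for response d
          r <- rows_i[[i]]
          for (mv in 1:2) {
            u <- u_b[, d, i]
            step <- if (mv == 1) exp(ls_devb[d, i]) * stats::rnorm(K)
                    else rep(exp(ls_devb2[d, i]) * stats::rnorm(1), K)
            prop <- u + step
            newlp <- as.numeric(Btr[r, , drop = FALSE] %*% prop)
            b_sub <- b_mat[r, , drop = FALSE]
            b_sub[, d] <- exp(lpP_b[r, d] + newlp)
            newll <- race_ll_rows(mu_mat[r, , drop = FALSE], b_sub,
                                  dt[r], dv[r])
            lr <- sum(newll) - sum(ll[r]) -
              0.5 * (sum(prop^2) - sum(u^2)) / sig2_b[d, i]
            acc <- is.finite(lr) && log(stats::runif(1)) < lr
            if (acc) {
              u_b[, d, i] <- prop
              lpU_b[r, d] <- newlp
              b_mat[r, d] <- b_sub[, d]
              ll[r] <- newll
            }
            try_cnt["devb"] <- try_cnt["devb"] + 1
            acc_cnt["devb"] <- acc_cnt["devb"] + acc
            if (adapting) {
              if (mv == 1) ls_devb[d, i] <- ls_devb[d, i] +
                  gam * (acc - cfg$target_accept)
              else ls_devb2[d, i] <- ls_devb2[d, i] +
                  gam * (acc - cfg$target_accept)
            }
          }
        }

        # -- non-decision offsets ---------------------------------------
        for (s in 1:4) {
          r <- rows_is[[i]][[s]]
          if (!length(r)) next
          prop <- delta[i, s] + exp(ls_delta[i, s]) * stats::rnorm(1)
          acc <- FALSE
          if (prop > 0 && prop < ub[i, s]) {
            newdt <- rt[r] - prop
            newll <- race_ll_rows(mu_mat[r, , drop = FALSE],
                                  b_mat[r, , drop = FALSE], newdt, dv[r])
            lr <- sum(newll) - sum(ll[r])
            acc <- is.finite(lr) && log(stats::runif(1)) < lr
            if (acc) {
              delta[i, s] <- prop
              dt[r] <- newdt
              ll[r] <- newll
            }
          }
          try_cnt["delta"] <- try_cnt["delta"] + 1
          acc_cnt["delta"] <- acc_cnt["delta"] + acc
          if (adapting) ls_delta[i, s] <- ls_delta[i, s] +
              gam * (acc - cfg$target_accept)
        }

        # -- joint participant-level ridge move -------------------------
        # The per-participant posterior has a near-degenerate ridge
        # coupling the overall drift level, boundary level, and offsets
        # (slower accumulation ~ lower boundaries ~ larger offsets give
        # similar data). Single-block moves cannot travel along it, so
        # propose a correlated shift of all of participant i's log
        # drifts, log boundaries, and offsets at once.
        r <- rows_i[[i]]
        k3 <- exp(ls_joint[, i]) * stats::rnorm(3)
        dnew <- delta[i, ] + k3[3]
        if (all(dnew > 0 & dnew < ub[i, ])) {
          mu_sub <- mu_mat[r, , drop = FALSE] * exp(k3[1])
          b_sub <- b_mat[r, , drop = FALSE] * exp(k3[2])
          newdt <- rt[r] - dnew[sv[r]]
          newll <- race_ll_rows(mu_sub, b_sub, newdt, dv[r])
          lprior <- 0
          for (d in 1:4) {
            for (s in 1:4) {
              u <- u_mu[, d, s, i]
              lprior <- lprior - 0.5 *
                (sum((u + k3[1])^2) - sum(u^2)) / sig2_mu[d, s, i]
            }
            u <- u_b[, d, i]
            lprior <- lprior - 0.5 *
              (sum((u + k3[2])^2) - sum(u^2)) / sig2_b[d, i]
          }
          lr <- sum(newll) - sum(ll[r]) + lprior
          acc <- is.finite(lr) && log(stats::runif(1)) < lr
          if (acc) {
            u_mu[, , , i] <- u_mu[, , , i] + k3[1]
            u_b[, , i] <- u_b[, , i] + k3[2]
            lpU_mu[r, ] <- lpU_mu[r, ] + k3[1]
            lpU_b[r, ] <- lpU_b[r, ] + k3[2]
            mu_mat[r, ] <- mu_sub
            b_mat[r, ] <- b_sub
            delta[i, ] <- dnew
            dt[r] <- newdt
            ll[r] <- newll
          }
          try_cnt["joint"] <- try_cnt["joint"] + 1
          acc_cnt["joint"] <- acc_cnt["joint"] + acc
          if (adapting) ls_joint[, i] <- ls_joint[, i] +
              gam * (acc - cfg$target_accept)
        }
      }

      # -- Gibbs updates of the deviation variances. Held fixed over the
      # first half of burn-in: all deviations start at zero, and an
      # immediate conjugate update would collapse the variance (and with
      # it every participant effect) into a funnel it cannot leave.
      if (it > cfg$burn_in / 2) {
        ssq_mu <- apply(u_mu^2, 2:4, sum)          # [d, s, i]
        sig2_mu[] <- 1 / stats::rgamma(length(ssq_mu),
                                       cfg$dev_a0 + K / 2,
                                       cfg$dev_b0 + ssq_mu / 2)
        ssq_b <- apply(u_b^2, 2:3, sum)            # [d, i]
        sig2_b[] <- 1 / stats::rgamma(length(ssq_b),
                                      cfg$dev_a0 + K / 2,
                                      cfg$dev_b0 + ssq_b / 2)
      }

      # -- retain --------------------------------------------------------
      if (it > cfg$burn_in && (it - cfg$burn_in) %% cfg$thinning == 0L) {
        kr <- kr + 1L
        for (d in 1:4) for (s in 1:4) {
          popc <- as.numeric(B %*% th_mu[, d, s])
          mu_pop_draws[kr, d, s, ] <- exp(popc)
          devs <- B %*% u_mu[, d, s, ]           # nblk x n
          mu_draws[kr, , d, s, ] <- t(exp(popc + devs))
        }
        for (d in 1:4) {
          popc <- as.numeric(B %*% th_b[, d])
          b_pop_draws[kr, d, ] <- exp(popc)
          devs <- B %*% u_b[, d, ]
          b_draws[kr, , d, ] <- t(exp(popc + devs))
        }
        delta_draws[kr, , ] <- delta
        sig_draws[kr, , ] <- cbind(apply(sig2_mu, 3, mean),
                                   colMeans(sig2_b))
      }
    }

    acc_rate <- acc_cnt / pmax(try_cnt, 1)
    if (any(acc_rate < 0.05 | acc_rate > 0.8)) {
      warning("proposal adaptation left acceptance rates outside [0.05, ",
              "0.8]: ", paste(sprintf("%s=%.2f", names(acc_rate), acc_rate),
                              collapse = ", "))
    }

    qs <- function(a, p) apply(a, seq_along(dim(a))[-1], stats::quantile,
                               probs = p, names = FALSE)
    pm <- function(a) apply(a, seq_along(dim(a))[-1], mean)
    draws <- list(mu = mu_draws, b = b_draws, delta = delta_draws,
                  mu_pop = mu_pop_draws, b_pop = b_pop_draws,
                  sigma_u = sig_draws)
    posterior_mean <- lapply(draws, pm)
    ci95 <- list(lower = lapply(draws, qs, p = 0.025),
                 upper = lapply(draws, qs, p = 0.975))

    # Geweke diagnostics: all population curve chains plus a random
    # fraction of participant-level correct-drift chains
    gew <- list()
    for (d in 1:4) for (s in 1:4) for (t in seq_len(nblk)) {
      gew[[sprintf("mu_pop[%d,%d,%d]", d, s, t)]] <-
        mu_pop_draws[, d, s, t]
    }
    for (d in 1:4) for (t in seq_len(nblk)) {
      gew[[sprintf("b_pop[%d,%d]", d, t)]] <- b_pop_draws[, d, t]
    }
    cells <- expand.grid(i = seq_len(n), d = 1:4, t = seq_len(nblk))
    pick <- cells[sample.int(nrow(cells),
                             max(1L, round(cfg$monitor_participant_frac *
                                             nrow(cells)))), ]
    for (j in seq_len(nrow(pick))) {
      gew[[sprintf("mu[%d,%d,%d,%d]", pick$i[j], pick$d[j], pick$d[j],
                   pick$t[j])]] <-
        mu_draws[, pick$i[j], pick$d[j], pick$d[j], pick$t[j]]
    }
    gz <- vapply(gew, function(ch) suppressWarnings(geweke_diag(ch)), 0)
    diagnostics <- list(
      geweke = tibble::tibble(chain = names(gz), z = unname(gz),
                              pass = abs(unname(gz)) < 2),
      acceptance = tibble::tibble(block_type = names(acc_rate),
                                  rate = unname(acc_rate)))

    structure(list(draws = draws, posterior_mean = posterior_mean,
                   ci95 = ci95, diagnostics = diagnostics,
                   mcmc_config = cfg, participants = levels(pid),
                   session = ses, n_retained = nret),
              class = "ddm_fit")
  })
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat("Inverse-Gaussian race model fit (session ", x$session, ")\n",
      sep = "")
  cat("  participants: ", length(x$participants),
      ", retained draws: ", x$n_retained, "\n", sep = "")
  cat("  Geweke |z| < 2: ", sum(x$diagnostics$geweke$pass), "/",
      nrow(x$diagnostics$geweke), " monitored chains\n", sep = "")
  invisible(x)
}

#' Correct-accumulator drift and boundary summaries
#'
#' Per participant x block: the mean over the four correct accumulators
#' (response = stimulus) of the posterior-mean drift, and the mean over
#' responses of the posterior-mean boundary. This is the table fed to the
#' working-memory association models.
#'
#' @param fit a [fit_session()] result.
#' @return tibble with `participant_id`, `session`, `block`, `drift`,
#'   `boundary`.
#' @export
correct_drift_summary <- function(fit) {
  stopifnot(inherits(fit, "ddm_fit"))
  n <- length(fit$participants)
  nblk <- dim(fit$posterior_mean$mu)[4]
  out <- expand.grid(participant_id = fit$participants,
                     block = seq_len(nblk), stringsAsFactors = FALSE)
  out$session <- fit$session
  out$drift <- NA_real_
  out$boundary <- NA_real_
  for (k in seq_len(nrow(out))) {
    i <- match(out$participant_id[k], fit$participants)
    t <- out$block[k]
    out$drift[k] <- mean(diag(fit$posterior_mean$mu[i, , , t]))
    out$boundary[k] <- mean(fit$posterior_mean$b[i, , t])
  }
  tibble::as_tibble(out[, c("participant_id", "session", "block",
                            "drift", "boundary")])
}

#' Geweke stationarity diagnostic
#'
#' Compares the mean of the first `frac1` of a chain with the mean of the
#' last `frac2`, standardized by spectral-density-at-zero variance
#' estimates (AR-fit estimator) of the two segments. `|z| < 2` is the
#' conventional pass. A constant chain returns 0 by convention; chains
#' shorter than 100 return `NA` with a warning.
#'
#' @param chain numeric vector of MCMC draws.
#' @param frac1,frac2 early and late segment fractions.
#' @return z-score (scalar).
#' @export
geweke_diag <- function(chain, frac1 = 0.1, frac2 = 0.5) {
  if (length(chain) < 100) {
    warning("chain too short for a Geweke diagnostic")
    return(NA_real_)
  }
  if (stats::var(chain) == 0) return(0)
  n <- length(chain)
  a <- chain[seq_len(floor(frac1 * n))]
  b <- chain[seq.int(n - floor(frac2 * n) + 1L, n)]
  s0 <- function(x) {
    if (stats::var(x) == 0) return(0)
    fit <- stats::ar(x, aic = TRUE,
                     order.max = min(20L, length(x) - 1L))
    fit$var.pred / (1 - sum(fit$ar))^2
  }
  den <- s0(a) / length(a) + s0(b) / length(b)
  if (den == 0) return(0)
  (mean(a) - mean(b)) / sqrt(den)
}

#' Posterior predictive check
#'
#' Simulates replicate datasets on the fitted trials' design (same
#' participant, stimulus and block slots) from randomly chosen retained
#' posterior draws, then compares per-block accuracy and pooled RT
#' quantiles (0.1, 0.5, 0.9) between the observed data and the replicate
#' 95% intervals. Replicates are untrimmed; when the fitted data had
#' their RT tails trimmed, expect mild upper-tail-quantile misfit of
#' about the trimmed fraction.
#'
#' @param fit a [fit_session()] result.
#' @param trials the trial table the model was fit to.
#' @param n_rep number of replicate datasets (default 200).
#' @param rng_seed integer seed.
#' @return tibble with one row per block x statistic: `observed`,
#'   `rep_lo`, `rep_hi`, `covered`.
#' @export
posterior_predictive_check <- function(fit, trials, n_rep = 200,
                                       rng_seed = 1L) {
  stopifnot(inherits(fit, "ddm_fit"))
  if (!fit$mcmc_config$include_generalization &&
      "phase" %in% names(trials)) {
    trials <- trials[trials$phase == "training", ]
  }
  i <- match(trials$participant_id, fit$participants)
  s <- as.integer(trials$tone_category)
  blkv <- as.integer(trials$block)
  dv <- as.integer(trials$response)
  rt <- trials$rt
  ntr <- length(rt)
  stat_tbl <- function(correct, rtv) {
    agg <- lapply(sort(unique(blkv)), function(t) {
      sel <- blkv == t
      tibble::tibble(block = t,
                     statistic = c("accuracy", "rt_q10", "rt_q50",
                                   "rt_q90"),
                     value = c(mean(correct[sel]),
                               stats::quantile(rtv[sel],
                                               c(0.1, 0.5, 0.9),
                                               names = FALSE)))
    })
    dplyr::bind_rows(agg)
  }
  obs <- stat_tbl(dv == s, rt)
  with_seed(rng_seed, {
    reps <- matrix(NA_real_, nrow(obs), n_rep)
    idxs <- sample.int(fit$n_retained, n_rep, replace = TRUE)
    for (k in seq_len(n_rep)) {
      id <- idxs[k]
      mu <- matrix(NA_real_, ntr, 4)
      b <- matrix(NA_real_, ntr, 4)
      for (d in 1:4) {
        mu[, d] <- fit$draws$mu[cbind(id, i, d, s, blkv)]
        b[, d] <- fit$draws$b[cbind(id, i, d, blkv)]
      }
      del <- fit$draws$delta[cbind(id, i, s)]
      sim <- simulate_race(mu, b, del)
      reps[, k] <- stat_tbl(sim$response == s, sim$rt)$value
    }
    lo <- apply(reps, 1, stats::quantile, 0.025, names = FALSE)
    hi <- apply(reps, 1, stats::quantile, 0.975, names = FALSE)
    tibble::tibble(block = obs$block, statistic = obs$statistic,
                   observed = obs$value, rep_lo = lo, rep_hi = hi,
                   covered = obs$value >= lo & obs$value <= hi)
  })
}
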
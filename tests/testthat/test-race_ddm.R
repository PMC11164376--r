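test_that("block bases form a partition of unity and are non-negative", {
  for (sp in list(basis_spec(),
                  basis_spec(degree = 2, interior_knots = 3),
                  basis_spec(degree = 1, interior_knots = c(2, 4)))) {
    B <- build_basis(sp)
    expect_equal(rowSums(B), rep(1, sp$n_blocks))
    expect_true(all(B >= 0))
    expect_equal(ncol(B), sp$n_basis)
  }
})

test_that("degree-0 basis with one knot per block is the indicator basis", {
  B <- build_basis(basis_spec(degree = 0, interior_knots = 2:6))
  expect_equal(B, diag(6))
})

test_that("invalid basis specs are rejected", {
  expect_error(basis_spec(interior_knots = c(0, 3)), "block axis")
  expect_error(basis_spec(degree = -1))
})

test_that("default MCMC accounting retains (6000 - 2000) / 5 = 800 draws", {
  expect_identical(n_retained(ddm_model_config()), 800L)
  expect_identical(n_retained(ddm_model_config(iterations = 1500,
                                               burn_in = 500,
                                               thinning = 2)), 500L)
  expect_error(ddm_model_config(iterations = 100, burn_in = 200))
})

test_that("geweke diagnostic is calibrated on stationary chains", {
  zs <- withr::with_seed(801, {
    vapply(1:100, function(k) geweke_diag(rnorm(1e4)), 0)
  })
  expect_gte(mean(abs(zs) < 2), 0.95)
})

test_that("geweke diagnostic flags trends and degenerate chains", {
  withr::with_seed(802, {
    trend <- seq(0, 3, length.out = 2000) + rnorm(2000, 0, 0.5)
    expect_gt(abs(geweke_diag(trend)), 4)
  })
  expect_identical(geweke_diag(rep(1.3, 500)), 0)
  expect_warning(z <- geweke_diag(rnorm(50)), "short")
  expect_true(is.na(z))
})

test_that("session fit recovers participant drift and boundary trajectories", {
  fx <- recovery_fixture()
  fit <- fx$fit
  # retained-draw accounting matches the configuration exactly
  expect_identical(dim(fit$draws$mu)[1], n_retained(fx$cfg))
  expect_identical(fit$n_retained, 500L)
  # correlation between true and posterior-mean correct-accumulator log
  # drifts across participants x blocks
  sm <- correct_drift_summary(fit)
  expect_gte(cor(log(sm$drift), fx$true_log_drift(sm)), 0.8)
  # posterior means lie inside their own pointwise credible intervals
  expect_true(all(fit$ci95$lower$mu <= fit$posterior_mean$mu + 1e-12))
  expect_true(all(fit$posterior_mean$mu <= fit$ci95$upper$mu + 1e-12))
  expect_true(all(fit$ci95$lower$b <= fit$posterior_mean$b + 1e-12))
  expect_true(all(fit$posterior_mean$b <= fit$ci95$upper$b + 1e-12))
  # most monitored chains pass the stationarity check
  expect_gt(mean(fit$diagnostics$geweke$pass), 0.6)
  # adapted acceptance rates are in a healthy band
  expect_true(all(fit$diagnostics$acceptance$rate > 0.1 &
                    fit$diagnostics$acceptance$rate < 0.6))
})

test_that("learner/non-learner generative contrast is recovered in late blocks", {
  fx <- recovery_fixture()
  sm <- correct_drift_summary(fx$fit)
  lrn <- vapply(fx$cohort, `[[`, TRUE, "learner_flag")
  ids <- vapply(fx$cohort, `[[`, "", "participant_id")
  late <- sm[sm$block == 6, ]
  is_l <- lrn[match(late$participant_id, ids)]
  expect_gt(mean(late$drift[is_l]), mean(late$drift[!is_l]))
})

test_that("drift summary is the plain average of the correct accumulators", {
  fx <- recovery_fixture()
  sm <- correct_drift_summary(fx$fit)
  i <- match(sm$participant_id[1], fx$fit$participants)
  expect_equal(sm$drift[1],
               mean(diag(fx$fit$posterior_mean$mu[i, , , sm$block[1]])))
  expect_equal(sm$boundary[1],
               mean(fx$fit$posterior_mean$b[i, , sm$block[1]]))
})

test_that("flat generative trajectories yield flat population curves", {
  fx <- flat_fit_fixture()
  fit <- fx$fit
  # no two blocks' 95% CIs of the population correct-drift curve disjoint
  for (d in 1:4) {
    lo <- fit$ci95$lower$mu_pop[d, d, ]
    hi <- fit$ci95$upper$mu_pop[d, d, ]
    for (t1 in 1:5) for (t2 in (t1 + 1):6) {
      expect_true(lo[t1] <= hi[t2] && lo[t2] <= hi[t1])
    }
  }
})

test_that("posterior predictive replicates cover self-generated data", {
  fx <- recovery_fixture()
  fit <- fx$fit
  # simulate a dataset from the fitted model itself (posterior means):
  # its block statistics must be covered by the replicate intervals
  self_data <- fx$s1[fx$s1$phase == "training", ]
  i <- match(self_data$participant_id, fit$participants)
  s <- self_data$tone_category
  blk <- self_data$block
  mu <- b <- matrix(NA_real_, nrow(self_data), 4)
  for (d in 1:4) {
    mu[, d] <- fit$posterior_mean$mu[cbind(i, d, s, blk)]
    b[, d] <- fit$posterior_mean$b[cbind(i, d, blk)]
  }
  withr::with_seed(30, {
    sim <- simulate_race(mu, b, fit$posterior_mean$delta[cbind(i, s)])
  })
  self_data$response <- sim$response
  self_data$rt <- sim$rt
  ppc <- posterior_predictive_check(fit, self_data, n_rep = 200,
                                    rng_seed = 31)
  expect_gte(mean(ppc$covered), 0.9)
})

test_that("posterior predictive check flags engineered misfit", {
  fx <- recovery_fixture()
  shifted <- fx$s1
  shifted$rt <- shifted$rt + 1
  ppc <- posterior_predictive_check(fx$fit, shifted, n_rep = 100,
                                    rng_seed = 32)
  med <- ppc[ppc$statistic == "rt_q50", ]
  expect_true(all(!med$covered))
})

test_that("fit rejects multi-session input and out-of-range blocks", {
  fx <- recovery_fixture()
  expect_error(fit_session(fx$trials, fx$cfg, 1), "one session")
})
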
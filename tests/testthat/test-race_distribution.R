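test_that("first-passage density matches its closed form and normalizes", {
  expect_equal(ig_pdf(1, 1, 1), 1 / sqrt(2 * pi), tolerance = 1e-12)
  for (par in list(c(1.5, 1), c(0.7, 2), c(3, 0.6))) {
    z <- integrate(function(t) ig_pdf(t, par[1], par[2]), 0, Inf,
                   rel.tol = 1e-9)
    expect_equal(z$value, 1, tolerance = 1e-6)
  }
  expect_error(ig_pdf(-1, 1, 1), "positive")
  expect_error(ig_pdf(1, 1, -1), "positive")
})

test_that("survival function matches direct arithmetic and calculus identities", {
  # S(1; mu=1, b=1) = 1 - [Phi(0) + e^2 Phi(-2)], evaluated directly
  expect_equal(ig_sf(1, 1, 1),
               1 - (pnorm(0) + exp(2) * pnorm(-2)), tolerance = 1e-10)
  expect_equal(ig_sf(0, 2.3, 0.8), 1)
  # d/dt S = -f on a grid, by central differences
  tt <- seq(0.1, 3, by = 0.1)
  h <- 1e-5
  num <- (ig_sf(tt + h, 1.3, 0.9) - ig_sf(tt - h, 1.3, 0.9)) / (2 * h)
  expect_equal(num, -ig_pdf(tt, 1.3, 0.9), tolerance = 1e-6)
  # monotone non-increasing, stable for large arguments
  s <- ig_sf(seq(0, 50, by = 0.5), 4, 8)
  expect_true(all(diff(s) <= 1e-12))
  expect_true(all(is.finite(s)))
})

test_that("exact sampler reproduces the closed-form moments", {
  withr::with_seed(401, {
    x <- sample_ig_first_passage(1e5, 2, 1)
    expect_equal(mean(x), 0.5, tolerance = 0.01)
    y <- sample_ig_first_passage(1e5, 1, 1)
    expect_equal(mean(y), 1, tolerance = 0.02)
    expect_equal(var(y), 1, tolerance = 0.05)
    expect_error(sample_ig_first_passage(10, -1, 1), "positive")
  })
})

test_that("exact sampler agrees with the Euler path-simulation oracle (KS)", {
  withr::with_seed(402, {
    exact <- sample_ig_first_passage(1e4, 2, 1)
    path <- euler_first_passage(1200, 2, 1)
    expect_gt(length(path), 1150)  # almost sure termination
    ks <- suppressWarnings(stats::ks.test(exact, path))
    expect_gt(ks$p.value, 0.01)
  })
})

test_that("race log-likelihood equals a direct unvectorized reference", {
  withr::with_seed(403, {
    for (rep in 1:5) {
      n <- 8
      mu <- matrix(runif(4 * n, 0.2, 3), n)
      b <- matrix(runif(4 * n, 0.4, 2.5), n)
      rt <- runif(n, 0.4, 3)
      resp <- sample(1:4, n, replace = TRUE)
      del <- runif(n, 0, 0.3)
      ll <- race_loglik(rt, resp, mu, b, del)
      ref <- vapply(seq_len(n), function(r) {
        t <- rt[r] - del[r]
        v <- log(ig_pdf(t, mu[r, resp[r]], b[r, resp[r]]))
        for (k in setdiff(1:4, resp[r])) {
          v <- v + log(ig_sf(t, mu[r, k], b[r, k]))
        }
        v
      }, 0)
      expect_equal(ll, ref, tolerance = 1e-10)
    }
  })
})

test_that("race likelihood integrates to total probability one", {
  withr::with_seed(404, {
    for (rep in 1:2) {
      mu <- runif(4, 0.4, 2.5)
      b <- runif(4, 0.6, 2)
      total <- sum(vapply(1:4, function(d) {
        integrate(function(tau) {
          vapply(tau, function(t1) {
            exp(race_loglik(t1, d, matrix(mu, 1), matrix(b, 1), 0))
          }, 0)
        }, 0, Inf, rel.tol = 1e-9)$value
      }, 0))
      expect_equal(total, 1, tolerance = 1e-6)
    }
  })
})

test_that("rt at or below the offset yields -Inf, not an error", {
  ll <- race_loglik(c(0.2, 0.5), c(1, 2), rep(1, 4), rep(1, 4),
                    delta = 0.3)
  expect_identical(ll[1], -Inf)
  expect_true(is.finite(ll[2]))
})

test_that("simulated choice frequencies match the race-identity quadrature", {
  mu <- c(1.6, 0.7, 0.5, 1.0)
  b <- c(1.2, 1.2, 0.8, 1.5)
  p_theory <- vapply(1:4, function(d) {
    integrate(function(tau) {
      vapply(tau, function(t1) {
        exp(race_loglik(t1, d, matrix(mu, 1), matrix(b, 1), 0))
      }, 0)
    }, 0, Inf, rel.tol = 1e-10)$value
  }, 0)
  withr::with_seed(405, {
    nsim <- 1e5
    sim <- simulate_race(matrix(mu, nsim, 4, byrow = TRUE),
                         matrix(b, nsim, 4, byrow = TRUE))
    p_hat <- tabulate(sim$response, 4) / nsim
    se <- sqrt(p_theory * (1 - p_theory) / nsim)
    expect_true(all(abs(p_hat - p_theory) < 3 * se))
  })
})

test_that("symmetric accumulators choose uniformly and dominance wins", {
  withr::with_seed(406, {
    sym <- simulate_race(matrix(1, 4e4, 4), matrix(1.2, 4e4, 4))
    p <- tabulate(sym$response, 4) / 4e4
    expect_true(all(abs(p - 0.25) < 3 * sqrt(0.25 * 0.75 / 4e4)))
    dom <- simulate_race(matrix(rep(c(8, 0.1, 0.1, 0.1), each = 2e3), 2e3),
                         matrix(1.5, 2e3, 4))
    expect_gt(mean(dom$response == 1), 0.99)
  })
})

test_that("boundary and drift move speed and accuracy as the model predicts", {
  withr::with_seed(407, {
    n <- 3e4
    base_mu <- matrix(rep(c(1.4, 0.6, 0.6, 0.6), each = n), n)
    lo_b <- matrix(1.0, n, 4)
    hi_b <- matrix(1.8, n, 4)
    lo <- simulate_race(base_mu, lo_b)
    hi <- simulate_race(base_mu, hi_b)
    # higher boundaries: slower and more accurate (speed-accuracy tradeoff)
    expect_gt(mean(hi$rt), mean(lo$rt))
    expect_gt(mean(hi$response == 1), mean(lo$response == 1))
    fast_mu <- base_mu
    fast_mu[, 1] <- 2.2
    fa <- simulate_race(fast_mu, lo_b)
    # higher correct drift: more accurate, faster correct responses
    expect_gt(mean(fa$response == 1), mean(lo$response == 1))
    expect_lt(mean(fa$rt[fa$response == 1]),
              mean(lo$rt[lo$response == 1]))
  })
})
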
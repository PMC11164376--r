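#' Inverse-Gaussian first-passage density
#'
#' Density of the first time a unit-diffusion Wiener process with drift
#' `mu > 0` reaches the absorbing boundary `b > 0`:
#' \deqn{f(t; \mu, b) = b (2\pi t^3)^{-1/2} \exp\{-(b - \mu t)^2 / (2t)\}.}
#' This is the Wald distribution with mean `b / mu` and variance
#' `b / mu^3`. Computed on the log scale internally so extreme arguments
#' underflow gracefully instead of producing NaN.
#'
#' @param t decision time(s), strictly positive.
#' @param mu drift rate(s), evidence units per second.
#' @param b boundary separation(s), evidence units; strictly positive.
#' @param log return the log density?
#' @return Numeric vector of (log) densities.
#' @export
ig_pdf <- function(t, mu, b, log = FALSE) {
  if (any(t <= 0) || any(b <= 0)) {
    stop("`t` and `b` must be strictly positive", call. = FALSE)
  }
  lp <- base::log(b) - 0.5 * (base::log(2 * pi) + 3 * base::log(t)) -
    (b - mu * t)^2 / (2 * t)
  if (log) lp else exp(lp)
}

#' Inverse-Gaussian first-passage survival function
#'
#' `P(T > t)` for the distribution of [ig_pdf()]:
#' \deqn{S(t) = 1 - [\Phi((\mu t - b)/\sqrt t) +
#'   e^{2\mu b}\Phi(-(\mu t + b)/\sqrt t)].}
#' The `exp(2 mu b)` factor is handled in log space (it overflows for
#' moderate `mu * b` even though the product term never exceeds the first),
#' so the result is stable for large drifts and boundaries. `ig_sf(0)` is 1.
#'
#' @inheritParams ig_pdf
#' @param log return the log survival probability?
#' @return Numeric vector of (log) survival probabilities in `[0, 1]`.
#' @export
ig_sf <- function(t, mu, b, log = FALSE) {
  if (any(t < 0) || any(b <= 0)) {
    stop("`t` must be >= 0 and `b` > 0", call. = FALSE)
  }
  n <- max(length(t), length(mu), length(b))
  t <- rep_len(t, n); mu <- rep_len(mu, n); b <- rep_len(b, n)
  ls <- numeric(n)
  pos <- t > 0
  if (any(pos)) {
    tt <- t[pos]; m <- mu[pos]; bb <- b[pos]
    st <- sqrt(tt)
    la <- stats::pnorm((bb - m * tt) / st, log.p = TRUE)
    lb <- 2 * m * bb + stats::pnorm(-(m * tt + bb) / st, log.p = TRUE)
    lsf <- ifelse(lb >= la, -Inf, la + log1p(-exp(lb - la)))
    ls[pos] <- lsf
  }
  if (log) ls else exp(ls)
}

#' Draw exact inverse-Gaussian first-passage times
#'
#' Exact sampler using the Michael–Schucany–Haas transformation (one
#' chi-square root plus a randomized root choice), i.e. no path
#' discretization. Used both by the trial simulator and by posterior
#' predictive checks.
#'
#' @param n number of draws.
#' @param mu drift rate(s) > 0 (recycled to length `n`).
#' @param b boundary value(s) > 0 (recycled to length `n`).
#' @return `n` first-passage times in seconds.
#' @export
sample_ig_first_passage <- function(n, mu, b) {
  if (any(mu <= 0) || any(b <= 0)) {
    stop("`mu` and `b` must be strictly positive", call. = FALSE)
  }
  mu <- rep_len(mu, n); b <- rep_len(b, n)
  m <- b / mu              # mean
  lam <- b^2               # shape (unit diffusion)
  y <- stats::rchisq(n, df = 1)
  x <- m + m^2 * y / (2 * lam) -
    m / (2 * lam) * sqrt(4 * m * lam * y + m^2 * y^2)
  u <- stats::runif(n)
  ifelse(u <= m / (m + x), x, m^2 / x)
}

#' Race-model log-likelihood of observed (choice, RT) pairs
#'
#' Joint log density of a choice `d` and reaction time `rt` under an
#' independent race of inverse-Gaussian accumulators, one per response
#' option: the chosen accumulator reaches its boundary at the decision
#' time `rt - delta` while every other accumulator survives past it,
#' \deqn{\log f_d(\tau-\delta) + \sum_{d' \ne d} \log S_{d'}(\tau-\delta).}
#' Trials with `rt <= delta` get log-likelihood `-Inf` (never an error, so
#' samplers can reject such proposals).
#'
#' @param rt observed reaction times, seconds (length n).
#' @param response chosen option index in `1:ncol(mu)` (length n).
#' @param mu drift matrix, n x n_options (or a single length-`n_options`
#'   vector shared by all trials).
#' @param b boundary matrix shaped like `mu`.
#' @param delta non-decision offset(s), seconds; scalar or length n.
#' @return Numeric vector of per-trial log-likelihoods.
#' @export
race_loglik <- function(rt, response, mu, b, delta = 0) {
  n <- length(rt)
  if (is.null(dim(mu))) mu <- matrix(mu, n, length(mu), byrow = TRUE)
  if (is.null(dim(b))) b <- matrix(b, n, length(b), byrow = TRUE)
  stopifnot(nrow(mu) == n, nrow(b) == n, length(response) == n)
  if (any(mu <= 0) || any(b <= 0)) {
    stop("drifts and boundaries must be strictly positive", call. = FALSE)
  }
  dt <- rt - rep_len(delta, n)
  as.numeric(race_ll_rows(mu, b, dt, as.integer(response)))
}

#' Simulate one batch of race trials
#'
#' Draws one first-passage time per accumulator, returns the winning
#' option (ties, a measure-zero event, go to the lowest index) and the
#' reaction time `delta + min(T_d)`.
#'
#' @param mu drift matrix, n_trials x n_options.
#' @param b boundary matrix shaped like `mu`.
#' @param delta non-decision offsets, scalar or length n_trials.
#' @return A list with integer vector `response` and numeric vector `rt`.
#' @export
simulate_race <- function(mu, b, delta = 0) {
  mu <- as.matrix(mu); b <- as.matrix(b)
  n <- nrow(mu); k <- ncol(mu)
  tt <- matrix(sample_ig_first_passage(n * k, as.vector(mu), as.vector(b)),
               n, k)
  win <- max.col(-tt, ties.method = "first")
  list(response = win,
       rt = rep_len(delta, n) + tt[cbind(seq_len(n), win)])
}
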
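# Slow but independent first-passage oracle: Euler-Maruyama simulation of
# the unit-diffusion Wiener path until it crosses the boundary. The step
# must be small: discrete crossing detection biases passage times upward
# by about 0.58 sqrt(dt), which two-sample tests detect at coarse steps.
euler_first_passage <- function(n, mu, b, dt = 5e-5, tmax = 30) {
  x <- numeric(n)
  out <- rep(NA_real_, n)
  alive <- seq_len(n)
  sdt <- sqrt(dt)
  step <- 0L
  while (length(alive) && step * dt < tmax) {
    step <- step + 1L
    x[alive] <- x[alive] + mu * dt + sdt * stats::rnorm(length(alive))
    hit <- alive[x[alive] >= b]
    out[hit] <- step * dt
    alive <- setdiff(alive, hit)
  }
  out[!is.na(out)]
}
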
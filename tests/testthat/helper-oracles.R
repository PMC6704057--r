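# Independent oracles, deliberately naive: a hand-written fixed-step RK4 for
# the first-order ODE, a dense-grid evaluator for pathway-activity peaks, and
# an exhaustive binomial-coefficient sum for the hypergeometric right tail.

# RK4 integration of tau dx/dt = -x + K*u(t), x(0) = 0, plain R loop.
rk4_oracle <- function(input_fn, tau, K, grid) {
  f <- function(t, x) (-x + K * input_fn(t)) / tau
  x <- numeric(length(grid))
  for (i in seq_len(length(grid) - 1L)) {
    h <- grid[i + 1L] - grid[i]
    k1 <- f(grid[i], x[i])
    k2 <- f(grid[i] + h / 2, x[i] + h / 2 * k1)
    k3 <- f(grid[i] + h / 2, x[i] + h / 2 * k2)
    k4 <- f(grid[i] + h, x[i] + h * k3)
    x[i + 1L] <- x[i] + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  x
}

# Dense-grid pathway activity of a single step event at t_on = 0.
dense_pa <- function(t, tau1, tau2, K, u) {
  d <- K * u * (1 - exp(-t / tau1)) - K * u * (1 - exp(-t / tau2))
  pmin(pmax(d, 0), 1)
}

# Exhaustive right-tail hypergeometric probability P(X >= k).
hyper_tail_oracle <- function(k, m, n, N) {
  js <- k:min(m, n)
  sum(choose(m, js) * choose(N - m, n - js)) / choose(N, n)
}

ctrl <- default_parameters("control")
wt1d <- default_parameters("wt1d")
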
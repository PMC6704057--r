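#' Model parameter set for one genotype
#'
#' Bundles the constants of the two-pathway model: time constants and
#' steady-state gains of the memory-strengthening (subscript 1) and
#' memory-weakening (subscript 2) first-order processes, plus the nominal step
#' input magnitude shared by all learning events.
#'
#' Shipped defaults (see [default_parameters()]) are: control
#' `tau1 = 0.5` h, `tau2 = 36` h, `K1 = K2 = 3`, `u = 0.125`; WT1-deficient
#' (`wt1d`) identical except `tau2 = 144` h and `K1 = K2 = 7.2`, reflecting a
#' slower weakening pathway and an approximately 2.4-fold stronger effective
#' drive when WT1 function is lost.
#'
#' @param tau1 Time constant of the strengthening pathway, hours (> 0).
#' @param tau2 Time constant of the weakening pathway, hours (> 0).
#' @param K1,K2 Dimensionless steady-state gains (> 0).
#' @param u Nominal dimensionless step-input magnitude (>= 0).
#' @param label Genotype label.
#'
#' @return An object of class `memflex_params`.
#' @export
#' @examples
#' parameter_set(0.5, 36, 3, 3, 0.125, "control")
parameter_set <- function(tau1, tau2, K1, K2, u, label = "custom") {
  stopifnot(is.numeric(tau1), is.numeric(tau2), is.numeric(K1),
            is.numeric(K2), is.numeric(u), length(label) == 1L)
  if (tau1 <= 0 || tau2 <= 0) stop("time constants tau1 and tau2 must be > 0", call. = FALSE)
  if (K1 <= 0 || K2 <= 0) stop("gains K1 and K2 must be > 0", call. = FALSE)
  if (u < 0) stop("input magnitude u must be >= 0", call. = FALSE)
  structure(
    list(tau1 = as.numeric(tau1), tau2 = as.numeric(tau2),
         K1 = as.numeric(K1), K2 = as.numeric(K2),
         u = as.numeric(u), label = as.character(label)),
    class = "memflex_params"
  )
}

#' @export
print.memflex_params <- function(x, ...) {
  cat(sprintf(
    "<memflex_params '%s'> tau1 = %g h, tau2 = %g h, K1 = %g, K2 = %g, u = %g\n",
    x$label, x$tau1, x$tau2, x$K1, x$K2, x$u))
  invisible(x)
}

#' Default genotype parameter sets
#'
#' @param genotype `"control"` for the wild-type parameterisation or `"wt1d"`
#'   (alias `"knockdown"`) for the WT1-deficient one.
#'
#' @return A [parameter_set()].
#' @export
#' @examples
#' default_parameters("wt1d")
default_parameters <- function(genotype = c("control", "wt1d", "knockdown")) {
  genotype <- match.arg(genotype)
  if (genotype == "control") {
    parameter_set(0.5, 36, 3, 3, 0.125, "control")
  } else {
    parameter_set(0.5, 144, 7.2, 7.2, 0.125, "wt1d")
  }
}

#' Step response of a first-order process
#'
#' Closed-form solution of `tau * dx/dt = -x + K * u(t)` for a step input of
#' magnitude `u` switched on at `t_on`, from a zero initial condition:
#' `x(t) = K * u * (1 - exp(-(t - t_on) / tau))` for `t >= t_on` and 0 before.
#'
#' @param t Time(s), hours; vectorised.
#' @param t_on Step onset time, hours.
#' @param tau Time constant, hours (> 0).
#' @param K Steady-state gain.
#' @param u Step magnitude.
#'
#' @return Signal level(s), same length as `t`. Monotone nondecreasing in `t`
#'   with limit `K * u`.
#' @export
#' @examples
#' first_order_step(0.5, 0, tau = 0.5, K = 3, u = 0.125) # one time constant in
first_order_step <- function(t, t_on = 0, tau, K, u) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("tau must be a single positive number", call. = FALSE)
  ifelse(t < t_on, 0, K * u * (1 - exp(-(t - t_on) / tau)))
}

#' Numerically integrate a first-order process for an arbitrary input
#'
#' Solves `tau * dx/dt = -x + K * u(t)` on a time grid from `x(grid[1]) = x0`,
#' using a fixed-step integrator from \pkg{deSolve}. For step inputs the result
#' agrees with [first_order_step()] to high accuracy at fine grid steps; the
#' generic-input path exists for non-step drives.
#'
#' @param input_fn Function of time returning the input magnitude `u(t)`.
#' @param tau Time constant, hours (> 0).
#' @param K Steady-state gain.
#' @param grid Strictly increasing numeric vector of time points, hours.
#' @param x0 Initial state at `grid[1]` (default 0).
#' @param method Integration method passed to [deSolve::ode()] (default
#'   `"rk4"`, classical fixed-step Runge-Kutta).
#'
#' @return Numeric trajectory of `x` on `grid`.
#' @export
#' @examples
#' g <- seq(0, 5, by = 0.01)
#' x <- integrate_first_order(function(t) 0.125, tau = 0.5, K = 3, grid = g)
integrate_first_order <- function(input_fn, tau, K, grid, x0 = 0, method = "rk4") {
  if (!is.numeric(tau) || tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (length(grid) < 2L || any(diff(grid) <= 0))
    stop("grid must be strictly increasing with at least two points", call. = FALSE)
  deriv <- function(t, y, parms) list((-y + K * input_fn(t)) / tau)
  sol <- deSolve::ode(y = c(x = x0), times = grid, func = deriv,
                      parms = NULL, method = method)
  unname(sol[, "x"])
}

#' Saturation (clipping) function
#'
#' @param v Numeric values.
#' @param lo,hi Lower and upper bound, `lo <= hi`.
#'
#' @return `min(max(v, lo), hi)`, elementwise.
#' @export
#' @examples
#' saturate(c(-0.3, 0.42, 1.7))
saturate <- function(v, lo = 0, hi = 1) {
  if (lo > hi) stop("saturation bounds must satisfy lo <= hi", call. = FALSE)
  pmin(pmax(v, lo), hi)
}

#' Pathway activity: saturated pathway difference
#'
#' The model's single nonlinearity: the difference between the strengthening
#' and weakening signals, clipped to \[0, 1\]. It represents the net short-term
#' learning capacity currently engaged.
#'
#' @param x1 Strengthening-signal level(s).
#' @param x2 Weakening-signal level(s).
#'
#' @return `saturate(x1 - x2, 0, 1)`.
#' @export
#' @examples
#' pathway_activity(0.9, 0.138)
pathway_activity <- function(x1, x2) {
  saturate(x1 - x2, 0, 1)
}

#' Effectors available given engaged pathway activity
#'
#' The model assumes a finite pool of downstream effectors; whatever fraction
#' is engaged by ongoing pathway activity is unavailable for encoding new
#' events.
#'
#' @param aggregate_activity Aggregate pathway activity in \[0, 1\].
#'
#' @return `1 - aggregate_activity`.
#' @export
#' @examples
#' effectors_available(0.645)
effectors_available <- function(aggregate_activity) {
  if (any(aggregate_activity < 0 | aggregate_activity > 1))
    stop("aggregate_activity must lie in [0, 1]", call. = FALSE)
  1 - aggregate_activity
}

#' Analytic peak time of the pathway difference after a single step
#'
#' For a single step at `t = 0` the difference `x1 - x2` peaks at
#' `t* = log((K1 * tau2) / (K2 * tau1)) / (1/tau1 - 1/tau2)` (requires
#' `tau1 < tau2`). With equal gains this reduces to
#' `log(tau2/tau1) / (1/tau1 - 1/tau2)`.
#'
#' @param params A [parameter_set()].
#'
#' @return Peak time in hours after onset.
#' @export
#' @examples
#' peak_time(default_parameters("control"))
peak_time <- function(params) {
  stopifnot(inherits(params, "memflex_params"))
  if (params$tau1 >= params$tau2)
    stop("peak_time requires tau1 < tau2 (fast strengthening, slow weakening)",
         call. = FALSE)
  ratio <- (params$K1 * params$tau2) / (params$K2 * params$tau1)
  if (ratio <= 1) return(0)
  log(ratio) / (1 / params$tau1 - 1 / params$tau2)
}

# Unsaturated x1 - x2 for a single step event, closed form; vectorised over t.
event_difference <- function(t, t_on, params, u = params$u) {
  first_order_step(t, t_on, params$tau1, params$K1, u) -
    first_order_step(t, t_on, params$tau2, params$K2, u)
}

# Per-event pathway activity (saturated), closed form.
event_activity <- function(t, t_on, params, u = params$u) {
  saturate(event_difference(t, t_on, params, u), 0, 1)
}
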
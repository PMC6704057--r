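#' Link from model memory to a behavioural readout scale
#'
#' Behavioural assays report percentages: freezing after contextual fear
#' conditioning spans 0-100 %, while place preference in novel object
#' location spans 50-100 % (50 % is chance; the dashed chance line of a
#' preference plot). The link is affine — `floor + (ceiling - floor) * Memory`
#' — plus Gaussian measurement noise, truncated to the scale.
#'
#' @param task_type `"preference"` or `"freezing"`; sets default floor and
#'   ceiling (50-100 and 0-100 respectively).
#' @param floor,ceiling Scale bounds in %, `floor < ceiling`.
#' @param noise_sd Measurement noise standard deviation, % units (>= 0).
#'
#' @return A `memflex_link` object.
#' @export
#' @examples
#' readout_link("preference", noise_sd = 5)
readout_link <- function(task_type = c("preference", "freezing"),
                         floor = NULL, ceiling = NULL, noise_sd = 5) {
  task_type <- match.arg(task_type)
  if (is.null(floor)) floor <- if (task_type == "preference") 50 else 0
  if (is.null(ceiling)) ceiling <- 100
  if (floor >= ceiling) stop("floor must be below ceiling", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(task_type = task_type, floor = floor, ceiling = ceiling,
                 noise_sd = noise_sd), class = "memflex_link")
}

# Noise-free expected readout for a memory value.
link_readout <- function(link, memory) {
  link$floor + (link$ceiling - link$floor) * memory
}

#' Generate a synthetic behavioural cohort
#'
#' Simulates per-animal readouts from the model's memory values at every
#' test of a protocol: `readout = floor + (ceiling - floor) * Memory + noise`,
#' with Gaussian noise of sd `noise_sd` truncated to the readout scale.
#' Reproducible under a fixed seed; the global RNG state is left untouched.
#'
#' @param proto A [protocol()].
#' @param params A [parameter_set()].
#' @param link A [readout_link()].
#' @param n Number of animals (>= 1).
#' @param seed Integer seed for the cohort's RNG stream.
#'
#' @return Tibble: `animal`, `genotype`, `task`, `time_h`, `readout_pct`,
#'   `memory_true`, `seed`.
#' @export
#' @examples
#' generate_cohort(built_in_protocol("single"), default_parameters("wt1d"),
#'                 readout_link("preference"), n = 5, seed = 1)
generate_cohort <- function(proto, params, link, n, seed = 1) {
  stopifnot(inherits(link, "memflex_link"))
  if (n < 1) stop("cohort size n must be >= 1", call. = FALSE)
  res <- run_protocol(proto, params, grid_step = max(proto$test_offsets))
  tests <- res$tests
  withr::with_seed(seed, {
    dplyr::bind_rows(lapply(seq_len(nrow(tests)), function(r) {
      mu <- link_readout(link, tests$memory[r])
      obs <- saturate(mu + rnorm(n, 0, link$noise_sd), link$floor, link$ceiling)
      tibble::tibble(animal = seq_len(n), genotype = params$label,
                     task = tests$event[r], time_h = tests$t_test[r],
                     readout_pct = obs, memory_true = tests$memory[r],
                     seed = seed)
    }))
  })
}

# Vectorised model prediction of memory at every (event, offset) of a protocol
# for grids of candidate (K, tau2); tau1 and u fixed. Returns a matrix with
# one row per candidate and one column per test, columns ordered as
# expand_grid(event, offset) of the protocol.
predict_memory_grid <- function(K, tau2, tau1, u, proto) {
  events <- proto$events
  offsets <- proto$test_offsets
  limiting <- proto$effector_mode == "limiting"
  Ku <- K * u
  # analytic peak time and unsaturated peak difference per candidate
  tstar <- log(tau2 / tau1) / (1 / tau1 - 1 / tau2)
  peak <- Ku * (exp(-tstar / tau2) - exp(-tstar / tau1))
  need <- saturate(peak, 0, 1)
  diff_at <- function(dt) Ku * (exp(-dt / tau2) - exp(-dt / tau1)) * (dt >= 0)
  cols <- list()
  for (i in seq_len(nrow(events))) {
    have <- if (i == 1L || !limiting) rep(1, length(K)) else {
      prior <- seq_len(i - 1L)
      agg <- Reduce(`+`, lapply(prior, function(j)
        diff_at(events$t_on[i] - events$t_on[j])))
      1 - saturate(agg, 0, 1)
    }
    w <- if (limiting) pmin(have / need, 1) else rep(1, length(K))
    for (off in offsets) {
      pa <- saturate(diff_at(off), 0, 1)
      cols[[length(cols) + 1L]] <- pa / need * w
    }
  }
  do.call(cbind, cols)
}

#' Recover model parameters from cohort readouts by grid search
#'
#' Fits the steady-state gain `K` (shared by both pathways) and the weakening
#' time constant `tau2` to cohort behavioural means by exhaustive grid search,
#' minimising the squared error between observed group means and the
#' noise-free model-predicted readouts under the protocol that generated the
#' data. `tau1` and `u` are held at their known values.
#'
#' A ridge in the loss surface (a near-optimal set spanning most of a
#' parameter's grid range) marks the fit as non-identifiable — e.g. a single
#' genotype observed at a single time point below saturation carries no
#' information about `K`.
#'
#' @param readouts Cohort tibble from [generate_cohort()] (needs `task`,
#'   `time_h`, `readout_pct`).
#' @param proto The [protocol()] under which the readouts were collected.
#' @param link The [readout_link()] used.
#' @param tau1 Known strengthening time constant, hours.
#' @param u Known input magnitude.
#' @param K_grid,tau2_grid Candidate grids (strictly increasing, length >= 2).
#'
#' @return List: `best` (a [parameter_set()] at the argmin), `loss`
#'   (tibble `K`, `tau2`, `loss`), `non_identifiable` (logical: ridge in `K`
#'   or `tau2`).
#' @export
#' @examples
#' proto <- built_in_protocol("single")
#' coh <- generate_cohort(proto, default_parameters("control"),
#'                        readout_link("preference", noise_sd = 0), n = 4)
#' fit <- recover_parameters(coh, proto, readout_link("preference", noise_sd = 0),
#'                           K_grid = c(2, 3, 4), tau2_grid = c(24, 36, 48))
#' fit$best
recover_parameters <- function(readouts, proto, link, tau1 = 0.5, u = 0.125,
                               K_grid = seq(3, 12, by = 0.3),
                               tau2_grid = seq(48, 288, by = 6)) {
  if (length(K_grid) < 2L || length(tau2_grid) < 2L)
    stop("K_grid and tau2_grid must each contain at least two values", call. = FALSE)
  n_points <- dplyr::n_distinct(readouts[, c("task", "time_h")])
  n_geno <- if ("genotype" %in% names(readouts))
    dplyr::n_distinct(readouts$genotype) else 1L
  if (n_points < 2L && n_geno < 2L)
    warning("readouts span a single time point and genotype; ",
            "parameters are unlikely to be identifiable", call. = FALSE)

  obs <- readouts |>
    dplyr::summarise(mean_pct = mean(.data$readout_pct),
                     .by = c("task", "time_h"))
  # align observation order with the prediction columns
  events <- proto$events
  design <- tidyr::expand_grid(task = events$label, offset = proto$test_offsets)
  design$time_h <- events$t_on[match(design$task, events$label)] + design$offset
  obs <- dplyr::inner_join(design, obs, by = c("task", "time_h"))
  if (nrow(obs) == 0L)
    stop("readouts do not match the protocol's tests", call. = FALSE)

  cand <- tidyr::expand_grid(K = K_grid, tau2 = tau2_grid)
  sub <- protocol(events, obs$offset[!duplicated(obs$offset)], proto$effector_mode)
  pred_mem <- predict_memory_grid(cand$K, cand$tau2, tau1, u, sub)
  # keep only columns present in obs, in obs order
  full <- tidyr::expand_grid(task = events$label,
                             offset = sub$test_offsets)
  keep <- match(paste(obs$task, obs$offset), paste(full$task, full$offset))
  pred_pct <- link_readout(link, pred_mem[, keep, drop = FALSE])
  loss <- rowSums((pred_pct - matrix(obs$mean_pct, nrow(cand), nrow(obs),
                                     byrow = TRUE))^2)
  best <- which.min(loss)
  near <- loss <= min(loss) + 0.01 * (max(loss) - min(loss)) + 1e-12
  ridge_K <- diff(range(cand$K[near])) >= 0.8 * diff(range(K_grid))
  ridge_tau2 <- diff(range(cand$tau2[near])) >= 0.8 * diff(range(tau2_grid))
  list(best = parameter_set(tau1, cand$tau2[best], cand$K[best], cand$K[best],
                            u, "fitted"),
       loss = dplyr::mutate(cand, loss = loss),
       non_identifiable = ridge_K || ridge_tau2)
}

#' Monte-Carlo parameter-recovery study
#'
#' Repeatedly simulates cohorts at a known ("truth") parameter set and
#' re-estimates `(K, tau2)` with [recover_parameters()], reporting how often
#' both land within stated relative tolerances of the truth. The default
#' design observes a short-interval sequential protocol at several test
#' offsets, so that the interference penalty makes `K` identifiable and the
#' late readouts pin down `tau2`.
#'
#' @param truth The generating [parameter_set()].
#' @param n Animals per cohort.
#' @param noise_sd Readout noise sd, % units.
#' @param n_reps Number of replicate cohorts.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param K_tol,tau2_tol Relative tolerances counted as success.
#' @param proto Protocol used for data collection; default sequential-short
#'   with readouts at +6, +24, +72 and +168 h after each training.
#' @param link Readout link; default preference scale with `noise_sd`.
#'
#' @return List: `replicates` (tibble `rep`, `K_hat`, `tau2_hat`, `success`),
#'   `success_rate` in \[0, 1\].
#' @export
recovery_study <- function(truth = default_parameters("wt1d"), n = 30,
                           noise_sd = 5, n_reps = 100, seed = 1,
                           K_tol = 0.2, tau2_tol = 0.3,
                           proto = NULL, link = NULL) {
  if (is.null(proto))
    proto <- protocol(experience_events(c("task1", "task2"), c(0, 48)),
                      test_offsets = c(6, 24, 72, 168),
                      effector_mode = "limiting")
  if (is.null(link)) link <- readout_link("preference", noise_sd = noise_sd)
  reps <- lapply(seq_len(n_reps), function(r) {
    coh <- generate_cohort(proto, truth, link, n = n, seed = seed + r)
    fit <- recover_parameters(coh, proto, link, tau1 = truth$tau1, u = truth$u)
    tibble::tibble(
      rep = r, K_hat = fit$best$K1, tau2_hat = fit$best$tau2,
      success = abs(fit$best$K1 - truth$K1) <= K_tol * truth$K1 &&
        abs(fit$best$tau2 - truth$tau2) <= tau2_tol * truth$tau2)
  })
  reps <- dplyr::bind_rows(reps)
  list(replicates = reps, success_rate = mean(reps$success))
}
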
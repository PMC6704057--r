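#' Build a schedule of learning experiences
#'
#' Each experience is an ideal step input of magnitude `u` switched on at
#' `t_on` and persisting thereafter (the hippocampus is modelled as a time
#' integrator of the brief stimulus, so its area becomes a step).
#'
#' @param label Character vector of unique event labels.
#' @param t_on Onset times in hours (>= 0), nondecreasing.
#' @param u Input magnitudes; `NA` entries are filled with the parameter set's
#'   nominal `u` at simulation time.
#'
#' @return A tibble with columns `label`, `t_on`, `u`, class
#'   `memflex_events`.
#' @export
#' @examples
#' experience_events(c("NOL", "CFC"), c(0, 48))
experience_events <- function(label, t_on, u = NA_real_) {
  stopifnot(length(label) == length(t_on))
  if (anyDuplicated(label)) stop("event labels must be unique", call. = FALSE)
  if (any(t_on < 0)) stop("event onsets must be >= 0 h", call. = FALSE)
  ev <- tibble::tibble(label = as.character(label),
                       t_on = as.numeric(t_on),
                       u = rep_len(as.numeric(u), length(label)))
  ev <- ev[order(ev$t_on), ]
  class(ev) <- c("memflex_events", class(ev))
  ev
}

#' Define a learning protocol
#'
#' A protocol is an event schedule plus the times (offsets after each event's
#' onset) at which memory is read out, and the effector-capacity regime:
#' `"limiting"` applies the capped `have/need` weight of the finite-effector
#' model, `"excess"` assumes effectors are never scarce (weight 1).
#'
#' @param events An [experience_events()] schedule.
#' @param test_offsets Hours after each event onset at which memory is read
#'   out (> 0). The first offset is the canonical test used in summaries.
#' @param effector_mode `"limiting"` or `"excess"`.
#'
#' @return A `memflex_protocol` object.
#' @export
#' @examples
#' protocol(experience_events(c("NOL", "CFC"), c(0, 48)))
protocol <- function(events, test_offsets = 24, effector_mode = c("limiting", "excess")) {
  effector_mode <- match.arg(effector_mode)
  stopifnot(inherits(events, "memflex_events") || is.data.frame(events))
  if (any(test_offsets <= 0)) stop("test_offsets must be > 0 h", call. = FALSE)
  if (nrow(events) > 1 && anyDuplicated(events$t_on))
    warning("events with identical onsets; they will superpose", call. = FALSE)
  structure(list(events = events,
                 test_offsets = as.numeric(test_offsets),
                 effector_mode = effector_mode),
            class = "memflex_protocol")
}

#' @export
print.memflex_protocol <- function(x, ...) {
  cat(sprintf("<memflex_protocol> %d event(s), tests at +%s h, effectors %s\n",
              nrow(x$events), paste(x$test_offsets, collapse = "/"),
              x$effector_mode))
  print(tibble::as_tibble(x$events))
  invisible(x)
}

#' Built-in learning protocols
#'
#' Shipped schedules mirroring the behavioural designs the model was built to
#' probe: a single task; short-interval sequential training (task 1 at 0 h,
#' task 2 two days later at 48 h — train day 0, test day 1, second training
#' the next day); and long-interval sequential training (task 2 at 240 h, i.e.
#' ten days after the first training). Memory is read out 24 h after each
#' training.
#'
#' @param name One of `"single"`, `"sequential-short"`, `"sequential-long"`.
#' @param effector_mode `"limiting"` or `"excess"`.
#'
#' @return A [protocol()].
#' @export
#' @examples
#' built_in_protocol("sequential-short")
built_in_protocol <- function(name = c("single", "sequential-short", "sequential-long"),
                              effector_mode = c("limiting", "excess")) {
  name <- match.arg(name)
  effector_mode <- match.arg(effector_mode)
  ev <- switch(name,
    "single" = experience_events("task1", 0),
    "sequential-short" = experience_events(c("task1", "task2"), c(0, 48)),
    "sequential-long" = experience_events(c("task1", "task2"), c(0, 240)))
  protocol(ev, test_offsets = 24, effector_mode = effector_mode)
}

#' Peak pathway activity of an isolated event ("need")
#'
#' The peak pathway activity an event would reach in isolation, with
#' unlimited effectors, is the capacity required to learn it fully. Evaluated
#' in closed form at the analytic peak time.
#'
#' @param params A [parameter_set()].
#' @param u Input magnitude (defaults to the parameter set's nominal `u`).
#'
#' @return The scalar `need`, in \[0, 1\]. Zero when `u = 0` (memory is then
#'   undefined for that event).
#' @export
#' @examples
#' peak_activity(default_parameters("control"))
peak_activity <- function(params, u = params$u) {
  stopifnot(inherits(params, "memflex_params"))
  if (u == 0) return(0)
  tstar <- peak_time(params)
  event_activity(tstar, 0, params, u)
}

#' Effectors available at an event's onset ("have")
#'
#' The effector fraction left for event `i` when its stimulus arrives, given
#' the pathway activity still engaged by all prior events:
#' `1 - sat(sum_{j<i} (x1_j - x2_j) at t_on_i, 0, 1)`. The first event of any
#' schedule gets 1. Per-event differences are summed before the single
#' saturation.
#'
#' @param index Event position in the schedule (1-based).
#' @param events An [experience_events()] schedule.
#' @param params A [parameter_set()].
#'
#' @return Scalar `have` in \[0, 1\].
#' @export
#' @examples
#' ev <- experience_events(c("NOL", "CFC"), c(0, 48))
#' have_at_event(2, ev, default_parameters("wt1d"))
have_at_event <- function(index, events, params) {
  stopifnot(index >= 1, index <= nrow(events))
  if (index == 1L) return(1)
  t_now <- events$t_on[index]
  prior <- seq_len(index - 1L)
  u_i <- ifelse(is.na(events$u[prior]), params$u, events$u[prior])
  diffs <- vapply(prior, function(j)
    event_difference(t_now, events$t_on[j], params, u_i[j]), numeric(1))
  effectors_available(saturate(sum(diffs), 0, 1))
}

# Weight applied to an event's memory: min(have/need, 1) in limiting mode,
# 1 in excess mode. NA when need == 0 (memory undefined).
event_weight <- function(index, events, params, effector_mode) {
  u_i <- ifelse(is.na(events$u[index]), params$u, events$u[index])
  need <- peak_activity(params, u_i)
  if (need == 0) return(NA_real_)
  if (effector_mode == "excess") return(1)
  min(have_at_event(index, events, params) / need, 1)
}

#' Memory trajectory of one event within a schedule
#'
#' Memory attributable to event `i` at time `t` is its own pathway activity
#' normalised by the peak it would reach in isolation, weighted by the capped
#' effector ratio `min(have/need, 1)` (weight 1 in excess mode). Defined for
#' `t >= t_on`; earlier times return `NA`.
#'
#' @param t Time(s), hours; vectorised.
#' @param index Event position in the schedule (1-based).
#' @param events An [experience_events()] schedule.
#' @param params A [parameter_set()].
#' @param effector_mode `"limiting"` or `"excess"`.
#'
#' @return Memory value(s) in \[0, 1\] (`NA` before onset).
#' @export
#' @examples
#' ev <- experience_events("task1", 0)
#' memory_trajectory(24, 1, ev, default_parameters("control"))
memory_trajectory <- function(t, index, events, params,
                              effector_mode = c("limiting", "excess")) {
  effector_mode <- match.arg(effector_mode)
  u_i <- ifelse(is.na(events$u[index]), params$u, events$u[index])
  need <- peak_activity(params, u_i)
  if (need == 0)
    stop("memory is undefined for an event with zero input (need = 0)", call. = FALSE)
  w <- event_weight(index, events, params, effector_mode)
  m <- event_activity(t, events$t_on[index], params, u_i) / need * w
  m[t < events$t_on[index]] <- NA_real_
  m
}

#' Run a learning protocol
#'
#' Simulates every event of a protocol under a parameter set: per-event
#' strengthening/weakening signals and pathway activity on a time grid, the
#' aggregate activity and effectors available, the per-event `need`, `have`
#' and capped weight, and memory at each requested test time.
#'
#' @param proto A [protocol()].
#' @param params A [parameter_set()].
#' @param grid_step Time-grid resolution in hours (default 0.01 h, fine enough
#'   for `tau1 = 0.5` h).
#' @param horizon Simulation end time in hours; default: last test time +24 h.
#'
#' @return A `memflex_simulation` list with elements
#'   `trajectories` (tidy tibble: `t`, `event`, `x1`, `x2`,
#'   `pathway_activity`, `memory`), `aggregate` (tibble: `t`,
#'   `aggregate_activity`, `effectors_available`), `events` (tibble: `event`,
#'   `t_on`, `u`, `need`, `have`, `weight`), `tests` (tibble: `event`,
#'   `offset`, `t_test`, `memory`), plus `params` and the protocol.
#' @export
#' @examples
#' res <- run_protocol(built_in_protocol("sequential-short"),
#'                     default_parameters("wt1d"), grid_step = 0.1)
#' res$tests
run_protocol <- function(proto, params, grid_step = 0.01, horizon = NULL) {
  stopifnot(inherits(proto, "memflex_protocol"), inherits(params, "memflex_params"))
  events <- proto$events
  if (nrow(events) == 0L) {
    empty <- tibble::tibble(t = numeric(), event = character(), x1 = numeric(),
                            x2 = numeric(), pathway_activity = numeric(),
                            memory = numeric())
    return(structure(list(
      trajectories = empty,
      aggregate = tibble::tibble(t = numeric(), aggregate_activity = numeric(),
                                 effectors_available = numeric()),
      events = tibble::tibble(event = character(), t_on = numeric(), u = numeric(),
                              need = numeric(), have = numeric(), weight = numeric()),
      tests = tibble::tibble(event = character(), offset = numeric(),
                             t_test = numeric(), memory = numeric()),
      params = params, protocol = proto), class = "memflex_simulation"))
  }
  if (is.null(horizon))
    horizon <- max(events$t_on) + max(proto$test_offsets) + 24
  grid <- seq(0, horizon, by = grid_step)
  u_ev <- ifelse(is.na(events$u), params$u, events$u)

  per_event <- lapply(seq_len(nrow(events)), function(i) {
    x1 <- first_order_step(grid, events$t_on[i], params$tau1, params$K1, u_ev[i])
    x2 <- first_order_step(grid, events$t_on[i], params$tau2, params$K2, u_ev[i])
    list(x1 = x1, x2 = x2, diff = x1 - x2, pa = saturate(x1 - x2, 0, 1))
  })
  agg_diff <- Reduce(`+`, lapply(per_event, `[[`, "diff"))
  agg <- saturate(agg_diff, 0, 1)

  summary_tbl <- tibble::tibble(
    event = events$label, t_on = events$t_on, u = u_ev,
    need = vapply(u_ev, function(ui) peak_activity(params, ui), numeric(1)),
    have = vapply(seq_len(nrow(events)), function(i)
      have_at_event(i, events, params), numeric(1)),
    weight = vapply(seq_len(nrow(events)), function(i)
      event_weight(i, events, params, proto$effector_mode), numeric(1))
  )

  traj <- dplyr::bind_rows(lapply(seq_len(nrow(events)), function(i) {
    mem <- if (summary_tbl$need[i] > 0) {
      m <- per_event[[i]]$pa / summary_tbl$need[i] * summary_tbl$weight[i]
      m[grid < events$t_on[i]] <- NA_real_
      m
    } else rep(NA_real_, length(grid))
    tibble::tibble(t = grid, event = events$label[i],
                   x1 = per_event[[i]]$x1, x2 = per_event[[i]]$x2,
                   pathway_activity = per_event[[i]]$pa, memory = mem)
  }))

  tests <- tidyr::expand_grid(i = seq_len(nrow(events)), offset = proto$test_offsets)
  tests <- tibble::tibble(
    event = events$label[tests$i],
    offset = tests$offset,
    t_test = events$t_on[tests$i] + tests$offset,
    memory = vapply(seq_len(nrow(tests)), function(r) {
      i <- tests$i[r]
      if (summary_tbl$need[i] == 0) return(NA_real_)
      event_activity(events$t_on[i] + tests$offset[r], events$t_on[i],
                     params, u_ev[i]) / summary_tbl$need[i] * summary_tbl$weight[i]
    }, numeric(1)))

  structure(list(
    trajectories = traj,
    aggregate = tibble::tibble(t = grid, aggregate_activity = agg,
                               effectors_available = 1 - agg),
    events = summary_tbl, tests = tests,
    params = params, protocol = proto), class = "memflex_simulation")
}

#' @export
print.memflex_simulation <- function(x, ...) {
  cat(sprintf("<memflex_simulation> genotype '%s', %d event(s), effectors %s\n",
              x$params$label, nrow(x$events), x$protocol$effector_mode))
  if (nrow(x$tests)) print(x$tests)
  invisible(x)
}

#' Sweep the input magnitude
#'
#' Re-runs a protocol across a range of input magnitudes `u` (applied to every
#' event) for one or more genotypes, recording memory at each test. The
#' default range 0.025-0.15 spans the parameter-variation band around the
#' nominal `u = 0.125`.
#'
#' @param proto A [protocol()].
#' @param params A [parameter_set()] or a list of them.
#' @param u_values Numeric vector of input magnitudes.
#'
#' @return Tibble with one row per `(u, genotype, event, offset)`:
#'   columns `u`, `genotype`, `event`, `offset`, `need`, `have`, `weight`,
#'   `memory` (`NA` with `defined = FALSE` when `u = 0`).
#' @export
#' @examples
#' sweep_input(built_in_protocol("single"), default_parameters("control"),
#'             u_values = c(0.025, 0.125, 0.15))
sweep_input <- function(proto, params, u_values = seq(0.025, 0.15, length.out = 6)) {
  if (length(u_values) == 0L) stop("u_values must be non-empty", call. = FALSE)
  if (inherits(params, "memflex_params")) params <- list(params)
  Kmax <- max(vapply(params, function(p) max(p$K1, p$K2), numeric(1)))
  if (any(u_values > 1 / Kmax + 1e-12))
    warning("some u values exceed 1/K; pathway activity will saturate", call. = FALSE)
  rows <- lapply(params, function(p) {
    dplyr::bind_rows(lapply(u_values, function(uu) {
      ev <- proto$events
      ev$u <- rep(uu, nrow(ev))
      p_u <- parameter_set(p$tau1, p$tau2, p$K1, p$K2, uu, p$label)
      pr <- protocol(ev, proto$test_offsets, proto$effector_mode)
      if (uu == 0) {
        return(tidyr::expand_grid(event = ev$label, offset = proto$test_offsets) |>
                 dplyr::mutate(u = uu, genotype = p$label, need = 0,
                               have = NA_real_, weight = NA_real_,
                               memory = NA_real_, defined = FALSE))
      }
      res <- run_protocol(pr, p_u, grid_step = 1)  # tests use closed form
      dplyr::left_join(res$tests, res$events[, c("event", "need", "have", "weight")],
                       by = "event") |>
        dplyr::mutate(u = uu, genotype = p$label, defined = TRUE) |>
        dplyr::select("event", "offset", "u", "genotype", "need",
                      "have", "weight", "memory", "defined")
    }))
  })
  dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$genotype, .data$u, .data$event, .data$offset)
}

#' Plot simulated trajectories
#'
#' Pathway activity and memory over time for each event of a simulation.
#'
#' @param sim A `memflex_simulation` from [run_protocol()].
#'
#' @return A ggplot object.
#' @export
plot_simulation <- function(sim) {
  stopifnot(inherits(sim, "memflex_simulation"))
  long <- tidyr::pivot_longer(sim$trajectories,
                              c("pathway_activity", "memory"),
                              names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = .data$event)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~quantity, ncol = 1) +
    ggplot2::labs(x = "time (h)", y = NULL,
                  title = sprintf("genotype: %s", sim$params$label)) +
    ggplot2::theme_minimal()
}
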
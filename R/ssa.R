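#' Configuration for stochastic simulations
#'
#' @param seed optional non-negative integer seed; when given, the run is
#'   bit-reproducible (the seed is applied with [set.seed()] at the start of
#'   the run). When `NULL` the current RNG stream is used.
#' @param max_events hard cap on reaction events per run (default 1e7); runs
#'   hitting the cap are flagged `truncated`.
#' @param record_mode `"grid"` (states sampled on a uniform time grid) or
#'   `"events"` (full event log).
#' @return an object of class `pm_ssa_config`.
#' @export
ssa_config <- function(seed = NULL, max_events = 1e7,
                       record_mode = c("grid", "events")) {
  record_mode <- match.arg(record_mode)
  if (!is.null(seed)) {
    stopifnot(length(seed) == 1, is.finite(seed), seed >= 0,
              seed == round(seed))
    seed <- as.integer(seed)
  }
  stopifnot(max_events >= 1)
  structure(list(seed = seed, max_events = as.integer(max_events),
                 record_mode = record_mode),
            class = "pm_ssa_config")
}

#' Exact stochastic simulation (Gillespie direct method)
#'
#' Simulates the continuous-time Markov chain of the compartment model with
#' propensities `b_i x_i` (birth in compartment `i`), `d_i x_i` (death),
#' `eps x_i` for `i = 1..n` (leach `i -> i-1`) and `mu x_0` (switch
#' `0 -> n`). Reactions are enumerated in fixed compartment-then-type order
#' (birth, death, leach/switch per compartment); waiting times are
#' inverse-CDF exponential draws and the reaction is selected by one uniform
#' draw against the cumulative propensity vector, so identical seed and
#' configuration give an identical event sequence.
#'
#' Extinction before `t_end` ends the trajectory at the extinction time with
#' `extinct = TRUE` (not an error); exceeding `max_events` sets
#' `truncated = TRUE`.
#'
#' @param params a [model_params()] object.
#' @param initial integer-valued [compartment_state()] or numeric vector.
#' @param t_end end time.
#' @param config an [ssa_config()].
#' @param dt_out grid step for `record_mode = "grid"`.
#' @return for `"grid"` mode a `pm_trajectory` (integer-valued states);
#'   for `"events"` mode an object of class `pm_event_log`: a data.frame
#'   `time, event, compartment, x0..xn` plus flags.
#' @examples
#' p <- model_params(4, mu = 0.2, epsilon = 0.5, birth = 1, death = 0.98)
#' tr <- gillespie(p, all_off_state(4, 100), t_end = 5, ssa_config(seed = 1))
#' @export
gillespie <- function(params, initial, t_end, config = ssa_config(),
                      dt_out = 0.1) {
  stopifnot(is_pm_params(params), inherits(config, "pm_ssa_config"),
            t_end > 0)
  st <- as_state(initial, params$n_on)
  if (any(st$abundances != round(st$abundances)))
    stop("SSA requires integer initial abundances", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  event_log <- config$record_mode == "events"
  grid <- if (event_log) numeric(0) else {
    g <- seq(st$time, t_end, by = dt_out)
    if (g[length(g)] < t_end) g <- c(g, t_end)
    g
  }
  res <- gillespie_cpp(st$abundances, params$mu, params$epsilon,
                       params$birth, params$death, st$time, t_end,
                       grid, config$max_events, event_log)
  if (event_log) {
    m <- res$events
    types <- c("birth", "death", "leach", "switch")
    df <- data.frame(time = m[, 1],
                     event = types[m[, 2] + 1],
                     compartment = as.integer(m[, 3]))
    states <- m[, -(1:3), drop = FALSE]
    colnames(states) <- paste0("x", 0:params$n_on)
    out <- cbind(df, as.data.frame(states))
    structure(list(events = out, final_time = res$final_time,
                   final_state = res$final_state, n_events = res$n_events,
                   extinct = res$extinct, truncated = res$truncated,
                   params = params),
              class = "pm_event_log")
  } else {
    states <- res$grid_states
    colnames(states) <- paste0("x", 0:params$n_on)
    keep <- if (res$extinct || res$truncated) grid <= res$final_time else
      rep(TRUE, length(grid))
    tr <- new_trajectory(grid[keep], states[keep, , drop = FALSE], params,
                         extinct = res$extinct, truncated = res$truncated)
    tr
  }
}

#' @export
print.pm_event_log <- function(x, ...) {
  cat("<pm_event_log>", nrow(x$events), "events to t =",
      format(x$final_time, digits = 8),
      if (x$extinct) " [extinct]" else "",
      if (x$truncated) " [truncated]" else "", "\n")
  invisible(x)
}

#' Sample single-cell 'on' residence times
#'
#' First-passage times of one cell placed in the freshest 'on' compartment
#' `n_on` until it reaches 'off' (compartment 0), with birth and death set
#' to zero so the pure leaching chain governs the passage. Each sample is an
#' explicit event-loop simulation of the `n_on` successive leaching steps, so
#' the residence time is the sum of `n_on` independent exponential(`epsilon`)
#' waits: gamma with shape `n_on` and rate `epsilon`.
#'
#' @param n_on memory length.
#' @param epsilon leaching rate.
#' @param n_samples number of independent first-passage samples.
#' @param config an [ssa_config()] (only `seed` is used).
#' @return an object of class `pm_residence`: `durations`, `n_on`,
#'   `epsilon`, `seed`, `n_samples`.
#' @examples
#' rs <- sample_residence_times(4, 0.3, 1000, ssa_config(seed = 1))
#' mean(rs$durations)   # close to 4 / 0.3 = 13.33
#' @export
sample_residence_times <- function(n_on, epsilon, n_samples,
                                   config = ssa_config()) {
  stopifnot(n_on >= 1, n_on == round(n_on), epsilon > 0, n_samples >= 1,
            inherits(config, "pm_ssa_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  durations <- residence_cpp(as.integer(n_on), epsilon,
                             as.integer(n_samples))
  structure(list(durations = durations, n_on = as.integer(n_on),
                 epsilon = epsilon, seed = config$seed,
                 n_samples = as.integer(n_samples)),
            class = "pm_residence")
}

#' @export
print.pm_residence <- function(x, ...) {
  cat("<pm_residence>", x$n_samples, "first-passage times, n_on =", x$n_on,
      " epsilon =", x$epsilon, "\n")
  cat("  mean =", format(mean(x$durations), digits = 6),
      " (theory ", format(x$n_on / x$epsilon, digits = 6), ")\n")
  invisible(x)
}

#' Write / read residence-time samples
#'
#' One duration per line in plain text, with a YAML sidecar
#' `<path>.meta.yaml` recording `n_on`, `epsilon`, `seed`, `n_samples`.
#'
#' @param sample a `pm_residence` object.
#' @param path output path.
#' @return `read_residence_times()` returns a numeric vector of durations;
#'   `write_residence_times()` returns `path` invisibly.
#' @export
write_residence_times <- function(sample, path) {
  stopifnot(inherits(sample, "pm_residence"))
  writeLines(sprintf("%.17g", sample$durations), path)
  yaml::write_yaml(list(n_on = sample$n_on, epsilon = sample$epsilon,
                        seed = sample$seed, n_samples = sample$n_samples),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_residence_times
#' @export
read_residence_times <- function(path) {
  as.numeric(readLines(path))
}

#' Write an SSA event log
#'
#' Tab-separated `time event compartment x0 ... xn`, one reaction per row.
#'
#' @param log a `pm_event_log` from [gillespie()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  stopifnot(inherits(log, "pm_event_log"))
  write_tsv_table(log$events, path)
  invisible(path)
}
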
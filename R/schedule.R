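#' Environment schedules: piecewise-constant seasons
#'
#' An environment schedule is an ordered list of seasons, each a duration, a
#' label (`"permissive"` or `"treatment"`), and the [model_params()] in force
#' during the season. Parameters switch instantaneously at season boundaries;
#' the state vector carries over unchanged.
#'
#' @param seasons a list of lists with fields `duration`, `label`, `params`.
#' @param id optional identifier carried into fitness records.
#' @return an object of class `pm_schedule` with fields `seasons`,
#'   `total_duration`, `treatment_length`, `onset`, `id`.
#' @export
environment_schedule <- function(seasons, id = NULL) {
  stopifnot(is.list(seasons), length(seasons) >= 1)
  n_on <- NULL
  for (s in seasons) {
    stopifnot(is.numeric(s$duration), s$duration > 0,
              s$label %in% c("permissive", "treatment"),
              is_pm_params(s$params))
    if (is.null(n_on)) n_on <- s$params$n_on
    else if (s$params$n_on != n_on)
      stop("all seasons must share the same n_on (compartment vectors ",
           "would be incompatible)", call. = FALSE)
  }
  durs <- vapply(seasons, `[[`, numeric(1), "duration")
  labs <- vapply(seasons, `[[`, character(1), "label")
  treat <- sum(durs[labs == "treatment"])
  onset <- if (any(labs == "treatment"))
    sum(durs[seq_len(which(labs == "treatment")[1] - 1)]) else NA_real_
  structure(
    list(seasons = seasons, total_duration = sum(durs),
         treatment_length = treat, onset = onset, id = id),
    class = "pm_schedule")
}

#' @export
print.pm_schedule <- function(x, ...) {
  labs <- vapply(x$seasons, `[[`, character(1), "label")
  durs <- vapply(x$seasons, `[[`, numeric(1), "duration")
  cat("<pm_schedule>", if (!is.null(x$id)) paste0("[", x$id, "] "),
      paste(sprintf("%s(%g)", labs, durs), collapse = " -> "),
      " total =", x$total_duration, "\n")
  invisible(x)
}

#' Single-block treatment schedule
#'
#' Builds the three-season schedule `permissive(onset) ->
#' treatment(treatment_length) -> permissive(total - onset -
#' treatment_length)`; zero-duration seasons are dropped.
#'
#' @param treatment_length non-negative treatment duration.
#' @param onset time of treatment onset (permissive growth before it).
#' @param total total schedule duration.
#' @param permissive_params,treatment_params [model_params()] in force during
#'   the respective seasons (same `n_on`).
#' @param id optional identifier.
#' @return a `pm_schedule`.
#' @export
make_treatment_schedule <- function(treatment_length, onset, total,
                                    permissive_params, treatment_params,
                                    id = NULL) {
  stopifnot(treatment_length >= 0, onset >= 0, total > 0)
  if (onset + treatment_length > total)
    stop("onset + treatment_length exceeds the total duration", call. = FALSE)
  pieces <- list(
    list(duration = onset, label = "permissive", params = permissive_params),
    list(duration = treatment_length, label = "treatment",
         params = treatment_params),
    list(duration = total - onset - treatment_length, label = "permissive",
         params = permissive_params))
  pieces <- Filter(function(s) s$duration > 0, pieces)
  environment_schedule(pieces, id = id)
}

#' Grid of treatment schedules of increasing length
#'
#' The default grid of the fitness protocol: `n_sequences` schedules of equal
#' total duration whose single treatment block grows by one time unit per
#' row (`treatment_length = 1, 2, ..., n_sequences`), all with a common
#' onset. Defaults: 84 sequences, total 165, onset 40.
#'
#' @param n_sequences number of schedules.
#' @param total total duration of each schedule.
#' @param onset common treatment onset.
#' @inheritParams make_treatment_schedule
#' @return a list of `pm_schedule` objects.
#' @export
make_grid <- function(n_sequences = 84, total = 165, onset = 40,
                      permissive_params, treatment_params) {
  stopifnot(n_sequences >= 1)
  if (onset + n_sequences > total)
    stop("longest treatment exceeds total - onset", call. = FALSE)
  lapply(seq_len(n_sequences), function(L)
    make_treatment_schedule(L, onset, total, permissive_params,
                            treatment_params, id = L))
}

#' Integrate the deterministic model through a schedule
#'
#' Piecewise matrix-exponential propagation with state continuity at season
#' boundaries. The output grid has step `dt_out` within each season, with
#' boundary times always included.
#'
#' @param schedule a `pm_schedule`.
#' @param initial a [compartment_state()] or numeric abundance vector.
#' @param dt_out output grid step.
#' @return a `pm_trajectory`; its `params` field holds the first season's
#'   parameters.
#' @export
integrate_schedule <- function(schedule, initial, dt_out = 0.01) {
  stopifnot(inherits(schedule, "pm_schedule"))
  n_on <- schedule$seasons[[1]]$params$n_on
  st <- as_state(initial, n_on)
  if (sum(st$abundances) <= 0)
    stop("initial state must contain at least one cell", call. = FALSE)
  t0 <- st$time
  x <- st$abundances
  all_times <- t0
  all_states <- matrix(x, 1)
  t_cursor <- t0
  for (s in schedule$seasons) {
    tr <- integrate_ode(s$params, compartment_state(x, time = t_cursor),
                        t_end = t_cursor + s$duration, dt_out = dt_out)
    all_times <- c(all_times, tr$times[-1])
    all_states <- rbind(all_states, tr$states[-1, , drop = FALSE])
    x <- tr$states[nrow(tr$states), ]
    t_cursor <- t_cursor + s$duration
  }
  colnames(all_states) <- paste0("x", 0:n_on)
  new_trajectory(all_times, all_states, schedule$seasons[[1]]$params)
}

# endpoint-only propagation through a schedule; `cache` is an environment
# memoising expm(A * duration) across schedules sharing season parameters
propagate_schedule <- function(schedule, x0, cache = new.env(parent = emptyenv())) {
  x <- x0
  for (s in schedule$seasons) {
    key <- paste0(s$label, "|", s$params$n_on, "|", s$params$mu, "|",
                  s$params$epsilon, "|", s$params$birth[1], "|",
                  s$params$death[1], "|", s$duration)
    P <- cache[[key]]
    if (is.null(P)) {
      P <- expm_dense(build_rate_matrix(s$params) * s$duration)
      cache[[key]] <- P
    }
    x <- as.numeric(P %*% x)
  }
  x
}

#' Write / read a schedule as a tab-separated season table
#'
#' One season per line with columns `start end label mu b_off d_off b_on
#' d_on epsilon` (homogeneous 'on' rates assumed, as in the persistence
#' parameterization). `read_schedule()` needs the memory length, which the
#' table does not carry.
#'
#' @param schedule a `pm_schedule`.
#' @param path file path.
#' @param n_on memory length used to rebuild per-season [model_params()].
#' @return `read_schedule()` returns a `pm_schedule`; `write_schedule()`
#'   returns `path` invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "pm_schedule"))
  start <- 0
  rows <- lapply(schedule$seasons, function(s) {
    r <- data.frame(start = start, end = start + s$duration, label = s$label,
                    mu = s$params$mu, b_off = s$params$birth[1],
                    d_off = s$params$death[1], b_on = s$params$birth[2],
                    d_on = s$params$death[2], epsilon = s$params$epsilon)
    start <<- start + s$duration
    r
  })
  write_tsv_table(do.call(rbind, rows), path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path, n_on) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  seasons <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    list(duration = r$end - r$start, label = r$label,
         params = model_params(n_on, r$mu, r$epsilon,
                               birth = c(r$b_off, rep(r$b_on, n_on)),
                               death = c(r$d_off, rep(r$d_on, n_on))))
  })
  environment_schedule(seasons)
}
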
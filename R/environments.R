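#' Persistence parameterization of one season
#'
#' The antibiotic-treatment setting treats 'off' cells as the normal
#' phenotype and 'on' cells as persisters (no growth, drug-tolerant). Under
#' permissive conditions 'off' cells grow at `b_off - d_off = 1 - 0.98 =
#' 0.02` and the switch is inactive (`mu = 0`); under treatment 'off' cells
#' die at net `-0.02` (`d_off = 1.02`) and the switch is triggered
#' (`mu = 0.2`). Persisters never grow or die (`b_on = d_on = 0`) and leach
#' at `epsilon = 0.25` in both seasons.
#'
#' @param n_on memory length.
#' @param season `"permissive"` or `"treatment"`.
#' @param epsilon leaching rate (default 0.25).
#' @param mu_treatment switch rate under treatment (default 0.2).
#' @param growth net 'off' growth rate magnitude (default 0.02; applied as
#'   `+growth` permissive, `-growth` treatment via the death rate).
#' @return a [model_params()] object.
#' @export
persistence_params <- function(n_on, season = c("permissive", "treatment"),
                               epsilon = 0.25, mu_treatment = 0.2,
                               growth = 0.02) {
  season <- match.arg(season)
  if (season == "permissive")
    model_params(n_on, mu = 0, epsilon = epsilon,
                 birth = c(1, rep(0, n_on)), death = c(1 - growth, rep(0, n_on)))
  else
    model_params(n_on, mu = mu_treatment, epsilon = epsilon,
                 birth = c(1, rep(0, n_on)), death = c(1 + growth, rep(0, n_on)))
}

#' Fitness of a memory lineage over one environment schedule
#'
#' Runs the deterministic model through `schedule` for (a) the memory
#' lineage at the requested `n_on` and (b) the memoryless comparator
#' (`n_on = 1`) with leaching rate `epsilon / n_on`
#' ([memoryless_equivalent_epsilon()]), which shares the memory lineage's
#' equilibrium 'on' fraction under sustained switching. Both start from
#' `initial_off_cells` 'off' cells. Absolute growth is
#' `g = log(N(t_max) / N(0))`; relative fitness is the difference of the two
#' absolute growth rates divided by the total duration,
#' `(g_m - g_mless) / t_max`.
#'
#' @param n_on memory length of the focal lineage.
#' @param schedule a `pm_schedule` (its per-season parameters are re-sized to
#'   `n_on` for the memory lineage and to the calibrated memoryless lineage).
#' @param initial_off_cells starting 'off' population (default 1000).
#' @param cache optional environment memoising season propagators across
#'   calls (used by [fitness_landscape()]).
#' @return a one-row data.frame: `n_on`, `schedule_id`, `treatment_length`,
#'   `onset`, `epsilon`, `epsilon_memoryless`, `g_m`, `g_mless`, `r`,
#'   `extinct_flag`.
#' @export
lineage_fitness <- function(n_on, schedule, initial_off_cells = 1000,
                            cache = new.env(parent = emptyenv())) {
  stopifnot(inherits(schedule, "pm_schedule"), n_on >= 1)
  eps <- schedule$seasons[[1]]$params$epsilon
  eps_mless <- eps / n_on

  resized <- function(target_n, target_eps) {
    seasons <- lapply(schedule$seasons, function(s) {
      p <- resize_params(s$params, target_n)
      p$epsilon <- target_eps
      list(duration = s$duration, label = s$label, params = p)
    })
    environment_schedule(seasons, id = schedule$id)
  }
  sched_m <- resized(n_on, eps)
  sched_l <- resized(1L, eps_mless)

  g_of <- function(sch, n) {
    x0 <- c(initial_off_cells, rep(0, n))
    xf <- propagate_schedule(sch, x0, cache = cache)
    Nf <- sum(xf)
    if (Nf <= 0) return(-Inf)
    log(Nf / initial_off_cells)
  }
  g_m <- g_of(sched_m, n_on)
  g_mless <- g_of(sched_l, 1L)
  r <- (g_m - g_mless) / schedule$total_duration
  data.frame(
    n_on = n_on,
    schedule_id = if (is.null(schedule$id)) NA_integer_ else schedule$id,
    treatment_length = schedule$treatment_length,
    onset = schedule$onset,
    epsilon = eps, epsilon_memoryless = eps_mless,
    g_m = g_m, g_mless = g_mless, r = r,
    extinct_flag = !is.finite(g_m))
}

#' Fitness landscape over memory sizes and treatment schedules
#'
#' Crosses memory sizes (default `n_on = 1..31`) with a schedule grid
#' (default [make_grid()]'s 84 sequences) and computes [lineage_fitness()]
#' for every pair. Season propagators are cached per lineage, so the default
#' 31 x 84 landscape runs in seconds.
#'
#' @param n_on_range integer vector of memory sizes.
#' @param grid list of `pm_schedule` objects (default the 84-sequence grid at
#'   the persistence parameterization with `n_on = 1` placeholders).
#' @param initial_off_cells starting 'off' population.
#' @return a data.frame with one row per (lineage, schedule) pair, columns as
#'   in [lineage_fitness()].
#' @export
fitness_landscape <- function(n_on_range = 1:31, grid = NULL,
                              initial_off_cells = 1000) {
  if (is.null(grid))
    grid <- make_grid(permissive_params = persistence_params(1, "permissive"),
                      treatment_params = persistence_params(1, "treatment"))
  rows <- vector("list", length(n_on_range) * length(grid))
  k <- 1L
  for (n in n_on_range) {
    cache <- new.env(parent = emptyenv())
    for (sch in grid) {
      rows[[k]] <- lineage_fitness(n, sch, initial_off_cells, cache = cache)
      k <- k + 1L
    }
  }
  do.call(rbind, rows)
}

#' Write a fitness landscape table
#'
#' Tab-separated with columns `schedule_id treatment_length onset n_on
#' epsilon epsilon_memoryless g_m g_mless r extinct_flag`.
#'
#' @param landscape a data.frame from [fitness_landscape()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(landscape, path) {
  cols <- c("schedule_id", "treatment_length", "onset", "n_on", "epsilon",
            "epsilon_memoryless", "g_m", "g_mless", "r", "extinct_flag")
  write_tsv_table(landscape[, cols], path)
  invisible(path)
}
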
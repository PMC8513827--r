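#' Generate seeded fixture files
#'
#' Emits small, deterministic test inputs so every module can be exercised
#' from the shell with no external data: an exact-gamma sample with known
#' parameters, a short SSA event log, an ODE trajectory with a known
#' transient, and a three-season schedule file. Each file carries a YAML
#' metadata sidecar with the generating configuration and package version.
#'
#' @param seed non-negative integer seed.
#' @param outdir writable output directory (created if missing).
#' @return named character vector of the files written, invisibly.
#' @export
generate_fixtures <- function(seed, outdir) {
  stopifnot(length(seed) == 1, seed >= 0, seed == round(seed))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  ver <- as.character(packageVersion("phenomem"))
  files <- c()
  sidecar <- function(path, cfg) {
    yaml::write_yaml(c(cfg, list(seed = as.integer(seed),
                                 package_version = ver)),
                     paste0(path, ".meta.yaml"))
  }

  # exact gamma draws, known shape/rate, for fit_gamma recovery
  set.seed(seed)
  g <- rgamma(5000, shape = 2, rate = 1)
  p1 <- file.path(outdir, "gamma_shape2_rate1.txt")
  writeLines(sprintf("%.17g", g), p1)
  sidecar(p1, list(kind = "gamma_sample", shape = 2, rate = 1, n = 5000))
  files["gamma_sample"] <- p1

  # short SSA event log
  p <- model_params(2, mu = 0.3, epsilon = 0.4, birth = 0.5, death = 0.3)
  log <- gillespie(p, all_off_state(2, 20), t_end = 4,
                   ssa_config(seed = seed, record_mode = "events"))
  p2 <- file.path(outdir, "ssa_event_log.tsv")
  write_event_log(log, p2)
  sidecar(p2, list(kind = "ssa_event_log", n_on = 2, mu = 0.3, epsilon = 0.4,
                   birth = 0.5, death = 0.3, n_cells = 20, t_end = 4))
  files["ssa_event_log"] <- p2

  # ODE trajectory with a known overshoot (n_on = 8 from all-'off')
  p8 <- model_params(8, mu = 0.2, epsilon = 0.5, birth = 1, death = 0.98)
  tr <- integrate_ode(p8, all_off_state(8), t_end = 60, dt_out = 0.1)
  p3 <- file.path(outdir, "ode_trajectory.tsv")
  write_trajectory(tr, p3)
  sidecar(p3, list(kind = "ode_trajectory", n_on = 8, mu = 0.2, epsilon = 0.5,
                   birth = 1, death = 0.98, t_end = 60, dt_out = 0.1))
  files["ode_trajectory"] <- p3

  # three-season treatment schedule
  sch <- make_treatment_schedule(42, onset = 40, total = 165,
                                 persistence_params(1, "permissive"),
                                 persistence_params(1, "treatment"))
  p4 <- file.path(outdir, "schedule_3season.tsv")
  write_schedule(sch, p4)
  sidecar(p4, list(kind = "schedule", treatment_length = 42, onset = 40,
                   total = 165))
  files["schedule"] <- p4

  invisible(files)
}
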
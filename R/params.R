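#' Model parameters for one lineage
#'
#' Bundles the full parameterization of a memory lineage: the number of 'on'
#' compartments `n_on`, the 'off'->'on' switch rate `mu`, the leaching rate
#' `epsilon` between successive 'on' compartments (compartment 1 leaches to
#' 'off'), and per-compartment birth/death rates. Compartment 0 is 'off';
#' compartments 1..n_on are 'on' substates, with `n_on` the freshest (cells
#' switching 'on' enter there).
#'
#' @param n_on positive integer, number of 'on' compartments (memory length).
#' @param mu non-negative switch rate ('off' -> compartment `n_on`), per unit
#'   time.
#' @param epsilon positive leaching rate, per unit time.
#' @param birth,death non-negative birth/death rates per compartment; either a
#'   scalar (broadcast to all `n_on + 1` compartments) or a vector of length
#'   `n_on + 1` ordered as compartment 0 ('off') first.
#' @return an object of class `pm_params`.
#' @examples
#' p <- model_params(n_on = 4, mu = 0.2, epsilon = 0.5, birth = 1, death = 0.98)
#' build_rate_matrix(p)
#' @export
model_params <- function(n_on, mu, epsilon, birth, death) {
  if (length(n_on) != 1L || !is.finite(n_on) || n_on < 1 || n_on != round(n_on))
    stop("`n_on` must be a single positive integer", call. = FALSE)
  n_on <- as.integer(n_on)
  if (length(mu) != 1L || !is.finite(mu) || mu < 0)
    stop("`mu` must be a single non-negative number", call. = FALSE)
  if (length(epsilon) != 1L || !is.finite(epsilon) || epsilon <= 0)
    stop("`epsilon` must be a single positive number", call. = FALSE)
  nc <- n_on + 1L
  birth <- broadcast_rates(birth, nc, "birth")
  death <- broadcast_rates(death, nc, "death")
  structure(
    list(n_on = n_on, mu = as.numeric(mu), epsilon = as.numeric(epsilon),
         birth = birth, death = death),
    class = "pm_params")
}

broadcast_rates <- function(x, nc, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0))
    stop("`", what, "` rates must be non-negative numbers", call. = FALSE)
  if (length(x) == 1L) x <- rep(as.numeric(x), nc)
  if (length(x) != nc)
    stop("`", what, "` must have length 1 or n_on + 1 (= ", nc, "), got ",
         length(x), call. = FALSE)
  as.numeric(x)
}

#' @export
print.pm_params <- function(x, ...) {
  cat("<pm_params> n_on =", x$n_on, " mu =", x$mu, " epsilon =", x$epsilon, "\n")
  cat("  birth:", paste(signif(x$birth, 6), collapse = " "), "\n")
  cat("  death:", paste(signif(x$death, 6), collapse = " "), "\n")
  invisible(x)
}

is_pm_params <- function(x) inherits(x, "pm_params")

#' Test whether growth rates are fully symmetric
#'
#' Symmetric growth means all compartments share one birth rate and one death
#' rate; several closed forms (asymptotic growth `b - d`, equilibrium 'on'
#' fraction) hold only in this case.
#'
#' @param params a [model_params()] object.
#' @param tol absolute tolerance for rate equality.
#' @return logical.
#' @export
is_symmetric_growth <- function(params, tol = 0) {
  stopifnot(is_pm_params(params))
  diff(range(params$birth)) <= tol && diff(range(params$death)) <= tol
}

#' Calibrated leaching rate for an equivalent memoryless lineage
#'
#' A memoryless lineage (`n_on = 1`) with leaching rate `epsilon / n_on`
#' has the same equilibrium 'on' fraction, `mu / (eps' + mu) =
#' n_on * mu / (epsilon + n_on * mu)`, and the same mean 'on' residence time
#' (`n_on / epsilon`) as the memory lineage.
#'
#' @param params a [model_params()] object with symmetric growth.
#' @return the calibrated leaching rate, a positive scalar.
#' @export
memoryless_equivalent_epsilon <- function(params) {
  stopifnot(is_pm_params(params))
  if (!is_symmetric_growth(params))
    stop("calibration is defined for symmetric growth; use spectral_summary() ",
         "for asymmetric lineages", call. = FALSE)
  params$epsilon / params$n_on
}

#' Re-size a parameter set to a different memory length
#'
#' Keeps `mu` and `epsilon` and the 'off' compartment rates; the 'on'
#' compartment rates must be homogeneous and are broadcast to the new chain
#' length. Used by the fitness protocol to run one season parameterization at
#' many memory sizes.
#'
#' @param params a [model_params()] object.
#' @param n_on new memory length.
#' @return a [model_params()] object with `n_on` 'on' compartments.
#' @export
resize_params <- function(params, n_on) {
  stopifnot(is_pm_params(params))
  on_b <- unique(params$birth[-1]); on_d <- unique(params$death[-1])
  if (length(on_b) != 1L || length(on_d) != 1L)
    stop("resize_params() requires homogeneous 'on'-compartment rates",
         call. = FALSE)
  model_params(n_on, params$mu, params$epsilon,
               birth = c(params$birth[1], rep(on_b, n_on)),
               death = c(params$death[1], rep(on_d, n_on)))
}

#' A compartment state (abundance vector) at one time point
#'
#' @param abundances non-negative numeric vector of length `n_on + 1`,
#'   compartment 0 ('off') first.
#' @param time non-negative time stamp.
#' @return an object of class `pm_state`.
#' @export
compartment_state <- function(abundances, time = 0) {
  if (!is.numeric(abundances) || anyNA(abundances) || any(abundances < 0))
    stop("abundances must be non-negative numbers", call. = FALSE)
  if (length(time) != 1L || !is.finite(time) || time < 0)
    stop("time must be a single non-negative number", call. = FALSE)
  structure(list(time = as.numeric(time), abundances = as.numeric(abundances)),
            class = "pm_state")
}

#' All-mass-'off' initial state
#'
#' The default initial condition throughout: `n_cells` in compartment 0 and
#' empty 'on' chain.
#'
#' @param n_on memory length of the lineage the state is for.
#' @param n_cells number of 'off' cells (default 1000).
#' @param time time stamp.
#' @return a [compartment_state()].
#' @export
all_off_state <- function(n_on, n_cells = 1000, time = 0) {
  compartment_state(c(n_cells, rep(0, n_on)), time = time)
}

as_state <- function(initial, n_on) {
  if (inherits(initial, "pm_state")) {
    st <- initial
  } else if (is.numeric(initial)) {
    st <- compartment_state(initial)
  } else stop("initial state must be a pm_state or numeric vector", call. = FALSE)
  if (length(st$abundances) != n_on + 1L)
    stop("initial state has ", length(st$abundances),
         " compartments; params require ", n_on + 1L, call. = FALSE)
  st
}

#' Write / read model parameters as a flat YAML config
#'
#' Flat keys `n_on`, `mu`, `epsilon`, `birth`, `death`; birth/death may be a
#' scalar (broadcast) or a full list.
#'
#' @param params a [model_params()] object.
#' @param path file path.
#' @return `read_params()` returns a [model_params()] object;
#'   `write_params()` returns `path` invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(is_pm_params(params))
  yaml::write_yaml(list(n_on = params$n_on, mu = params$mu,
                        epsilon = params$epsilon,
                        birth = params$birth, death = params$death), path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("n_on", "mu", "epsilon", "birth", "death")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("config is missing keys: ", paste(miss, collapse = ", "), call. = FALSE)
  model_params(cfg$n_on, cfg$mu, cfg$epsilon,
               birth = unlist(cfg$birth), death = unlist(cfg$death))
}
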
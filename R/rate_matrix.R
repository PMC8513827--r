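#' Build the compartment rate matrix
#'
#' Returns the `(n_on+1) x (n_on+1)` matrix `A` of the linear system
#' `dx/dt = A x` for the compartment abundances `x = (x_0, ..., x_n)`:
#' \deqn{\dot x_0 = (b_0 - d_0) x_0 - \mu x_0 + \epsilon x_1}
#' \deqn{\dot x_i = (b_i - d_i) x_i - \epsilon x_i + \epsilon x_{i+1}, \quad 0 < i < n}
#' \deqn{\dot x_n = (b_n - d_n) x_n - \epsilon x_n + \mu x_0}
#' `A[row, col]` multiplies `x_col` in the equation for `x_row`; rows and
#' columns are named `x0 ... xn`.
#'
#' Column sums equal `b_j - d_j`: switching and leaching move cells between
#' compartments without changing the total, so only birth and death change
#' population size.
#'
#' @param params a [model_params()] object.
#' @return a numeric matrix.
#' @export
build_rate_matrix <- function(params) {
  stopifnot(is_pm_params(params))
  n <- params$n_on; nc <- n + 1L
  g <- params$birth - params$death
  A <- matrix(0, nc, nc, dimnames = list(paste0("x", 0:n), paste0("x", 0:n)))
  A[1, 1] <- g[1] - params$mu
  A[1, 2] <- params$epsilon
  A[nc, nc] <- g[nc] - params$epsilon
  A[nc, 1] <- params$mu
  if (n > 1) {
    for (i in 2:n) {                    # interior 'on' compartments 1..n-1
      A[i, i] <- g[i] - params$epsilon
      A[i, i + 1] <- params$epsilon
    }
  }
  A
}

#' Spectral summary of the compartment model
#'
#' Full eigen-decomposition of [build_rate_matrix()]. The matrix is Metzler
#' (non-negative off-diagonal), so a real dominant eigenvalue with a
#' non-negative eigenvector exists; the dominant eigenvalue is the asymptotic
#' per-capita growth rate and its sum-normalized right eigenvector is the
#' equilibrium compartment distribution. Subdominant eigenvalues (sorted by
#' descending real part) control the transient: complex pairs produce
#' oscillations, and a small spectral gap makes them long-lived.
#'
#' Dominant selection: maximal real part; among eigenvalues tied within
#' `1e-12` the one with an entrywise sign-constant eigenvector is preferred.
#' The eigenvector is flipped so its largest-magnitude entry is positive,
#' entries in `[-1e-12, 0)` are clipped to zero, and it is renormalized to
#' sum 1. A `defective` flag (not an error) marks numerically defective
#' decompositions (ill-conditioned eigenvector matrix).
#'
#' @param params a [model_params()] object.
#' @return an object of class `pm_spectrum` with fields `growth_rate`,
#'   `equilibrium_distribution`, `subdominant_eigenvalues`, `spectral_gap`,
#'   `eigenvalues` (all, dominant first) and `defective`.
#' @export
spectral_summary <- function(params) {
  A <- build_rate_matrix(params)
  e <- eigen(A)
  vals <- e$values
  re <- Re(vals)
  top <- max(re)
  cand <- which(re >= top - 1e-12)
  pick <- cand[1]
  if (length(cand) > 1L) {
    for (k in cand) {
      v <- e$vectors[, k]
      if (max(abs(Im(v))) < 1e-9) {
        rv <- Re(v); rv[abs(rv) < 1e-12] <- 0
        if (all(rv >= 0) || all(rv <= 0)) { pick <- k; break }
      }
    }
  }
  lam <- vals[pick]
  growth_rate <- Re(lam)
  v <- Re(e$vectors[, pick])
  if (v[which.max(abs(v))] < 0) v <- -v
  v[v < 0 & v >= -1e-12] <- 0
  v <- v / sum(v)
  names(v) <- rownames(A)

  sub <- vals[-pick]
  sub <- sub[order(-Re(sub), abs(Im(sub)))]
  gap <- if (length(sub)) growth_rate - max(Re(sub)) else 0
  defective <- tryCatch(kappa(e$vectors, exact = FALSE) > 1e10,
                        error = function(e2) TRUE)
  structure(
    list(growth_rate = growth_rate,
         equilibrium_distribution = v,
         subdominant_eigenvalues = sub,
         spectral_gap = max(gap, 0),
         eigenvalues = c(lam, sub),
         defective = defective),
    class = "pm_spectrum")
}

#' @export
print.pm_spectrum <- function(x, ...) {
  cat("<pm_spectrum> growth_rate =", format(x$growth_rate, digits = 10),
      " spectral_gap =", format(x$spectral_gap, digits = 6),
      if (x$defective) " [defective]" else "", "\n")
  cat("  equilibrium:", paste(signif(x$equilibrium_distribution, 4),
                              collapse = " "), "\n")
  invisible(x)
}

#' Closed-form equilibrium 'on' fraction (symmetric growth)
#'
#' Under fully symmetric growth (`b_i = b`, `d_i = d`) the equilibrium
#' fraction of cells in the 'on' state is `n_on * mu / (epsilon + n_on * mu)`,
#' independent of `b - d`. For asymmetric growth there is no closed form; use
#' `1 - spectral_summary(params)$equilibrium_distribution[1]`.
#'
#' @param params a [model_params()] object with symmetric growth.
#' @return a number in `[0, 1]`.
#' @export
equilibrium_on_fraction <- function(params) {
  stopifnot(is_pm_params(params))
  if (!is_symmetric_growth(params))
    stop("closed form holds only under symmetric growth; ",
         "use spectral_summary()", call. = FALSE)
  n <- params$n_on
  n * params$mu / (params$epsilon + n * params$mu)
}

#' Leaching rate achieving a target equilibrium 'on' fraction
#'
#' Inverts the symmetric-growth equilibrium `q = n mu / (eps + n mu)` for
#' `eps`, giving `eps = n mu (1 - q) / q`. Used to calibrate lineages of
#' different memory length to a common equilibrium composition.
#'
#' @param n_on memory length.
#' @param mu switch rate.
#' @param q target equilibrium 'on' fraction in `(0, 1)`.
#' @return the leaching rate, a positive scalar.
#' @export
epsilon_for_equilibrium <- function(n_on, mu, q) {
  stopifnot(q > 0, q < 1, mu > 0, n_on >= 1)
  n_on * mu * (1 - q) / q
}

#' Write a spectral summary as tab-separated tables
#'
#' Writes one row per eigenvalue (`re`, `im`, `is_dominant`) to `path`, and
#' the equilibrium distribution (`compartment`, `weight`) to
#' `<path>.equilibrium.tsv`.
#'
#' @param spectrum a `pm_spectrum` from [spectral_summary()].
#' @param path output path for the eigenvalue table.
#' @return `path`, invisibly.
#' @export
write_spectral_summary <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "pm_spectrum"))
  ev <- spectrum$eigenvalues
  tab <- data.frame(re = Re(ev), im = Im(ev),
                    is_dominant = seq_along(ev) == 1L)
  write_tsv_table(tab, path)
  eq <- data.frame(compartment = names(spectrum$equilibrium_distribution),
                   weight = as.numeric(spectrum$equilibrium_distribution))
  write_tsv_table(eq, paste0(path, ".equilibrium.tsv"))
  invisible(path)
}

# tab-separated writer used by all tabular outputs: header line, full
# float precision, no quoting
write_tsv_table <- function(df, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  is_num <- vapply(df, is.numeric, logical(1))
  df[is_num] <- lapply(df[is_num], function(x) sprintf("%.17g", x))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df))
    writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con)
  invisible(path)
}
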
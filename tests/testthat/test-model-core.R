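test_that("rate matrix transcribes the linear system exactly", {
  p <- model_params(1, mu = 0.2, epsilon = 0.5,
                    birth = c(1, 1), death = c(0.98, 0.98))
  A <- build_rate_matrix(p)
  expect_equal(unname(A), matrix(c(-0.18, 0.2, 0.5, -0.48), 2, 2),
               tolerance = 1e-15)

  # n_on = 2, mu = 0: no route into the 'on' chain, first column has no
  # sub-diagonal entries; all mass ends 'off'
  p0 <- model_params(2, mu = 0, epsilon = 0.7, birth = 1, death = 1)
  A0 <- build_rate_matrix(p0)
  expect_equal(unname(A0[2:3, 1]), c(0, 0))
  s0 <- spectral_summary(p0)
  expect_equal(unname(s0$equilibrium_distribution), c(1, 0, 0),
               tolerance = 1e-12)
})

test_that("column sums equal net per-compartment growth (cell conservation)", {
  set.seed(101)
  for (k in 1:25) {
    p <- random_params()
    A <- build_rate_matrix(p)
    expect_equal(unname(colSums(A)), p$birth - p$death, tolerance = 1e-12)
  }
})

test_that("dominant eigenvalue equals b - d under full symmetry", {
  set.seed(202)
  for (k in 1:25) {
    n <- sample(1:32, 1)
    b <- runif(1, 0.5, 2); d <- runif(1, 0, 2)
    p <- model_params(n, mu = runif(1, 0, 1), epsilon = runif(1, 0.05, 2),
                      birth = b, death = d)
    s <- spectral_summary(p)
    expect_equal(s$growth_rate, b - d, tolerance = 1e-9)
    expect_gte(s$growth_rate + 1e-12, max(Re(s$subdominant_eigenvalues)))
  }
})

test_that("spectral summary is cross-checked by a generic eigen routine", {
  # independent route: characteristic polynomial roots via polyroot()
  p <- sym_params(4)
  A <- build_rate_matrix(p)
  cp <- pracma::charpoly(A)          # coefficients, highest degree first
  roots <- polyroot(rev(cp))
  s <- spectral_summary(p)
  expect_equal(max(Re(roots)), s$growth_rate, tolerance = 1e-8)
  expect_equal(s$growth_rate, 0.02, tolerance = 1e-9)
})

test_that("equilibrium distribution is a proper stationary composition", {
  s <- spectral_summary(sym_params(5, epsilon = 0.25))
  expect_equal(sum(s$equilibrium_distribution), 1, tolerance = 1e-10)
  expect_true(all(s$equilibrium_distribution >= 0))
  # A v = lambda v for the normalized eigenvector
  A <- build_rate_matrix(sym_params(5, epsilon = 0.25))
  v <- s$equilibrium_distribution
  expect_equal(as.numeric(A %*% v), s$growth_rate * as.numeric(v),
               tolerance = 1e-10)
})

test_that("closed-form equilibrium 'on' fraction matches the spectrum", {
  expect_equal(equilibrium_on_fraction(sym_params(5, epsilon = 0.25)), 0.8)
  expect_equal(equilibrium_on_fraction(model_params(3, 0, 0.4, 1, 1)), 0)
  expect_equal(equilibrium_on_fraction(sym_params(1)), 0.2 / 0.7)
  set.seed(303)
  for (k in 1:10) {
    n <- sample(1:20, 1)
    p <- model_params(n, runif(1, 0.01, 1), runif(1, 0.05, 2),
                      birth = 1, death = 0.98)
    s <- spectral_summary(p)
    expect_equal(equilibrium_on_fraction(p),
                 1 - s$equilibrium_distribution[[1]], tolerance = 1e-8)
  }
  # closed form refuses asymmetric growth
  expect_error(equilibrium_on_fraction(
    model_params(2, 0.2, 0.5, birth = c(1, 0, 0), death = c(0.98, 0, 0))),
    "symmetric")
})

test_that("memoryless calibration preserves the equilibrium and mean residence", {
  p <- sym_params(5, epsilon = 0.25)
  eps1 <- memoryless_equivalent_epsilon(p)
  expect_equal(eps1, 0.05)
  expect_equal(memoryless_equivalent_epsilon(sym_params(1, epsilon = 0.3)), 0.3)
  q_mem <- equilibrium_on_fraction(p)
  q_less <- equilibrium_on_fraction(model_params(1, p$mu, eps1, 1, 1))
  expect_equal(q_mem, q_less, tolerance = 1e-12)
  # mean 'on' residence time n/eps is preserved: gamma(n, eps) vs exp(eps/n)
  p4 <- sym_params(4, epsilon = 0.3)
  expect_equal(4 / 0.3, 1 / memoryless_equivalent_epsilon(p4),
               tolerance = 1e-12)
  expect_equal(4 / 0.3, 13.333, tolerance = 1e-4)
})

test_that("complex subdominant eigenvalues appear only with multiple 'on' compartments", {
  s1 <- spectral_summary(sym_params(1))
  expect_true(all(abs(Im(s1$subdominant_eigenvalues)) < 1e-12))
  s10 <- spectral_summary(sym_params(10))
  expect_true(any(abs(Im(s10$subdominant_eigenvalues)) > 1e-8))
})

test_that("spectral gap is non-increasing in memory length", {
  gaps <- vapply(1:32, function(n)
    spectral_summary(sym_params(n, b = 1, d = 1))$spectral_gap, numeric(1))
  expect_true(all(diff(gaps) <= 1e-12))
})

test_that("parameter validation rejects malformed inputs", {
  expect_error(model_params(0, 0.2, 0.5, 1, 1), "n_on")
  expect_error(model_params(2, -0.1, 0.5, 1, 1), "mu")
  expect_error(model_params(2, 0.2, 0, 1, 1), "epsilon")
  expect_error(model_params(2, 0.2, 0.5, c(1, 1), 1), "length")
  expect_error(model_params(2, 0.2, 0.5, 1, c(-1, 0, 0)), "non-negative")
})

test_that("spectral summary exports as tab-separated tables", {
  path <- tempfile(fileext = ".tsv")
  s <- spectral_summary(sym_params(4))
  write_spectral_summary(s, path)
  ev <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(ev), 5)
  expect_equal(sum(ev$is_dominant), 1)
  expect_equal(ev$re[ev$is_dominant], 0.02, tolerance = 1e-9)
  eq <- read.table(paste0(path, ".equilibrium.tsv"), header = TRUE, sep = "\t")
  expect_equal(sum(eq$weight), 1, tolerance = 1e-10)
})
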
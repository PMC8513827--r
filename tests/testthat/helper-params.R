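# shared builders for the test suite

# fully symmetric lineage (b_i = b, d_i = d for all compartments)
sym_params <- function(n_on, mu = 0.2, epsilon = 0.5, b = 1, d = 0.98) {
  model_params(n_on, mu, epsilon, birth = b, death = d)
}

# random valid parameter draw (used by property-style tests)
random_params <- function(n_max = 12) {
  n <- sample(seq_len(n_max), 1)
  model_params(n,
               mu = runif(1, 0, 1),
               epsilon = runif(1, 0.05, 2),
               birth = runif(n + 1, 0, 2),
               death = runif(n + 1, 0, 2))
}

perm_p <- function(n_on = 1) persistence_params(n_on, "permissive")
treat_p <- function(n_on = 1) persistence_params(n_on, "treatment")
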
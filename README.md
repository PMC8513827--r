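# phenomem

Phenotypic memory in microbial populations, modelled as a linear chain of
'on' compartments attached to a single 'off' state.

## The model

Isogenic cells switch between a normal ('off') phenotype and an alternative
('on') phenotype — persisters, in the antibiotic-tolerance setting. Classic
two-state switching models give exponentially distributed 'on' residence
times: the probability of reverting is constant in time, i.e. the cell has
no memory of how long it has been 'on'. Experiments instead report
gamma-distributed lag times and overshooting frequency transients.

`phenomem` decomposes the 'on' state into *n* sequential compartments.
A cell switching 'on' (rate *μ*) jumps to the freshest compartment *n* and
then leaches down the chain (rate *ε* per step, compartment 1 → 'off'),
while birth and death act per compartment at rates *b_i*, *d_i*:

    dx₀/dt = (b₀ − d₀)x₀ − μx₀ + εx₁
    dxᵢ/dt = (bᵢ − dᵢ)xᵢ − εxᵢ + εxᵢ₊₁     (0 < i < n)
    dxₙ/dt = (bₙ − dₙ)xₙ − εxₙ + μx₀

The chain is a mechanistic memory: the single-cell 'on' residence time is a
sum of *n* exponential(*ε*) waits, i.e. gamma with shape *n* and rate *ε*.
Key population-level consequences, all computable with this package:

* **Asymptotics.** Under symmetric growth (*b_i = b*, *d_i = d*) the
  asymptotic per-capita growth rate is *b − d* for any *n*, and the
  equilibrium 'on' fraction is *nμ/(ε + nμ)*.
* **Transients.** For *n > 1* the rate matrix acquires complex subdominant
  eigenvalues: the 'on' frequency overshoots and oscillates on its way to
  equilibrium, more strongly the longer the memory; the spectral gap
  narrows as *n* grows.
* **Fitness under fluctuating environments.** In an antibiotic-treatment
  protocol ('off' cells grow in permissive seasons and die under treatment;
  'on' cells are dormant and tolerant; switching is stress-triggered),
  memory lineages are compared against a memoryless lineage calibrated to
  the same equilibrium 'on' fraction (*ε′ = ε/n*). Relative fitness
  *r = (g_m − g_mless)/t_max*, with *g = log(N(t_max)/N(0))*, is negative
  for short treatments, peaks at intermediate memory for intermediate
  treatments, and vanishes under lengthy sustained treatment.

The package provides both engines: exact deterministic propagation by matrix
exponentials, and an exact Gillespie (direct-method) stochastic simulator
whose ensemble mean is the deterministic solution.

## Worked example

```r
library(phenomem)

# a lineage with 4 'on' compartments, symmetric growth
p <- model_params(n_on = 4, mu = 0.2, epsilon = 0.5, birth = 1, death = 0.98)
spectral_summary(p)
#> <pm_spectrum> growth_rate = 0.02  spectral_gap = 0.143237
#>   equilibrium: 0.3846 0.1538 0.1538 0.1538 0.1538

equilibrium_on_fraction(model_params(5, 0.2, 0.25, 1, 1))
#> [1] 0.8

# single-cell 'on' residence times: gamma(shape = n_on, rate = epsilon)
rs <- sample_residence_times(4, 0.3, 10000, ssa_config(seed = 1))
fit_gamma(rs)
#> <pm_gammafit> shape = 4.0988728  rate = 0.30730672  loglik = -32177.915  n = 10000

# transient overshoot grows with memory at a fixed equilibrium of 0.8
ns <- c(5, 15, 25, 35)
amplitude_sweep(0.2, ns, epsilon_for_equilibrium(ns, 0.2, 0.8))
#>   n_on epsilon equilibrium_fraction peak_to_peak degenerate_flag
#> 1    5    0.25                  0.8   0.07431407           FALSE
#> 2   15    0.75                  0.8   0.17291952           FALSE
#> 3   25    1.25                  0.8   0.21819790           FALSE
#> 4   35    1.75                  0.8   0.24465556           FALSE

# antibiotic-treatment fitness landscape: 31 memory sizes x 84 schedules
land <- fitness_landscape()
nrow(land)
#> [1] 2604
```

The growth rate 0.02 equals *b − d* independently of memory length; the
fitted shape ≈ 4.1 recovers the number of compartments from simulated
residence times; and the amplitude column shows the transient oscillations
strengthening with memory at a fixed equilibrium composition.

A command-line interface over the same functions is installed under
`inst/cli/phenomem.R`:

```sh
Rscript inst/cli/phenomem.R spectrum --n-on 4 --mu 0.2 --epsilon 0.5 --b 1.0 --d 0.98 --out spectrum.tsv
Rscript inst/cli/phenomem.R residence --n-on 4 --epsilon 0.3 --samples 10000 --seed 1 --out res.txt
Rscript inst/cli/phenomem.R fit --in res.txt --out fit.tsv
Rscript inst/cli/phenomem.R landscape --out landscape.tsv
```

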
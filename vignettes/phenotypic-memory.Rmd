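---
title: "Phenotypic memory as a compartment chain: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotypic memory as a compartment chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomem)
```

## The model and its assumptions

A cell is either 'off' (compartment 0) or 'on', and the 'on' state is
subdivided into $n$ sequential compartments indexed $1..n$. Switching 'on'
(rate $\mu$) sends the cell to the freshest compartment $n$; it then leaches
down the chain at rate $\epsilon$ per step, re-entering 'off' from
compartment 1. Births ($b_i$) and deaths ($d_i$) act per compartment and are
the only reactions that change total population size — switching and
leaching merely move cells, which is why every column of the rate matrix
sums to $b_j - d_j$ (a conservation identity the test suite asserts on
random parameter draws).

The model is linear and Markovian. That is a deliberate modelling stance:
memory is generated *mechanistically*, by the chain length, rather than by
writing a non-exponential waiting time into a two-compartment model, which
would require nonlinear or non-Markovian terms. The cost is the assumption
that the leaching rate is the same across compartments and that switching
always targets compartment $n$; compartment-dependent leaching and
partial-potential switching are out of scope.

Three consequences organize the package:

1. **Single-cell level.** With negligible growth, the 'on' residence time is
   a sum of $n$ independent exponential($\epsilon$) waits — gamma with shape
   $n$ and rate $\epsilon$. Shape $> 1$ (rejected exponentiality) is the
   operational definition of memory.
2. **Asymptotics.** Under fully symmetric growth ($b_i = b$, $d_i = d$) the
   dominant eigenvalue is exactly $b - d$ for every $(n, \mu, \epsilon)$ and
   the equilibrium 'on' fraction has the closed form
   $n\mu/(\epsilon + n\mu)$. Both are exposed only for the symmetric case;
   asymmetric parameterizations must use `spectral_summary()`, because the
   closed forms genuinely fail there (see the calibration caveat below).
3. **Transients.** For $n > 1$ the spectrum acquires complex subdominant
   eigenvalues, and their real parts approach the dominant one as $n$ grows
   (narrowing spectral gap), so the 'on' frequency overshoots and
   oscillates, more persistently the longer the memory.

## Parameters that matter

| Parameter | Meaning | Unit | Typical value here |
|---|---|---|---|
| `n_on` | memory length ('on' compartments) | — | 1–35 |
| `mu` | 'off'→'on' switch rate | 1/time | 0.2 |
| `epsilon` | leaching rate per chain step | 1/time | 0.25–0.5 |
| `birth`, `death` | per-compartment growth | 1/time | 1.0 / 0.98 |

Time is dimensionless throughout; no unit conversion happens anywhere. The
mean 'on' residence time is $n/\epsilon$, so $\epsilon$ and $n$ trade off
against each other asymptotically — `epsilon_for_equilibrium(n, mu, q)`
inverts the equilibrium formula to hold the composition fixed while varying
memory, which is how the amplitude analyses keep a fair comparison.

## Numerical choices

**Deterministic engine.** `integrate_ode()` propagates the exact solution
$x(t + \Delta t) = e^{A \Delta t} x(t)$ per output step using
`Matrix::expm()` (Ward's Padé with balancing). There is no truncation
error and nothing to tune; the test suite cross-checks against
`deSolve::lsoda` at tolerance 1e-6. We chose `Matrix::expm` after observing
that a Padé implementation without balancing can fail catastrophically on
these matrices at long horizons (the treatment-season matrix integrated
over hundreds of time units is the stress case).

**Extremum detection.** Transient metrics are read off the output grid
(default `dt_out = 0.01`): a grid point is a local extremum if it differs
from both neighbours in the right direction by at least 1e-9, which
suppresses floating-point ripple on flat stretches. When a trajectory
overshoots but decays monotonically afterwards (no undershoot — common at
small $n$), the peak-to-peak amplitude is defined as overshoot minus
equilibrium and flagged `degenerate`; a fully monotone approach gives 0.
`amplitude_sweep()` chooses its horizon per configuration as
$12/\mathrm{gap}$ (capped at 20000 time units) so every trajectory reaches
equilibrium within the 1e-3 convergence check.

**Stochastic engine.** `gillespie()` is the direct method with exhaustive
propensity recomputation — populations at desk scale are small, and
auditability beats the next-reaction method's bookkeeping. Reactions are
enumerated in a fixed compartment-then-type order and selected by a single
uniform draw against the cumulative propensity vector; waiting times are
inverse-CDF exponentials. Everything runs on R's RNG stream, so a seed in
`ssa_config()` makes event sequences bit-reproducible. Extinction ends a
run with a flag, never an error; an event cap (default 1e7) guards runaway
growth and flags truncation.

**Residence-time sampler.** `sample_residence_times()` places one cell in
compartment $n$ with $b = d = 0$ and simulates the explicit leaching event
loop until the cell reaches 'off'. Zero growth rates give the identical
first-passage law as tiny-but-positive rates while removing demographic
noise from the experiment; the tiny-rate variant remains available through
`gillespie()` and is checked against the same gamma law in the test suite.

**Gamma MLE.** `fit_gamma()` solves the profile equation
$\log k - \psi(k) = \log \bar x - \overline{\log x}$ by Newton iteration
from Minka's closed-form initializer, converged to 1e-10, with the rate
$k/\bar x$. This is dependency-light and reproducible; a unit test confirms
agreement with `MASS::fitdistr` to 1e-4. The exponentiality check is a
likelihood-ratio test of shape $\equiv 1$ against free shape on
$\chi^2_1$, default $\alpha = 0.01$ (the choice of $\alpha$ is a
convention, configurable).

## The treatment protocol and the synthetic conditions

The fitness experiment emulates transient antibiotic exposure: sequences of
total length 165 starting from 1000 'off' cells, with a single contiguous
treatment block of length 1..84 beginning at onset 40. Permissive seasons:
'off' cells grow at $b - d = 1 - 0.98 = 0.02$ and the switch is inactive
($\mu = 0$, stress-triggered switching only). Treatment seasons: 'off'
cells die at net $-0.02$ ($d = 1.02$), the switch activates ($\mu = 0.2$),
and 'on' cells are dormant persisters ($b = d = 0$ — implemented as no
birth/death events at all, which is indistinguishable from equal nonzero
rates in the deterministic engine and matches "tolerant, non-growing"
at the single-cell level). Leaching stays $\epsilon = 0.25$ in both
seasons. The onset value 40 is a design choice — the qualitative
properties (memoryless neutrality, monotone survival, interior optima) are
onset-invariant, and pixel-level reproduction of any particular grid figure
is a non-goal.

The comparator is a memoryless lineage ($n = 1$) with
$\epsilon' = \epsilon/n$, which matches the memory lineage's equilibrium
'on' fraction and mean residence time under symmetric growth. A caveat the
package is honest about: under the *asymmetric* treatment parameterization
the two lineages' dominant eigenvalues differ by up to $\sim 10^{-4}$, so
relative fitness under sustained treatment converges to that small residual
rather than to exactly zero. The neutrality test therefore asserts
$|r| < 10^{-4}$ at a 2000-unit sustained horizon, which the calibration
meets for all $n \le 31$.

These synthetic conditions capture stress-triggered persistence with a
clean seasonal structure. They do not emulate nutrient depletion,
density-dependent switching, drug pharmacokinetics, or growth-phase
structure of real treatment experiments — so passing tests demonstrate the
internal consistency of the model and implementation, not quantitative
agreement with any particular laboratory system.

## Problem sizes

The default analyses are desk-scale and chosen to be comfortably
reproducible: 10,000 residence-time samples for gamma recovery, 2000
stochastic replicates (1000 cells, 20 checkpoints) for the mean-field
comparison, and the full $31 \times 84$ deterministic landscape (which runs
in seconds thanks to memoised season propagators).

## Known limitations

* The closed-form equilibrium and the $\epsilon/n$ calibration are exact
  only under symmetric growth; asymmetric settings must go through the
  spectrum, and the calibration carries the $O(10^{-4})$ residual noted
  above.
* No tau-leaping or hybrid acceleration: very large populations are the
  deterministic engine's job.
* Residence times are gamma only when sampling starts from a single
  compartment; mixtures arising from distributed starting compartments are
  out of scope.
* No evolutionary dynamics on $n$ or $\epsilon$: the landscape evaluates
  fixed lineages, it does not evolve them.
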
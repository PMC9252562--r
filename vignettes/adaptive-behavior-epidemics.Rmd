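---
title: "Coupling SEIAR dynamics with forward-looking contact decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupling SEIAR dynamics with forward-looking contact decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptepi)
```

## The model

`adaptepi` simulates an epidemic in a closed population whose members
adjust their daily social activity in response to the infection risk they
perceive. Two behavioral groups — risk-takers (a fraction `p`) and
risk-evaders — differ in two ways: risk-evaders face a per-contact
infection likelihood scaled by `epsilon < 1` (precautionary behaviors),
and they are more willing to give up contacts (a flatter utility, smaller
`nu`).

### Disease progression

Each group follows SEIAR progression: susceptible, exposed (already
shedding at relative infectiousness `rho`), then either asymptomatic
(relative infectiousness `alpha`, probability `sigma`) or symptomatic, and
finally recovered. Symptomatic individuals form a single shared
compartment because behavior in that class is homogeneous; recovered
individuals are likewise pooled. Transmission is frequency-dependent with
explicit contact rates: the probability that one of a susceptible's
contacts is infectious equals the infectious share of the total population
activity `Theta = sum_h C^h h`, weighted by relative infectiousness
(`mixing_fraction()`). The simulation advances in daily steps, converting
rates to daily probabilities `1 - exp(-rate)` (`step_epidemic()`).

We deliberately use the same daily discrete-time transition law for the
epidemic kernel and for the decision model (which is posed in daily
transition probabilities), rather than integrating differential equations
between decision epochs: the agent's model of the world and the world
itself then agree exactly, and exact structural identities — zero
reporting reproducing the constant-contacts model to machine precision,
exchangeable groups collapsing onto one trajectory — hold by construction.
The continuous-time reproduction number formula is retained because the
calibration target (R0 = 2.4) is conventionally stated in continuous time.

### The reproduction number

`r0()` implements the next-generation value for the homogeneous model at
the disease-free optimal contact rate `C* = b/2`. At the disease-free
equilibrium everyone makes `C*` contacts, so the mixing fraction reduces
to `rho E + alpha A + I` and each infectious person-day at relative
infectiousness `w` produces `beta C* w` new infections. Accumulating
expected residence times along the two progression paths:

R0 = beta C\* (rho / kappa + sigma alpha / gamma + (1 - sigma) / gamma).

With the baseline values (beta = 0.01324, b = 48, rho = 0.25, alpha = 0.4,
sigma = 0.5, kappa = 1/5, gamma = 1/9) this gives

```{r}
r0(disease_params(), b = 48, kernel = "continuous")
```

The daily kernel's expected residence times are geometric,
`1/(1 - exp(-kappa))` and `1/(1 - exp(-gamma))`, slightly longer than the
exponential `1/kappa`, `1/gamma`; the kernel-consistent value is

```{r}
r0(disease_params(), b = 48, kernel = "discrete")
```

Final-size checks against the implicit equation `z = 1 - exp(-R0 z)` must
use the discrete value — the simulated homogeneous epidemic matches its
root to well under one percent. Which convention stands behind any externally reported
trajectory is generally unknowable; both are exposed.

### Contact decisions

Susceptibles of group `i` choose the contact rate maximizing

u(C) + delta [(1 - P(C)) V(S) + P(C) V(E)]

by backward induction over a planning horizon `tau_i` (`tau = 14` days by
default), with `u(C) = (bC - C^2)^nu` and perceived infection probability
`P(C) = 1 - exp(-beta_i C phi Phi/Theta)`. Key modeling commitments, all
configurable where reasonable alternatives exist:

* **Frozen environment (constant-prevalence projection).** The decision
  uses today's compartment distribution and yesterday's realized contact
  profile, held fixed over the whole horizon. The decision variable `C`
  scales the individual's own exposure only — an atomistic decision-maker
  does not perceive their choice as moving the population activity
  `Theta`.
* **One-step decoupling.** Both groups optimize simultaneously against
  the same frozen profile (the latest observation), not sequentially and
  not to a within-day fixed point.
* **Misperceived health states.** Exposed and asymptomatic individuals
  have no symptoms, consider themselves susceptible, and adopt their
  group's susceptible contact rate; their true continuation values (used
  inside the susceptible's Bellman equation) nevertheless account for
  progression and the utility lost while symptomatic.
* **Symptomatic utility.** The default (`symptomatic_utility = "zero"`)
  gives symptomatic individuals no utility while infectious — this is the
  economic cost that makes infection worth avoiding. The alternative
  `"full"` credits them `u(C*)` like recovered individuals; under it the
  continuation penalty of infection nearly vanishes and the behavioral
  response collapses to nothing, which is why `"zero"` is the default.
* **Terminal value.** `V(.) = 0` beyond the horizon. Any state-independent
  terminal constant leaves every argmax unchanged, so zero is canonical;
  the constant is exposed as `terminal_value` for sensitivity runs.
* **Search domain `(0, b/2]`.** Rates above `b/2` reduce utility and raise
  risk simultaneously, so they are dominated. The optimizer evaluates a
  256-point grid to bracket the maximum and refines the realized (step-0)
  choice to an absolute tolerance of 1e-6 contacts; exact ties are broken
  toward the disease-free optimum. The solution is routinely verified in
  the test suite against a 2000-point dense-grid backward induction.
* **Reporting `phi`** scales only the perceived infectious activity `Phi`
  (others' total activity is observable; their infection status is not),
  and never the true transmission process.
* **Discounting.** `delta = 0.99986` per day, the conventional 5% annual
  rate: `annual_to_daily_discount(0.05)^365 = 0.95`.

The daily loop (`simulate_adaptive()`) is: solve both groups' problems
against the frozen environment; apply each group's optimum to its S, E
and A classes (I and R stay at `C*`); advance the epidemic one day with
true transmission (`epsilon` yes, `phi` no); repeat until total infectious
prevalence falls below `stop_tol` (1e-7) or `t_max` (1000 days).

## Parameters

| Parameter | Meaning | Default |
|---|---|---|
| `beta` | per-contact transmission likelihood | 0.01324 |
| `kappa` | incubation rate (1/day) | 1/5 |
| `gamma` | recovery rate (1/day) | 1/9 |
| `rho`, `alpha` | exposed / asymptomatic relative infectiousness | 0.25, 0.4 |
| `sigma` | asymptomatic fraction | 0.5 |
| `epsilon` | risk-evader per-contact risk scalar | 0.7 |
| `b` | maximum contacts/day (`C* = b/2`) | 48 |
| `nu1`, `nu2` | utility shapes RT / RE | 0.1, 0.05 |
| `tau1`, `tau2` | planning horizons (days) | 14, 14 |
| `delta` | daily discount factor | 0.99986 |
| `phi` | reporting level | 1 |
| `i0` | initial exposed seed | 1e-4 |

`b = 48` with `beta = 0.01324` is the pair that reproduces R0 = 2.4
exactly (0.01324 × 24 × 7.55 = 2.399); nearby roundings in common use
(b = 50, beta = 0.01325) are accepted through the configuration. The seed
`i0 = 1e-4` is placed in the exposed compartments proportionally to group
sizes, making the per-capita seed identical across groups (the final size
is insensitive to the seed magnitude; the trajectory merely shifts in
time). Scenarios are flat YAML mappings (`read_scenario()` /
`write_scenario()`); packaged examples live in `inst/extdata/`.

## What the simulations emulate — and what they do not

The generated scenarios emulate an influenza/COVID-like respiratory
epidemic in a well-mixed population with a large non-symptomatic
infectious fraction and economically motivated, privately optimal
behavior. They do not emulate: contact-network structure, demography or
reinfection, symptom-biased testing (reporting scales all infectious
classes proportionally), within-group preference heterogeneity, altruism
or externalities, or behavioral rules beyond expected-utility
maximization. Passing tests therefore certify the internal mechanics of
this stylized world, not fidelity to any real surveillance data.

## Numerical choices

Population mass is conserved to machine precision per daily step (drift
below 1e-9 over 1000 steps is enforced in the tests). A degenerate
environment with zero total activity raises an error rather than
returning zero, to surface configuration mistakes. Simulations stop at
total infectious prevalence `stop_tol = 1e-7` or `t_max = 1000` days,
whichever comes first, and flag non-convergence instead of failing.
Bisection in `iso_attack_curve()` matches the reference attack rate to
1e-3 absolute and flags unreachable points as boundary markers.
Planning-horizon searches break ties toward smaller `tau1 + tau2`, then
smaller `tau1`.

The test suite and examples keep experiment grids coarse — 0.25 steps on
`(p, epsilon)` surfaces, planning-horizon grids of about six values per
axis, three-to-four-point grids for the iso-attack trace — which is
sufficient for the qualitative properties they check (monotonicity,
baseline crossings, axis sensitivity). The exported sweep machinery runs
the full 0.05-step and 1..30 grids that the benchmark surfaces use; a
full `(p, epsilon)` surface at 0.05 steps is a few hundred adaptive
simulations at roughly a second each.

## Known limitations

* The two benchmark scenarios (`preset_fig("3A")`, `preset_fig("3B")`)
  reproduce the expected qualitative pattern — risk-evaders respond more
  strongly than risk-takers when risk-takers dominate, and the two
  responses are more similar when risk-evaders dominate — but the
  risk-taker contact reductions run several percentage points deeper
  than the roughly-20% level those scenarios are nominally associated
  with. The first-order condition of the choice problem ties the two
  groups' reduction depths together through `nu1/nu2` and `epsilon`, so
  a composition-invariant risk-taker response combined with a doubling
  risk-evader response is difficult to attain under any variant we
  examined (continuous versus daily kernel, symmetric versus atomistic
  perception of own-group activity, either symptomatic-utility
  convention). The acceptance suite states the nominal bands and reports
  honestly against them.
* Utility-maximizing behavior responds to prevalence levels, so behavior
  lags incidence; models with anticipatory agents (responding to growth
  rates) would bottom out earlier.
* The decision problem is solved per representative agent per group per
  day; heterogeneity within a group would require a distribution over
  `nu` and `tau` and is out of scope.
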
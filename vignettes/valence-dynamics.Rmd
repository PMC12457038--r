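---
title: "Modelling valence dynamics under egosyntonicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling valence dynamics under egosyntonicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egovalence)
```

## The model

`egovalence` implements a discrete-time Markov model of the valence of
the dominant emotion. Three binary variables evolve jointly: the valence
`V` (0 negative, 1 positive), the internal mood `M`, and the external
situation `E`. Mood and events are *autonomous*: each follows its own
symmetric two-state chain, mood persisting with probability `r` (inertia)
and events with probability `s`. The valence is the dependent variable:
its probability of being retained at the next step mixes an external term
and an internal term through the attention weight `ω`,

* stay negative: `p00 = ω(1 − E) + (1 − ω) η0`, with `η0 = 1 − α` when
  the previous step was egosyntonic (`V = M`) and `η0 = 1` otherwise;
* stay positive: `p11 = ω E + (1 − ω) η1`, with `η1 = 1` when egosyntonic
  and `η1 = 1 − β` otherwise.

Egosyntonicity — agreement between what is felt and the background
mood — thus always pushes toward the positive side: it erodes a negative
valence (at rate `α`) and locks in a positive one, while egodystonicity
does the opposite (at rate `β`). Both the egosyntonicity flag and the
event term are evaluated on the *previous* step's `(V, M, E)`. This
timing convention is what makes the joint process a time-homogeneous
Markov chain on the eight states `(V, M, E)`; conditioning on
current-step agreement would not define a transition kernel on this
state space.

### Assumptions

* Mood and events do not react to the valence or to each other — a
  deliberate tractability assumption. Consequently their dynamics can be
  marginalized out exactly, and their stationary marginals are both
  (0.5, 0.5) regardless of `r` and `s` (symmetric chains).
* All five parameters lie *strictly* inside (0, 1). On the open cube the
  joint chain is irreducible and aperiodic, so the stationary
  distribution exists, is unique, and equals the vector of long-run time
  fractions. Boundary values are rejected by `validate_params()` rather
  than special-cased: at 0 or 1 the uniqueness argument collapses, and a
  silently multi-stationary chain is worse than an error.

## Parameters

| parameter | meaning | default grid | role |
|---|---|---|---|
| `r` | mood inertia (per-step persistence probability) | 0.01–0.99 | inertia |
| `s` | external-situation persistence | fixed 0.1 | contingency |
| `α` | egosyntonicity sensitivity: erosion of negative valence when `V = M` | 0.01–0.99 | regulation |
| `β` | egodystonicity sensitivity: erosion of positive valence when `V ≠ M` | 0.01–0.99 | regulation |
| `ω` | attention to external events (weight of the external term) | 0.01–0.99 | contingency |

All are unitless per-step probabilities.

## Two constructions of the transition matrix

`transition_matrix()` offers two permanently public constructions:
`"composed"` multiplies the three conditional laws
`PV(V'|V,M,E) · PM(M'|M) · PE(E'|E)`, while `"printed"` writes each of
the 64 entries as an explicit monomial in the parameters and their
complements. The tabulated form has an error-inviting layout — on rows
whose previous event is positive the `s`/`1−s` columns swap, and the
rows from states 3 and 8 (where retention is certain) contain zero
half-rows — so the composition route is kept as a structural oracle:
the two are compared entrywise at `1e-12` inside `summary()` and across
large random parameter samples in the test suite. Any future edit to
one construction is caught by the other.

```{r}
m <- valence_model(r = 0.7, s = 0.1, alpha = 0.3, beta = 0.2, omega = 0.4)
max(abs(transition_matrix(m, "composed") - transition_matrix(m, "printed")))
```

## Steady state

The stationary distribution is obtained by a direct linear solve of the
transposed balance equations with the normalization row substituted —
deterministic, iteration-free, and exact to machine precision for an
8-state chain. Power iteration (`propagate()` from the uniform vector)
is retained in the tests as an independent oracle, not as the solver.

The stationary probability of positive valence `pi_v1` has an exact
closed form in `α, β, ω, r` (`pi_v1_closed_form()`), implemented in its
tabulated grouped form — including the `/4` and `5r/2 − 7/4` groupings —
rather than re-derived or simplified, so the code certifies the printed
expression verbatim; the reduced form at `r = 0.5` or `α = β`
(`pi_v1_simplified()`) and the numerical stationary mass serve as the
cross-checks. `s` does not appear in the closed form: the long-run
valence depends on the attention paid to events, not on how fast events
churn. The test suite verifies this `s`-independence numerically.

`δego`, the difference between long-run fractions of time spent
egosyntonic and egodystonic, is defined empirically as a time average;
the package also evaluates it analytically as
`2(π̄₁ + π̄₂ + π̄₇ + π̄₈) − 1`, which ergodicity justifies (time
fractions equal stationary masses). This analytic form is an extension
of the time-average definition, and the two are confirmed to agree
within Monte Carlo error in the tests.

### Structural facts the tests pin down

* `α = β` forces `pi_v1 = 0.5` exactly, by all three routes.
* `pi_v1 > 0.5` iff `α > β`, on every cell of the default grid, and
  `pi_v1` is nondecreasing in `α` at fixed `(β, r, ω)`.
* Exchanging `α` and `β` maps `(pi_v1, δego)` to `(1 − pi_v1, −δego)` —
  a point reflection of the phase diagram through `(0.5, 0)`, exchanging
  the BH and CT phenotypes and the SD and TH phenotypes. Note the sign
  of `δego` flips: the naive state-flip `(V,M,E) → (1−V,1−M,1−E)` is
  *not* a symmetry of the chain, because the retention structure is
  itself asymmetric (syntonicity erodes only negative valence, fully
  locks positive valence). The reflection was verified numerically to
  `1e-10` over random draws and confirmed by independent simulations.
* The `r = 0.5` plane is exactly degenerate for `δego`: an iid mood coin
  makes the next mood independent of everything, so the chain spends
  exactly half its time egosyntonic and `δego = 0`.

## Simulation

`simulate()` draws seeded trajectories by inverse-CDF sampling from
successive rows of the *composed* joint matrix, using one generator for
the whole run: a single `(params, seed, nsim, init)` tuple reproduces a
trajectory exactly, and the simulated law agrees with the analytic chain
by construction. A factorized sampler (independent draws for `V`, `M`
and `E`) exists only as a test oracle for distributional equality, never
as the implementation.

Choices where the protocol was open:

* **Initial state** — `"uniform"` by default (least informative,
  reproducible); `"stationary"` and `"fixed:<k>"` are available. At the
  default 500,000 steps the initial-state bias is far below the Monte
  Carlo noise floor.
* **Burn-in** — none by default (`discard = 0` in
  `delta_ego_empirical()`), matching the plain ergodic-average protocol;
  a discard argument is exposed for sensitivity checks.
* The RNG state of the calling session is saved and restored around a
  seeded call, following `stats::simulate()` conventions.

## The phenotype sweep

`phenotype_grid()` defaults to eleven values
{0.01, 0.1, …, 0.9, 0.99} for each of `α, β, r, ω` — the nine interior
decimal steps bracketed by two near-boundary extremes — with `s` fixed
at 0.1 (events churn fast; the steady-state valence ignores `s`
anyway), giving 11⁴ = 14,641 combinations. `run_sweep()` evaluates every
cell; `slice_mismatch()` restricts to the complementary pairs
`α + β = 1`, whose mismatch `α − β` spans −0.98 to 0.98 on the default
grid, crossed with the `r` grid at one attention level — the axes of the
phase diagrams.

Classification (`classify_phenotype()`) reads the signs of
`pi_v1 − 0.5` and `δego`: BH (+,+), SD (−,+), CT (−,−), TH (+,−).
Values within a tolerance band of a boundary are labelled `"boundary"`
instead of being assigned: the `α = β` plane and the `r = 0.5` plane are
*exact* ties, and a phenotype should never be fabricated by rounding
noise. The band defaults to `1e-9` for analytic values and `0.02` for
500,000-step empirical `δego` estimates (about five times the binomial
standard error, allowing for autocorrelation). Classification defaults
to the analytic `δego` — deterministic and seed-free — while
`mode = "simulated"` mirrors the one-seeded-run-per-cell Monte Carlo
protocol and records per-cell seeds.

```{r, eval = FALSE}
sw <- run_sweep(phenotype_grid())   # 14,641 records, ~20 s
table(sw$class)
sl <- slice_mismatch(omega = 0.5)
plot_sweep_map(sl, "pi_v1")
plot_sweep_map(sl, "delta_ego")
```

The heat maps use a diverging coral–white–blue palette centred at the
neutral value (0.5 for `pi_v1`, 0 for `δego`) with symmetric limits, so
colour encodes the side of neutrality — the semantics the phase diagrams
rely on; exact hues are configurable cosmetics.

## Numerical choices

* Row-stochasticity and construction agreement: absolute tolerance
  `1e-12`; cross-method agreement (closed form vs stationary solve):
  `1e-10`. Double precision on 8-state problems leaves orders of
  magnitude of headroom under both.
* The stationary solver verifies its residual `max|π̄P − π̄|` against
  `1e-12` and errors on failure rather than returning a bad vector;
  `summary()` additionally errors if the closed form and the solve
  disagree, treating disagreement as an internal transcription bug.
* The closed-form denominator is checked against `1e-14` defensively; it
  cannot vanish on the open cube.
* Grid values are rounded to 10 decimals on construction so sweep keys
  are exact decimals, keeping joins and golden files stable.
* Cumulative rows of the sampling CDF are clamped to end at exactly 1.

## What the tests do and do not show

The test suite validates the implementation against its own analytic
structure: exact degeneracies, dual-construction agreement, closed-form
versus numerical steady states, ergodic consistency of the sampler
(500,000-step runs match analytic `δego` within 0.01 and per-state
frequencies within 0.005 across random parameter draws), and the
emergence and geometry of the four phenotype classes. The generator
emulates the model's own study conditions — it is a generative model,
not a data-fitting exercise. Nothing here tests against empirical
emotion data: binary states, autonomous mood/event dynamics and
time-constant parameters are modelling idealizations, and passing tests
says the mathematics is implemented faithfully, not that real affect
dynamics behave this way.

## Known limitations

* Binary `V`, `M`, `E` only; no multi-level states.
* No feedback from valence to mood or events, no mood–event coupling,
  no parameter adaptation or learning — all deliberate non-goals.
* `δego` magnitudes from single runs carry Monte Carlo noise of order
  `1/√n`; the class guard band handles this for labelling, but
  near-boundary cells legitimately report `"boundary"`.
* No symbolic algebra: the closed form is certified numerically, not
  re-derived.
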
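---
title: "Methods: the public-goods game with exclusion behind qsgame"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the public-goods game with exclusion behind qsgame}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsgame)
```

## The model

Quorum-sensing bacteria such as *Pseudomonas aeruginosa* secrete costly
extracellular enzymes that digest proteins into a shared amino-acid pool —
a textbook public good. `qsgame` models this as an N-player public-goods
game in a large well-mixed population with three heritable strategies:

* **Cooperator (C)** — quorum-sensing active: contributes cost $c$ to the
  pool and pays a punishment cost $\delta$ per round to police cheats
  (e.g. via a toxin that the producer is immune to).
* **Defector (D)** — a signal-blind mutant: contributes nothing, and is
  the target of punishment.
* **Conditional defector (CD)** — a phenotypically silent wild-type cell:
  pays a perception cost $\Delta$ to monitor conditions, and in each round
  a fraction $q$ of CDs behave as cooperators while the rest cheat. CDs
  are never punished — policing targets the genetically signal-blind.

Groups of $N$ players form at random. Contributions are summed, multiplied
by the enhancement factor $r$, and split equally among the members of the
sharing pool. Each cooperator independently excludes each defector from
the pool with probability $p$, so a defector facing $E$ potential
excluders survives with probability $(1-p)^E$. With $N_C$ cooperating
co-players, $N_{CD}$ cheating conditional defectors, and $N_W$ surviving
defectors in the pool, the realized payoffs are

$$\pi_C = \frac{rc\,(N_C+1)}{N_C+N_{CD}+N_W+1} - c - \delta, \qquad
  \pi_D = (1-p)^{N_C}\frac{rc\,N_C}{N_C+N_{CD}+N_W+1},$$

$$\pi_{CD} = (1-q)\frac{rc\,N_C}{N_C+N_{CD}+N_W+1}
  + q\left[\frac{rc\,(N_C+1)}{N_C+N_{CD}+N_W+1} - c - \delta\right]
  - \Delta.$$

The exclusion exponent depends on who is looking: a focal cooperator adds
itself to the $N_C$ excluders ($E = N_C+1$), a focal defector does not
($E = N_C$), and a focal conditional defector adds itself only in its
cooperating fraction, giving the real-valued $E = (1-q)N_C + q(N_C+1)$.
Two modelling conventions worth making explicit: $\delta$ is paid once per
round by each cooperator, regardless of how many defectors it actually
excludes — this is what the payoff expression above says, and we implement
it literally; and conditional defectors are never subject to exclusion, so
$\pi_{CD}$ has no survival factor of its own.

At a population state $(x, y, z)$ (frequencies of C, D, CD on the
2-simplex), `expected_payoffs()` evaluates the exact finite sums: a
multinomial draw of the $N-1$ co-players with category probabilities
$(x+qz,\; y,\; (1-q)z)$ — the transformed CD fraction counts as
cooperators — nested over a binomial draw of the surviving defectors. At
the default $N = 5$ that is 15 co-player compositions times at most 5
survivor counts, enumerated exactly; the multinomial/binomial weights sum
to one by construction. `monte_carlo_payoffs()` is an independent
stochastic oracle for the same quantity, used throughout the test suite:
it samples groups, applies Bernoulli exclusion, and averages realized
payoffs, with agreement required within four standard errors at $10^5$
samples.

Two useful closed-form limits anchor the implementation: with
$p=\delta=\Delta=0$ and $q=0$ the payoff gap collapses to
$P_C - P_D = c(r-N)/N$ at every state (the classic cost of cooperation in
an unpunished public-goods game, $-0.12$ at the defaults), and with
$p=1,\,q=0$ deterministic policing forces $P_D = 0$ everywhere.

## Replicator dynamics

Strategy frequencies evolve by the standard replicator equations
$\dot{x} = x(P_C - \bar P)$, $\dot{y} = y(P_D - \bar P)$,
$\dot{z} = z(P_{CD} - \bar P)$ with
$\bar P = xP_C + yP_D + zP_{CD}$; the two-strategy restriction reduces to
the gradient of selection $\dot{x} = x(1-x)(P_C - P_D)$.
`integrate_replicator()` solves the system with an adaptive explicit
Runge-Kutta pair (Dormand-Prince 4(5) from **deSolve**), relative
tolerance $10^{-8}$ and absolute tolerance $10^{-10}$ — the vector field
is a smooth low-degree polynomial in the frequencies, so a cheap explicit
method is appropriate. Boundary faces are invariant analytically (a
frequency of exactly zero has zero derivative), and the integrator
preserves this exactly in floating point because the derivative is a
product with the frequency itself. After integration, components in
$(-10^{-9}, 0)$ — pure roundoff — are clipped to zero and the state
renormalized; anything worse raises an error carrying the offending state.
The clip window matches the $10^{-9}$ simplex tolerance used everywhere
else in the package (a tighter window of $10^{-12}$ would reject states
whose error is still well inside the declared simplex tolerance).

The default horizon `t_end = 2000` with 2001 output points is long enough
to separate the long-run outcomes at the default parameters: fixation
endpoints reach their vertex to well under $10^{-6}$, and the oscillatory
regime completes roughly 30 cycles. `detect_oscillation()` discards the
first 20% of samples as transient, finds strict three-point local maxima
of $x(t)$ (a flat tie yields no peak, so nothing is counted twice), and
declares oscillation at $\ge 3$ peaks with a peak-to-trough amplitude
above $10^{-3}$; the coexistence flag additionally requires every
frequency to stay inside $(10^{-6}, 1-10^{-6})$ over the whole trajectory.

## Fixed points and regimes

`find_equilibria_two_strategy()` brackets sign changes of the payoff gap
$g(x) = P_C - P_D$ on a uniform grid (default resolution 1000) and
polishes each bracket until $|g| < 10^{-12}$. Stability follows the sign
pattern: $x=0$ is stable iff $g(0)<0$, $x=1$ iff $g(1)>0$, an interior
root iff $g$ crosses from positive to negative.

`find_equilibria_three_strategy()` reports vertices, edge-interior points
(the same 1-D machinery on each pairwise restriction), and interior points
(damped Newton on $P_C = P_D = P_{CD}$ in reduced $(x,y)$ coordinates from
a triangular grid of starts with step 0.05; non-converging starts are
skipped, duplicates within $10^{-6}$ dropped). Stability comes from the
eigenvalues of a central finite-difference Jacobian (step $10^{-6}$) of
the reduced dynamics. We deliberately avoid closed-form derivatives of the
nested sums — they are error-prone — and the payoff sums are polynomials,
so finite differences at this step size are accurate to ~$10^{-9}$. The
polynomials also extend smoothly to slightly negative frequencies, which
lets boundary Jacobians use genuine central differences; clipping there
would silently halve boundary eigenvalues. An eigenvalue with
$|\mathrm{Re}\,\lambda| < 10^{-6}\max(1,|\lambda|)$ is treated as zero and
the point labelled `neutral-within-tolerance` rather than forced into
stable/unstable: at the default parameters the interior point is exactly
such a center (numerically $|\mathrm{Re}\,\lambda| \sim 10^{-12}$), and
whether it is a true center or a very slow focus cannot be decided
numerically — the eigenvalues are reported and the label defers to the
tolerance rule.

`classify_regime()` maps stable sets to labels: only the D vertex stable →
`defection-only`; D and C vertices → `coordination`; only C →
`cooperation-only`; no stable attractor with detected oscillating
coexistence from the canonical interior start $(0.4, 0.3, 0.3)$ →
`oscillatory-coexistence`; anything else → `other`.

One regime deserves a caveat. With $q = 0.1$ and $p = 0.8$ the interior
fixed point is a slightly unstable focus
($\mathrm{Re}\,\lambda \approx +0.005$) and the boundary heteroclinic
cycle is attracting (the product of saddle eigenvalue ratios around the
cycle is $\approx 69 > 1$), so deterministic trajectories spiral outward:
the three strategies keep displacing each other cyclically, but the
minimum frequency decays far below $10^{-6}$ and the strict coexistence
flag eventually fails. Over moderate horizons this regime looks like
growing periodic oscillation, and in a finite population it is exactly the
"each strategy takes its turn dominating" behaviour; over $t = 2000$ the
strict detector reports the collapse. At $p = 1$ the interior point is
neutral and oscillating coexistence is sustained indefinitely.

The "cooperators cannot exclude" scenario is modelled as $p = 0$ with
$\delta$ kept at its default, and additionally as $p = 0,\ \delta = 0$
(no pointless policing cost); both variants lead to defector fixation and
both are exercised by the tests, since the choice between them is a
modelling convention, not a result.

## Experimental statistics

`relative_fitness()` implements
$v = \log_{10}[x_1(1-x_0)/(x_0(1-x_1))]$, the log odds-ratio change
between a focal strain's initial and final frequencies in co-culture;
$v>0$ means the focal strain outgrew its opponent. The statistic is
undefined at fixation and the function says so rather than applying a
hidden pseudocount; the competition-assay generator exposes an explicit
`(k+0.5)/(n+1)` continuity correction flag instead.

`frequency_table()` turns colony counts into proportions with Wilson
score intervals (default 95%). Wilson rather than Wald because colony
samples are small (typically 100 per time point) and frequencies often sit
at the boundary, where the Wald interval degenerates.

`calibrate_parameters()` is a deliberately transparent estimator:
exhaustive grid search minimising the sum of squared differences between
observed colony proportions and model frequencies over all sampled time
points and all three strategies, with ties broken to the first
(lexicographically smallest) grid point. No likelihood is claimed — the
sampling noise is multinomial, but the purpose is parameter *recovery* at
grid resolution, for which least squares on frequencies is adequate and
exactly reproducible.

Model time is mapped to laboratory hours by a declared `time_scale`
(default 1 model unit per hour, so a 24-h cycle spans 24 model units).
Nothing in the model fixes this correspondence — it is a configuration
choice, stated, not an inferred quantity.

## Synthetic data

`generate_evolution_assay()` emulates serial-passage evolution: the
replicator model is integrated across dilution-regrowth cycles and colony
counts are drawn multinomially (default 100 colonies at 8, 16, and 24 h
within each 24-h cycle). Because the model tracks frequencies, a 1:10
dilution is frequency-neutral and cycles only define the sampling grid —
the generator does not model absolute CFU dynamics, within-cycle nutrient
depletion, or the density dependence of quorum sensing itself, so passing
tests say nothing about those aspects of real experiments. Column order is
fixed as $(C, CD, D) = (x, z, y)$ everywhere.

`generate_competition_assay()` restricts the model to a strategy pair,
integrates over the assay duration, resamples the final frequency
binomially at the plating depth, and computes $v$.

`simulate_finite_population()` is the stochastic counterpart: a
Wright-Fisher style update in which each generation's strategy counts are
redrawn multinomially with probabilities proportional to
$\text{count}_I \cdot e^{s P_I}$ (exponential payoff-to-fitness map with
selection intensity $s$, which stays positive under negative payoffs such
as the bare perception cost $-\Delta$). Expected payoffs at the empirical
frequencies drive the update — individual group-sampling noise is
intentionally averaged out, since the target is the replicator limit, not
a new micro-model, and this simulator is an explicitly synthetic stand-in
for round-based laboratory evolution rather than a claim about any
particular experimental protocol. For large populations the sample paths
track the replicator flow after a linear rescaling of generation time; the
test suite estimates the rescaling by least squares on matched oscillation
peak times. Two caveats: the first-peak position of a single stochastic
run is a noisy scale estimator (hence the regression over all peaks), and
the unit-generation update behaves like an explicit Euler step, which near
a neutral center slowly amplifies oscillation amplitude even as
$M \to \infty$ — agreement to within 0.05 mean absolute deviation holds
over the 200-generation horizon used in the tests, but should not be
extrapolated to arbitrarily long horizons.

## Problem sizes used in the tests

The shipped tests integrate to $t = 2000$ for long-run classification,
use $10^5$ Monte-Carlo samples for oracle agreement (4-standard-error
band), 10 seeds of a 10-cycle, 100-colony assay for calibration recovery
over an 11×11 $(p, q)$ grid, and $M = 10^5$, 200 generations for the
finite-population convergence check. These sizes were chosen so that each
property is measured well inside its tolerance; all are arguments, so
larger studies are one function call away.

## Known limitations

* Well-mixed populations only: no spatial or network structure.
* The linear public-goods payoff with equal sharing is the only payoff
  scheme; exclusion never targets conditional defectors, by construction.
* Stability analysis is numerical; center-vs-slow-focus distinctions
  below the $10^{-6}$ eigenvalue tolerance are reported as neutral, not
  resolved.
* The calibration estimator is grid-limited by design; it reports the SSE
  surface so users can see ridge structure, but provides no interval
  estimates.
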
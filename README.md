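# qsgame

Evolutionary game dynamics of quorum-sensing cooperation in bacterial
public-goods games.

## The problem

Quorum-sensing (QS) bacteria secrete costly extracellular enzymes whose
products are shared by everyone nearby — a public good that signal-blind
cheater mutants can exploit without paying for. Yet cooperation often
persists. `qsgame` is for microbiologists and evolutionary modellers who
want to analyse one mechanism for that persistence: *punishment by
exclusion*, in which cooperators police cheats by probabilistically
shutting them out of the shared pool, combined with a third, conditional
strategy that monitors the environment instead of committing.

## The model

An N-player public-goods game in a well-mixed population with three
strategies at frequencies $(x, y, z)$:

* **C** (cooperator): contributes $c$, which is multiplied by $r$ and
  shared; pays $\delta$ per round to punish. With $N_C$ cooperating
  co-players and a sharing pool of size $N_C + N_{CD} + N_W + 1$,
  $\pi_C = rc(N_C+1)/(N_C+N_{CD}+N_W+1) - c - \delta$.
* **D** (defector): contributes nothing; each cooperator excludes it with
  probability $p$, so it survives $E$ excluders with probability
  $(1-p)^E$ and earns
  $\pi_D = (1-p)^{N_C}\, rc\,N_C/(N_C+N_{CD}+N_W+1)$.
* **CD** (conditional defector): pays a perception cost $\Delta$; a
  fraction $q$ behaves as cooperators, the rest cheat; never excluded.

Expected payoffs $P_C, P_D, P_{CD}$ are exact multinomial/binomial sums
over group compositions, and frequencies follow the replicator equations
$\dot{x} = x(P_C - \bar{P})$, etc. Punishment turns the game from
defector-dominance through coordination to full cooperation as $p$ grows,
and with all three strategies it creates rock-paper-scissors cycling:
C beats D (punishment), CD beats C (cheating without being punished),
D beats CD (no perception cost).

The package also implements the competition-assay statistic
$v = \log_{10}[x_1(1-x_0)/(x_0(1-x_1))]$, Wilson-interval frequency
tables from colony counts, grid-search parameter calibration, and seeded
generators for serial-passage and competition experiments, including a
finite-population Wright-Fisher style simulator.

## Worked example

```r
library(qsgame)

params <- qs_params()   # N = 5, r = 3, c = 0.3, delta = 0.3,
params                  # p = 1, q = 0, Delta = 0.35
#> Public-goods game with exclusion
#>   group size N      = 5
#>   enhancement r     = 3
#>   ...

find_equilibria_three_strategy(params)
#> Replicator fixed points (4 found)
#>   vertex   (1.000000, 0.000000, 0.000000)  saddle
#>   vertex   (0.000000, 1.000000, 0.000000)  saddle
#>   vertex   (0.000000, 0.000000, 1.000000)  saddle
#>   interior (0.387010, 0.281267, 0.331723)  neutral-within-tolerance
```

All three pure states are saddles and the interior point is a neutral
center: no strategy can take over, and trajectories orbit the interior
point. Integrating from an interior start confirms sustained cycling:

```r
traj <- integrate_replicator(pop_state(0.4, 0.3, 0.3), params, t_end = 2000)
detect_oscillation(traj)
#> Oscillation report: oscillating
#>   peaks = 27, amplitude = 0.07137, period = 59.81
#>   coexistence of all strategies: TRUE
```

All three strategists coexist, oscillating with a period of about 60 model
time units. Weakening punishment changes the regime — at `p = 0.6` the
two-strategy game is a coordination game with full cooperation and full
defection both stable, and at `p = 0` defectors always fix:

```r
classify_regime(qs_params(p = 0.6), model = "two")
#> Dynamical regime: coordination (2 stable equilibria)
```

A competitor going from 10% to 50% of a co-culture has relative fitness
`relative_fitness(0.1, 0.5)` = `0.9542` (log10 of a 9-fold odds change),
and a seeded emulated serial-passage assay returns colony counts ready
for `frequency_table()` or `calibrate_parameters()`:

```r
des <- assay_design(n_cycles = 3, seed = 42)
head(generate_evolution_assay(pop_state(0.4, 0.3, 0.3), params, des), 4)
#>   cycle time_h n_sampled n_C n_CD n_D
#> 1     1      8       100  41   31  28
#> 2     1     16       100  39   34  27
#> 3     1     24       100  52   29  19
#> 4     2      8       100  45   36  19
```

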
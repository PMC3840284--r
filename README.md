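# aeforage

Operant simulations of foraging have long used the *number* of responses
(ratio schedules) or their duration as a stand-in for the energy an animal
spends foraging — but optimal foraging theory (OFT) is formulated in terms of
energy, and response counts do not convert to joules. `aeforage` is a
discrete-event simulator and analysis toolkit for the **adjusting-energy (AE)
reinforcement schedule**, a procedure in which energy expenditure itself is
the controlling variable: two pecks on a touch surface are reinforced only if
their *interresponse energy* exceeds a requirement that is titrated against a
fixed-ratio (FR) alternative. The package is for behavior analysts and
foraging modellers who want to study the schedule's dynamics — titration
convergence, indifference points, energy cost per reinforcer — with
configurable synthetic subjects instead of live animals.

## The statistic and the procedure

Energy expended by a movement of mass *M* over distance *D* in time *T* is

```
E = M · D² / T²        (joules)
```

With body mass constant within an experiment (unit-mass convention), the
energy of one response pair is the **interresponse energy**

```
IRE = IRD² / IRT²
```

where IRD is the straight-line distance (m) between two consecutive pecks and
IRT the elapsed time (s) between them. Under the AE schedule a peck pair is
reinforced iff `IRE > a`, the current AE requirement. For a requirement of
0.25 J, a pair with IRT = 0.1 s needs an IRD above `0.1·√0.25 = 0.05` m; with
IRT = 0.2 s, above 0.1 m (`min_ird_to_meet()`).

Sessions hold 60 trials (90-min cap) in 15 blocks of four: two forced-choice
trials (one key only; failed forced AE attempts re-run as correction trials,
at most five) and two free-choice trials. The free choices drive a titration:
both AE → `a` rises by 0.001 J for the next block, both FR → falls by
0.001 J, split → unchanged, carrying over between sessions. Conditions run at
least 18 sessions and end when three stability criteria pass; the
**indifference point** for a given FR requirement is the mean AE requirement
over the last six sessions. The **total energy per reinforcement (E/RFT)**
sums the IREs of every response — failed attempts included — emitted for one
reinforcer.

## Worked example

Titrate a stationary logistic agent (indifference requirement
`a* = 0.03` J, temperature 0.005 J) against FR 30:

```r
library(aeforage)
agent <- agent_stationary(a_star = 0.03, tau = 0.005)
cond  <- run_condition(agent, schedule_config(fr_requirement = 30),
                       ae_start = 0.010, seed = 42)
cond
#> <ae_condition> FR30: 18 sessions (stable); indifference point 0.02971 J
```

The condition stabilised at the 18-session minimum and the titrated
requirement recovered the agent's built-in indifference point (0.0297 vs
0.03 J). The stability report shows why the condition ended:

```r
cond$stability
#> # A tibble: 1 × 9
#>   criterion1_pass criterion2_pass criterion3_pass pass  last6_mean prev6_mean
#> 1 TRUE            TRUE            TRUE            TRUE      0.0297     0.0305
```

Energy analytics over the last six sessions' free-choice AE trials:

```r
tr <- free_ae_trials(cond)
e_per_rft(tr)
#> # A tibble: 1 × 3
#>   e_per_rft n_reinforcers run_totals
#> 1     0.139            74 <dbl [74]>
```

Each reinforcer cost the agent 0.139 J on average — more than its ~0.11 J
mean per-response IRE, because unreinforced attempts count toward the next
reinforcer. `autoplot(cond)` draws the titration trajectory;
`run_experiment()` + `condition_summaries()` run a whole ascending/descending
FR series (15, 30, 60, 30, 15) and produce the indifference-point,
IRE-distribution and E/RFT summaries with `plot_indifference()`,
`plot_ire_distribution()` and `plot_e_per_rft()`.

## Command line

A thin wrapper over the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "aeforage.R", package = "aeforage"))') \
  run --config inst/extdata/example-config.yml --seed 7 --out logs
```

Subcommands: `run` (execute a configured experiment, write versioned CSV
event logs), `analyze` (recompute session means, indifference points, E/RFT
from logs), `fixtures` (small deterministic logs), `report` (figures). The
YAML configuration schema is shown in `inst/extdata/example-config.yml`;
every omitted key takes the documented default.

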
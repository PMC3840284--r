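---
title: "The adjusting-energy schedule: model, simulator design, and analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The adjusting-energy schedule: model, simulator design, and analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aeforage)
```

## The problem and the model

Optimal foraging theory predicts that animals forage so as to maximise their
net rate of energy intake, yet classic operant simulations of foraging
control only proxies for energy expenditure — response counts (ratio
schedules) or response time. The adjusting-energy (AE) schedule closes that
gap: it makes the energy of the response itself the reinforced dimension.

The energy of a movement of mass $M$ over straight-line distance $D$ in
elapsed time $T$ is $E = M D^2 / T^2$ joules. For two consecutive pecks on a
touch surface, with the interresponse distance $\mathrm{IRD}$ (m) and
interresponse time $\mathrm{IRT}$ (s), the per-response statistic is the
interresponse energy

$$\mathrm{IRE} = \mathrm{IRD}^2 / \mathrm{IRT}^2 .$$

**Unit-mass convention.** Within a condition the subject's body mass is held
approximately constant, so $M$ drops out of all comparisons; IRE is energy
per unit body mass, reported in joules. `energy_expenditure()` keeps the
general mass term for completeness; everything downstream fixes $M = 1$.

**Strict inequality.** A peck pair is reinforced iff
$\mathrm{IRE} > a$, the current AE requirement. The procedure's definition
speaks of "greater than" for success and "less than" for failure and leaves
exact equality unaddressed; we resolve the boundary as *failure* (matching
the success wording), so `min_ird_to_meet(a, irt) = irt\sqrt{a}` is the
infimum distance, itself non-reinforcing.

**Coordinates.** Pecks are ideal points in continuous planar metres, origin
at the centre of the 22-cm circular response area. No touch-panel pixel
quantisation is modelled (no resolution is specified for the reference
apparatus), and whether a real measured IRD uses the touch centroid or the
first contact point is unknowable from our side; point pecks are the neutral
choice.

## The titration procedure

A session is 60 trials or 90 simulated minutes, whichever comes first, in 15
blocks of four trials: two forced-choice trials (one key shown; left = AE,
right = FR; order pseudorandom within block — a uniform shuffle from the
session's RNG stream) and two free-choice trials. Free choices drive the
staircase: both AE $\to a$ rises by one step (default 0.001 J) for the next
block; both FR $\to$ falls one step; a split leaves it unchanged. The rule
also applies from the last block of one session to the first block of the
next, so session $k{+}1$ starts at session $k$'s final-block requirement
*after* its adjustment.

Design points the published procedure leaves open, resolved here:

* **Initial requirement.** The first session's starting requirement is not
  stated; it is a configuration parameter (`ae_start`, default 0.010 J,
  inside the band titrations typically traverse). Sensitivity to it is a
  test, not an assumption: the parameter-recovery checks start well away
  from the target indifference point.
* **Requirement floor.** No lower bound is stated. We clip at 0.001 J (one
  step above zero): at $a = 0$ every moving peck pair is reinforced and the
  staircase loses its meaning, so a vacuous schedule is excluded by
  construction.
* **Mid-block session end.** If the time cap lands mid-block, the incomplete
  block produces no adjustment and carryover uses the last completed block.
* **Corrections.** Failed *forced* AE attempts re-run the AE schedule phase
  after the 3-s ITI, at most five times; a fifth-correction failure consumes
  the trial unreinforced. Free-choice AE failures get no correction — the
  correction method is explicitly a forced-trial device — just the ITI.
* **Between conditions.** Whether the requirement carried across conditions
  is unstated. `carryover_conditions = TRUE` (default) continues the
  staircase, which mirrors an animal living through consecutive conditions
  and shortens re-convergence; setting it `FALSE` restarts every condition
  at `ae_start`.

**The simulated clock.** Choice latency and peck times come from the agent;
the reinforcer (4 s) and ITI (3 s) are fixed. The 90-min cap is checked
between trials; a trial that has started runs to completion. This makes the
cap meaningful without modelling within-trial interruption, which the
procedure never needs.

**Termination.** Conditions run at least 18 sessions, then end at the first
session where all three stability criteria pass (below). A hard cap
(default 200 sessions, pure artifact plumbing) guarantees termination; hitting
it raises an error carrying the partial logs.

## Synthetic agents

The subjects are synthetic; their job is to supply choices and peck
kinematics with the statistical structure the schedule assumes.

* **Choice.** The stock agent chooses AE with probability
  $1/(1 + e^{(a - a^*)/\tau})$ — a smooth decreasing function equal to 1/2 at
  the indifference requirement $a^*$. Under the block rule the requirement
  drifts up when $P(\mathrm{AE})^2 > P(\mathrm{FR})^2$ and down in the
  opposite case, so the staircase equilibrates exactly where
  $P(\mathrm{AE}) = 1/2$, i.e. at $a^*$: titration is an unbiased estimator
  of the agent's indifference point, which is what the parameter-recovery
  tests verify. Because indifference points in this paradigm rise with the
  FR requirement but no functional form is known, $a^*$ may be supplied as a
  map keyed by FR (default $a^* = N/750$, i.e. 0.02/0.04/0.08 J at FR
  15/30/60 — a calibration, not a fact).
* **Kinematics.** IRT is lognormal (`irt_meanlog = log(0.35)`,
  `irt_sdlog = 0.4`); peck locations are uniform over the response area (or
  gaussian about its centre, truncated by rejection). These defaults were
  calibrated once so typical IREs land in the 0.01–0.2 J band that realistic
  requirements occupy — with uniform scatter over an 0.11-m disc the mean
  IRD is $128r/45\pi \approx 0.0996$ m, and at a 0.35-s modal IRT the median
  IRE is near 0.05 J.
* **Stationarity.** The stock agent's kinematics ignore the requirement, so
  its IRE distribution is identical at every $a$ — the schedule's weak
  control of per-response energy is thereby built in, and the analytics must
  recover it (flat mean IRE). `agent_adaptive()` instead scales its scatter
  by $\sqrt{a/a_{\mathrm{ref}}}$ to probe the opposite regime.
* **Deterministic presets.** `agent_always_ae()` / `agent_always_fr()` pin
  the staircase direction; `agent_alternating()` splits every free-choice
  pair, freezing the requirement — the "immediately stable" subject;
  `agent_custom()` accepts scripted choice and peck functions for exact
  tests.

What the generator does *not* emulate: learning and autoshaping history,
satiation and weight regulation within sessions, positional drift and
perseveration on the touch surface, inter-peck spatial correlation, or
between-subject kinematic differences. Passing tests therefore demonstrate
that the *schedule machinery and analytics* behave as specified under
well-behaved input, not that live subjects would produce any particular
indifference point.

## Stability criteria and analytics

Stability is assessed on the series of per-session mean AE requirements
(the session-mean convention: the unweighted mean over the session's
trials):

1. Neither the condition-wide maximum nor minimum occurs in the last six
   sessions, ties counting against stability. An exactly constant series
   (every value both max and min) passes: the criterion's intent is to
   exclude extremes, not to penalise flatness.
2. No systematic trend over the last six sessions. "No trend" is not
   operationalised in the reference procedure; the default here is the
   conventional reading — a two-sided $t$-test on the least-squares slope,
   non-significant at $\alpha = 0.05$ (with a zero-residual series passing
   iff the slope is zero). `trend_method = "monotone"`, failing only a
   strictly monotone run of six, is available as the laxer alternative.
3. The last-six mean differs from the preceding-six mean by at most 7.5 %
   *of the preceding-six mean* (the stated denominator). The comparison
   tolerates floating-point representation at the boundary (`all.equal`),
   so a series constructed exactly on the threshold passes.

The **indifference point** is the mean requirement over the last six
sessions. **E/RFT** partitions the last six sessions' free-choice AE trials
into runs terminated by a reinforcer and sums *all* attempt IREs within a
run; with zero reinforcers in the input the statistic falls back to the
total IRE. Two decisions the source leaves open: runs do not span session
boundaries, and attempts after a session's last reinforcer belong to no
completed reinforcement and are dropped (they would bias per-reinforcer
totals downward if forced into a run of their own). Correction-trial
(forced) IREs are excluded throughout, since the analytics are defined over
free-choice trials.

`condition_summaries()` adds the cross-condition statistics: Pearson
correlation of E/RFT with the AE requirement (reported as absent below three
conditions) and a Friedman test of the FR effect on indifference points,
computed only when at least three FR levels each have an ascending and a
descending visit — under the default 15, 30, 60, 30, 15 series FR 60 is
visited once, so the test is reported as absent by design.

## Numerics, determinism, and problem sizes

* One RNG stream per session, derived from (master seed, condition index,
  session index) by modular mixing below $2^{31}$; conditions are therefore
  reproducible independently of execution order, and identical seeds give
  byte-identical CSV logs.
* Event logs are versioned plain CSV with doubles at round-trip precision;
  the reader rejects unknown schema versions and reports malformed rows
  with a line number rather than dropping them.
* Boundary cases: `ire == a` fails (strict `>`); a session time cap of zero
  yields an empty but valid log; `ae_step = 0` pins the requirement, which
  the fixed-requirement analytics use.
* Test problem sizes are chosen to keep the full suite in the low minutes:
  parameter recovery uses 20 replicates of 40 sessions; distributional
  checks use 2 000 IRE samples per requirement level (Kolmogorov–Smirnov at
  $\alpha = 0.01$); E/RFT calibration uses 8 fixed-requirement sessions per
  level with the Monte-Carlo oracle $E[\text{attempts per reinforcer}] =
  1/P(\mathrm{IRE} > a)$ at 40 000 draws.

## Limitations

The simulator validates schedule logic and analytics, not animal behaviour:
agent defaults cannot be validated against real subjects' IRE distributions,
the titration's convergence rate depends on the assumed choice temperature,
and the E/RFT growth curve inherits the stationarity assumption. Schedules
beyond FR and AE (VR/VI travel or search analogues), real-time hardware
control, and biomechanical peck models are out of scope.
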
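---
title: "Decision profiling of foraging mice: descriptors, archetypes, and a reinforcement-learning model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision profiling of foraging mice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forageRL)
```

## The problem

Group-housed mice in an automated home cage forage for all their fluid in
a T-maze whose two arms hold solutions of different value (water = 1,
sucrose = 3, saccharin = 1, nicotine + saccharin = 0.3 in the model's
dimensionless units). The high-value side swaps every few days; each swap
starts a new *session*. Even isogenic animals settle into strikingly
different strategies: some track the reward side, some choose almost at
random, some stick to one wall for weeks. `forageRL` turns raw choice
logs and RFID event streams into a quantitative profile of each animal,
decomposes the cohort into extreme behavioral types, fits a generative
decision model per animal, and uses that model to predict behavior under
reward manipulations it has never seen.

## The five choice descriptors

For each animal we compute, on the fraction scale:

* **Switch** — `1 - |p_L - p_R|` over all trials: 0 when one side is
  used exclusively, 1 when side visits are exactly balanced. The anchor
  cases (one side only → 0; equal visits → 1) pin the formula down; the
  linear fold in between is our convention, chosen because it is monotone
  in side imbalance.
* **SwWat / SwSuc** (`sw_low` / `sw_high`) — probability of changing side
  after a low- or high-value outcome, over consecutive within-session
  trial pairs. Pairs spanning a bottle swap are excluded by default
  (`within_session_only = FALSE` restores them) because the outcome label
  of the earlier trial is ambiguous across a swap.
* **Pref** — mean over sessions of the fraction of choices on the
  high-value side. The unweighted session mean (rather than a pooled
  fraction) keeps long sessions from dominating.
* **SideBias** — `|2m - 1|` where `m` is the session-mean left-choice
  fraction. Because the high side alternates between sessions, averaging
  *before* folding cancels reward tracking and isolates spatial bias: a
  perfect tracker has SideBias 0, a wall-hugger 1.

Undefined values (an animal with no qualifying trial pair) propagate as
`NA` and are rejected, by default, when the matrix is assembled.

## Archetypal analysis

The n × 5 descriptor matrix is min-max scaled per column (the same
convention used to display descriptor fingerprints) and decomposed as
`X ≈ A Z`, where the k = 3 archetypes `Z` are themselves convex
combinations of the data (`Z = D X`) and every row of `A` and `D` lies on
the probability simplex. Each animal's row of `A` — its *archetypal
composition* — says how much Tracker, Explorer and Non-Switcher it is; 1
means a pure archetype, and the nearest archetype (arg max) gives a
discrete label. Compositions are visualized in a ternary plot via the
barycentric map with vertices (0,0), (1,0), (0.5, √3/2).

Fitting alternates two exact simplex-constrained least-squares steps,
each solved by Lawson–Hanson non-negative least squares on a system
augmented with a sum-to-one penalty row (penalty constant 200, the
classical device), followed by an exact renormalization so simplex sums
hold to 1e−9. The archetype update computes the unconstrained
least-squares archetypes and projects them back onto the convex hull
through `D`. That two-stage update is the classical algorithm but does
not *guarantee* descent, so a candidate update that would raise the
residual sum of squares is rejected and the restart stops there —
making RSS non-increasing per iteration by construction (asserted in the
tests). Ten seeded restarts from random data rows are run (defaults:
`max_iter = 200`, `tol = 1e-8` relative RSS change, plus an absolute
stop at RSS < 1e−15 for exactly representable data) and the best RSS
wins; the fit is bit-reproducible from `(X, k, seed)`.

Archetypes are named in raw descriptor units: the one with the highest
Pref is the **Tracker**; of the remaining two, the higher SideBias is the
**Non-Switcher** and the last is the **Explorer**. Ties break by SideBias
then index, with a warning. Whether the decomposition should run on
scaled or raw descriptors is genuinely open; we scale, so that Pref and
SideBias (which have compressed dynamic ranges in real cohorts) are not
drowned by Switch.

## The decision model

Choice is modeled by a delta-rule learner with softmax choice and
one-trial perseveration:

* value update (chosen option only): `V <- V + alpha * (R - V)`;
* choice rule:
  `P_R(t) = 1 / (1 + exp(-[beta (V_R - V_L) + chi (C_R(t-1) - C_L(t-1))]))`,
  with the previous-choice indicators coded 0/1 so the perseveration
  input is ±1, and 0 on the first trial.

Parameters are bounded — `alpha ∈ ]0, 1]`, `beta ∈ ]0, 20]`,
`chi ∈ [-2, 2]` — with the open ends realized as a floor of 1e−6 for the
optimizer. Rewards are deterministic at the chosen side's current
solution value, and learned values persist across bottle swaps: the swap
changes which side pays what, not what the animal has learned. Initial
values are 0 when fitting real data (nothing is known before the first
trial) and 1 when simulating naive agents (the water value); both are
explicit `v0` fields, and the discrepancy is deliberate — it mirrors the
two distinct uses of the model.

Per-animal fitting maximizes the sequence likelihood with L-BFGS-B from
20 uniform random starts inside the parameter box plus a 3 × 3
deterministic grid over (alpha, beta) at chi = 0 — the likelihood is flat
in alpha as beta → 0, and uniform starts alone can miss low-beta /
high-alpha basins — and a final Nelder–Mead polish. Per-trial
probabilities are floored at 1e−12 before the log so pathological
parameter values stay finite during the search. Ties between starts
(< 1e−9 nats) go to the earlier start, making fits reproducible. The
nested chi = 0 model is fitted the same way, and the pair is compared by
BIC (`2·nll + p·ln n`) and a 1-df likelihood-ratio test; a slightly
negative raw statistic from optimizer noise is clipped to 0 with a
warning.

## Generative simulations

`simulate_mouse()` runs the same model forward (draw a choice from
`P_R`, deliver the chosen side's value, update) under a session schedule;
the default emulates the water/sucrose phase: six 50-choice sessions,
alternating high side starting on the left (the starting side is a
convention; it is configurable). Three prediction experiments build on
it:

* **delta-V sweep** — one side fixed at value 1, the other at `1 + dV`
  for `dV ∈ {-1, 0, 1, 2, 3}`; descriptors (Pref taken toward the
  varying side) are averaged over replicates. Simulation seeds depend on
  (group, replicate, animal) but not on dV, so the `dV = 2` column is
  exactly the plain water/sucrose simulation.
* **attribution study** — each animal re-simulated with its own triplet,
  with one parameter permuted across animals, or with whole triplets
  permuted. Permutation (without replacement) preserves marginals; a
  with-replacement option exists. The summary statistic is the mean
  absolute between-archetype gap of the descriptor group means.
* **cross-context prediction** — twelve sessions with a value change
  after six: (1, 3) then (1, 0.3), i.e. the varying side flips from the
  best (sucrose) to the worst (nicotine) option. Values carry across the
  boundary by default, mirroring the animals' continuous experience; a
  reset option supports sensitivity analysis.

## The synthetic cohort generator

The generator defines the study conditions for every test in this
package. Each profile draws latent triplets uniformly from
archetype-typical ranges:

| profile | alpha | beta | chi | trials/day |
|---|---|---|---|---|
| Tracker | 0.5–0.95 | 0.8–2.5 | −1.1–1.1 | 15–25 |
| Explorer | 0.1–0.4 | 0.2–0.5 | −1.1–1.1 | 10–18 |
| Non-Switcher | 0.001–0.03 | 4–8 | −1.1–1.1 | 5–10 |

High-alpha/low-beta agents track the reward; low-alpha/high-beta agents
barely learn but choose near-deterministically on tiny value
differences, which locks them onto one side; intermediate agents explore.
These ranges are calibration targets, not measurements: the binding
requirement, asserted in the acceptance tests, is that cohorts drawn
from them are recovered end to end (nearest-archetype labels match the
planted profile for ≥ 80% of animals, and maximum-likelihood fits
recover each parameter with Spearman ρ ≥ 0.7 on the six-session,
50-trial schedule). The ranges were calibrated on that criterion across
a panel of validation seeds disjoint from the acceptance seed. Two kinds
of adjustment proved necessary. First, the chi range was widened to
±1.1: with a narrow perseveration range the rank signal drowns in
estimation noise for near-deterministic records, where chi is partly
confounded with beta·ΔV. Second, the beta ranges were separated (a gap
between the Explorer ceiling and the Tracker floor, and a trimmed
Non-Switcher range), because moderate-beta Explorers genuinely track and
get labeled Tracker, and soft Non-Switchers drift toward Explorer. The
two requirements pull against each other — chi identifiability needs
stochastic choices, profile separation needs near-deterministic ones —
so the final ranges are a compromise, and an unlucky cohort draw can
still dip below the nominal thresholds. Parameter-recovery
experiments fit with `v0 = 1` — matching the generative initial value —
so they measure identifiability, not initial-condition misspecification.

By default each animal's six sessions last three days
(`n = round(3 × trials/day)` trials), reproducing heterogeneous record
lengths; a fixed schedule can be forced. Matched RFID event streams come
from a continuous-time Markov walk over the five cage zones (nest N,
feeder F, stairs S and T-maze T, all routed through the hub C) with
per-profile overall rates and hub-exit preferences, a ×3 rate increase
in the dark phase, and long exponential nest dwells in the light phase
(mean 3 h, probability 0.35 per light-phase nest entry) giving the
bimodal nest-residency distribution typical of such cages. Profile rate
scales are set so that activity (NbD) rises with Tracker composition and
the nest-to-feeder hub transition (NtoF) falls — the sign structure the
correlation module must recover.

What the generator does **not** emulate: reward stochasticity, satiety
or consumption dynamics, social gating of maze access, intertrial
timing, or the real cohort's archetype proportions. Passing tests
therefore demonstrate that the pipeline's machinery is correct and
internally consistent under realistic heterogeneity — not that it
reproduces any particular animal cohort.

## Home-cage metrics

Residency episodes are maximal runs of same-zone detections; the final
open episode is closed at the last event and flagged. Occupancy uses all
recorded dwell time. **NbD** counts zone transitions per observed day;
**EnA** is the Shannon entropy (nats) of the occupancy distribution,
between 0 (one zone) and ln 5 — the definition is ours, chosen because
occupancy evenness is the natural "territory sharing" summary; the
event logs do not constrain it further. First-order transition
probabilities condition on the source zone; second-order transitions
describe hub-routed moves (from a non-hub zone to the next non-hub zone
reached, skipping any number of hub visits). Both normalize to 1 over
observed destinations; sources never left are undefined rather than
zero. Daily fluid consumption is estimated as the chosen-side bottle
delta minus the non-chosen-side delta (which absorbs evaporation and
handling loss), averaged over days with both measurements; implausibly
negative deltas are flagged, never clipped. Composition–metric
association uses Pearson correlation and per-pair OLS (slope, adjusted
R², slope p); group contrasts delegate to Wilcoxon/Kruskal–Wallis with
Holm correction.

## Numerical choices and degenerate inputs

* Logistic terms are evaluated in saturating form; extreme logits give
  probabilities in (0, 1) without overflow.
* The likelihood floor (1e−12 per trial) only matters for pathological
  parameters during search; at fitted optima it is inactive.
* Empty records, all-empty sessions, exactly tied side counts, sources
  never left, and under-sized cohorts (n ≤ k) all return `NA` flags or
  informative errors rather than silent numbers.
* Every stochastic function takes a seed, and cohort-level functions
  derive per-animal child seeds from it with a fixed integer hash, so
  outputs are byte-reproducible and per-animal records do not depend on
  cohort-mate count.

## Problem sizes used in the tests

The test suite and the acceptance script run on synthetic cohorts of 60
animals (20 per profile) with six 50-trial sessions (or 3-day empirical
scaling), 100–200 sweep replicates, and 10-day tracking streams. These
sizes were chosen as the smallest at which the Monte-Carlo assertions
(recovery correlations, sweep symmetry at dV = 0, attribution ratios)
are stable across seeds.

## Known limitations

* The Switch/Pref/SideBias aggregation conventions are declared, not
  recovered from data; alternative conventions would shift descriptor
  values but not the pipeline's structure.
* chi is weakly identified for near-deterministic (Non-Switcher-like)
  records — its likelihood contribution is confounded with beta·ΔV —
  so per-animal chi estimates in that regime carry large uncertainty
  even when the cohort-level rank correlation is high.
* The archetype count is fixed at k = 3 by design; no model-selection
  scree is provided.
* Hypothesis-testing helpers are thin wrappers over standard routines,
  intended for reporting parity, not methodological contribution.
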
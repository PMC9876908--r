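---
title: "Modelling choice on the two-stage Markov decision task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling choice on the two-stage Markov decision task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twostep)
```

## The task

The environment is a two-layer tree. From the start state S0 a left/right
choice leads to one of four second-stage states (L1, L2 for left; R1, R2
for right), the high-probability successor with probability 0.7 (the
*common* transition) and the other with 0.3 (*rare*). A second left/right
choice then leads, again 70/30, to an outcome state worth 0, 10 or 25 yen.
Outcome identity is keyed by reward amount: every path worth 25 yen ends
in the same outcome state. All model computations use rewards rescaled to
0, 0.4 and 1; yen are used for behavioral summaries.

The canonical layout shipped with the package (`two_step_task()`, also as
`inst/extdata/canonical_task.yaml`) is constructed so that backward
induction gives the first-stage right action the larger optimal value
(14.5 yen against 9.25) and places the single best second-stage action
(17.5 yen) at R1-left, i.e. behind the common transition after the optimal
first choice. Only those optimal values pin the layout; the arrangement of
the left branch is otherwise a package choice and any layout with the same
tree shape can be supplied via the YAML configuration.

```{r}
task <- two_step_task()
ground_truth_values(task, units = "yen")
```

Two simplifications relative to a live experiment: the 2-second response
deadline and the repeat-on-miss rule are not modelled (simulated agents
always respond), and stimulus randomization is out of scope.

## The learner family

Three learners share one recursion (`process_trial()` in R,
the same loop compiled in C++ behind `trial_loglik()` and
`simulate_hybrid_agent()`):

* **SARSA** (model-free): `Q(s,a) ← Q(s,a) + α·δ`,
  `δ = r(s′) + γ·Q(s′,a′) − Q(s,a)`, γ fixed at 1. The stage-1 update uses
  reward 0 and bootstraps on the *chosen* stage-2 action (on-policy, hence
  the model's name); the stage-2 update uses the scaled outcome reward
  with a terminal bootstrap of 0.
* **FORWARD** (model-based): transition estimates updated from state
  prediction errors, `T(s,a,s′) ← T(s,a,s′) + η·(1 − T(s,a,s′))`, the
  non-visited successor scaled by `(1 − η)` so rows stay normalized;
  values planned through the estimates,
  `Q_FWD(s,a) = Σ_s′ T(s,a,s′)·[E[r(s′)] + max_a′ Q_FWD(s′,a′)]`, with
  outcome rewards treated as known (`E[r]` is the scaled reward for
  outcome states, 0 for second-stage states; max over an empty action set
  is 0).
* **HYBRID**: `Q_HYB = w·Q_FWD + (1 − w)·Q_SARSA`, elementwise. `w = 0`
  reproduces SARSA exactly, `w = 1` makes choice depend only on FORWARD
  values while the SARSA table still updates silently (and vice versa).

Choices follow a softmax, `P(s,a) ∝ exp(β·Q(s,a))`, computed with
max-subtraction for overflow safety.

**Order of computation within a trial.** Choice probabilities for both
stages are emitted from the value tables as they stood *before* the trial
(the standard likelihood convention); then both observed transitions
update `T`, the FORWARD table is fully recomputed (cheap: ten state-action
pairs), and the two SARSA updates are applied in stage order.

**Initial values.** `Q_SARSA = Q_FWD = 0` and `T = 0.5/0.5` everywhere, so
a fresh agent is exactly indifferent and the stage-1 value difference
starts at 0. One consequence worth knowing: because `Q_FWD` is recomputed
from `T` only after a trial, the very first trial replaces the neutral
zero table with the one implied by uniform beliefs, so even with
`α = η = 0` the probabilities can shift once between trials 1 and 2 before
freezing. The alternative (initializing `Q_FWD` at its uniform-belief
fixed point) would freeze everything at zero learning rates but make the
fresh agent non-indifferent in states whose two actions differ under
uniform beliefs; we prefer the indifferent start, which is also what
anchors the learning curves at 0.

## MAP estimation

Free parameters are the two learning rates α, η ∈ (0, 1), the inverse
temperature β ∈ (0, 10) and the weight w ∈ [0, 1]; γ is fixed. The fitted
objective is the negative log posterior: the teacher-forced negative
log-likelihood (`−Σ log P(a1) − Σ log P(a2)`) plus negative log prior
densities — beta(2, 2) for α and η, gamma for β, nothing for w (it is only
bound-constrained).

The gamma prior is parameterized as shape 2, *scale* 3 (mode 3, mean 6).
The shape/rate reading (mean 2/3) would place almost all prior mass below
β = 2 and heavily penalize the β ≈ 3–6 regime that softmax choice on
0–1-scaled values actually requires; both parameterizations are available
in `prior_spec()`.

`fit_learner()` divides a 200-trial session into five 40-trial blocks.
Each block is fitted by bound-constrained L-BFGS-B started from the
previous block's estimates (prior modes for block 1) plus Latin-hypercube
restarts — 10 starts for block 1, 5 for later blocks; a single constrained
optimization is the minimum the procedure needs, the restarts guard
against local minima. The learner state carried into block k+1 is obtained
by replaying block k under its fitted parameters from its incoming state.
With no data the optimizer sits at the prior modes (α = η = 0.5, β = 3),
which the test suite checks to 1e-4; the weight has no prior gradient and
stays at its start. Parameter bounds are enforced 1e-6 inside the open
intervals; optimizer convergence is flagged per block.

`fit_fixed_effects()` shares one parameter set per block across a group,
summing the members' likelihoods while each member keeps their own
carryover state. The prior penalty is applied once in total by default —
regularization of a shared parameter set should not grow with group
size — but a per-participant weighting is selectable; under the latter,
fitting a duplicated participant provably returns the single-participant
estimates, which the suite verifies numerically.

**Model comparison.** `compare_models()` reports, per model and block,
`BIC = 2·NLL_pooled + k·log(n_obs)` with two observations per trial.
The default pools per-participant individual fits and counts the model's
parameters once — the convention commonly used when one criterion per
model is computed from all participants' data, and the reading under
which a 30-agent synthetic HYBRID cohort (w = 0.5, α = η = 0.2, β = 5)
prefers HYBRID in all five blocks. The statistically stricter
fixed-effects variant (`method = "fixed"`) makes the penalty exact for
the parameters actually fitted; under it the late-block HYBRID advantage
on such a cohort (a few nats over 1200 trials) can fall below the
two-parameter penalty gap, and SARSA can win late blocks. Both are
exposed because the choice is a genuine convention, not a theorem.

## SVO scoring

Six primary slider items, each a nine-option self/other payoff menu, ship
as a data file. The angle is
`atan((mean other − 50) / (mean self − 50))` in degrees; the response at
the 50/50 origin is undefined and flagged. Group splits: *strict* —
prosocial at or above the inequity-aversion archetype 37.48°, proself at
or below the complete-individualism archetype 7.82°, intermediate
otherwise (boundaries included in the named group, since an archetypal
responder must belong to it); *conventional* — prosocial strictly above
22.45°. Exact enumeration of all 9^6 option combinations shows the
attainable angle range on these items is −7.82° to 61.39°; the synthetic
generator truncates its proself angle distribution accordingly.

## Behavioral metrics

`moving_average_reward()` uses a centered 20-trial window spanning 10
trials before through 9 after the current one (the convention of an
even-length centered moving mean), truncated at the series edges so the
mean is over the available trials only; the placement is configurable and
recorded in the output attributes. `rt_block_summaries()` averages RT1 and
RT2 per 40-trial block, RT2 split by common/rare transition, excluding the
session's first trial; empty cells yield `NA`, never 0.
`group_series_compare()` applies a per-trial Wilcoxon rank-sum test
between two groups' per-participant series values (per-participant values,
not participant means, enter the test). Inferential mixed models and
ANOVAs are deliberately out of scope; `cohort_trial_table()` emits the
tidy long table such routines expect.

## The simulation study

`run_weight_schedule_sim()` simulates independent HYBRID agents
(α = η = 0.2, β = 5.0) whose weight follows a blockwise schedule:
w = 1 in block 1 then 0.5 (model-based learner), or w = 0 then 0.5
(model-free). Per repetition and trial it records the obtained reward and
the stage-1 hybrid values of both actions at emission time, whose
difference Q(1,R) − Q(1,L) starts at 0 and grows toward the ground-truth
gap as learning proceeds.

Learning speed is the slope *b* of an origin-constrained sigmoid
`y = a/(1 + exp(−b·x)) − a/2` fitted per repetition by nonlinear least
squares. Because *a* enters linearly for fixed *b*, the plateau is
profiled out analytically and *b* found by bounded one-dimensional
minimization over (0, 5] — no starting values, no convergence failures
from bad initialization. Degenerate inputs (constant series), non-positive
plateaus and boundary slopes are flagged as failed fits; failed fits are
excluded from slope comparisons and counted in the report. Slopes are
compared with a rank-sum test whose normal-approximation z (tie-corrected)
is reported alongside the two-sided p.

The defaults run 1,000 repetitions per schedule; a full 10,000-repetition
run is a single argument away and costs minutes. The
qualitative contrast (model-based learners earn more in block 1 and have
larger slopes) is what the test suite asserts; the exact magnitude of the
rank-sum statistic depends on repetition count and fitting details and is
not a target.

## The synthetic cohort generator

`generate_cohort()` is the package's stand-in for a real dataset: for each
participant it samples per-block true parameters from group-specific
truncated normals, simulates the 200-trial session generatively, attaches
reaction times and slider responses, and records the truth for recovery
studies. Its defaults are the cohort conditions the package assumes:

* Group parameter means anchor to whole-session group estimates (proself
  α 0.34, η 0.49, β 5.21, w 0.49; prosocial 0.33, 0.48, 4.58, 0.40),
  unfolded over blocks with the qualitative trends of the blockwise
  analysis — α decreasing, β increasing, w decreasing from an elevated
  proself block-1 value (0.75 vs 0.50). Between-subject SDs (0.12 for
  rates and weight, 1.0 for β, truncated inside the bounds) are the
  generator's own realism choice.
* SVO angles are bimodal: proself targets from a truncated normal below
  7.82°, prosocial above 37.48°; slider responses are constructed by exact
  search over the item menus to score within 1° of the target.
* Reaction times follow a generative model of the package's own design: RT1 decays exponentially from ~650 ms toward a
  480 ms asymptote with a 30-trial constant (practice); RT2 is
  520 ms + 280 ms × transition surprise `1 − T(S0, a1, s2)`, so rare
  transitions slow responding once the transition model is learned;
  Gaussian noise (SD 80 ms), truncated to [150, 2000] ms. These constants
  were chosen once to produce the qualitative pattern RT1 < RT2-common <
  RT2-rare in late blocks and are fully config-exposed.
* One root seed yields per-participant child seeds, recorded in each
  dataset, so any participant is individually reproducible.

What the generator does *not* emulate: missed/repeated trials and their
missing RTs (the reader tolerates missing RT cells in real logs),
within-block drift of the true parameters, any coupling between SVO angle
and learning parameters beyond group membership, and the deposited
dataset's exact file schema (a column-mapping adapter in
`read_trial_log()` covers dialect differences). Tests passing on
synthetic cohorts therefore validate the estimation machinery — not
claims about human data, whose printed values (RT means, group sizes,
total earnings) are properties of the deposited recordings.

## Problem sizes and numerical choices

The shipped tests use 30-agent cohorts for model comparison, 40+40 agents
for weight recovery, and 1,000 repetitions per schedule for the
simulation contrast — sizes at which each check is decisively powered
while the whole suite runs in about a minute. Likelihood equivalence with
an independently written straight-line oracle is asserted to 1e-10 on
fuzzed short logs; transition-row stochasticity to 1e-9; behavioral
metrics exactly against brute-force recomputation. Ties in the FORWARD
max are resolved by the max value itself (no action sampling occurs
inside the Bellman term), and the common/rare label follows the
higher-probability successor, which also covers degenerate
probability-1 layouts.

## Known limitations

* Per-block, per-individual estimates from 40 trials are noisy; weights
  can pin to the [0, 1] bounds in single blocks. Group-level summaries
  are the supported level of inference.
* The fixed-effects objective shares parameters but not states; a
  hierarchical treatment (random effects, empirical Bayes) is out of
  scope, as are trial-resolved weight dynamics within a block.
* The secondary nine-item SVO slider set and the inequality-aversion
  decomposition are not implemented; scoring is primary-items only.
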
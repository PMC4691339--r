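---
title: "Curation efficiency, overhead and resource planning with rocur"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curation efficiency, overhead and resource planning with rocur}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rocur)
```

## The setting

A restricted curation project has a candidate set `x` of `n` items, a team
with average curation speed `v` (items per time unit, the inverse of the
mean curation time), and a hard time budget `T_max`. Resources are
*sufficient* when `v · T_max ≥ n` — the boundary counts as sufficient —
and *insufficient* otherwise, in which case a filtering strategy must cut
the candidate set down to a curable subset `x^f` of size `m` small enough
that `v · T_max ≥ m`. `feasibility()` performs exactly this check.

Throughout, items retained by a filter that were worth retaining are TPs,
wasteful retentions are FPs, and all metrics are kept internally as
fractions; only report rendering converts to whole percentages (rounded
half away from zero, so 0.3888… prints as 39%).

## Overhead as an efficiency measure

Precision measures the quality of a filtered set but compares filtering
strategies poorly: equal precision differences do not correspond to equal
differences in wasted work. The package therefore centres on **overhead**

$$O = \frac{FP}{TP}, \qquad P = \frac{1}{1+O},$$

the wasted effort per unit of productive effort. The conversion functions
(`overhead_from_precision()`, `precision_from_overhead()`) are exact
inverses, and the mapping is convex: moving precision from 40% to 50%
removes 50 points of overhead, while moving from 75% to 85% removes only
15 — improving an already-precise filter buys little. When FPs and TPs take
different mean curation times, `overhead_time_weighted()` weights the ratio
by `T̄_FP / T̄_TP`. Two denominator conventions are provided: the
definitional `tp` denominator (`FP·T̄_FP / TP·T̄_TP`, the default) and a
`filtered` denominator that expresses wasted time against the
TP-equivalent time of the whole filtered set, which is the natural
first-approximation when one only knows the filtered-set size. The worked
IL32/IL10 example in the README uses the `filtered` convention to get 39%
(uniform times) and 19% (TPs twice as slow).

Division-by-zero policy: a filter that yields only FPs has *infinite*
overhead, returned as R's `Inf` so that comparisons and optimizers treat it
as worst-case; a filter that yields nothing at all raises an
undefined-metric error, as does precision on an empty set. `f_beta(0, 0)`
returns 0 by the usual convention.

## Value scales, prospective metrics

With a continuous value scale `[w_min, w_max]` (FPs and redundant items at
`w_min`), overhead becomes a statement about value creation:

$$O = \frac{\sum_i (w_{max} - w_i)}{\sum_i (w_i - w_{min})},$$

optionally weighted by per-item curation times `T(w_i)`, and — before
curation, when each item is only *probably* a TP — adjusted by the TP
probability `p_i`: an item contributes its expected value shortfall plus
the full span `w_max - w_min` for the event that it turns out to be an FP.
Each refinement reduces to the previous one in the appropriate limit
(equal times; all `p_i = 1`; binary values recover `FP/TP` exactly), and
those reductions are property-tested.

## The strategy toolbox

Strategies live in precision–recall space. One strategy dominates another
when it is at least as good on both axes and strictly better on one;
`pareto_frontier()` extracts the maximal set. The **area covered (AC)** is
defined here as the area of the region weakly dominated by the toolbox —
the union of origin-anchored rectangles of the fixed operating points,
with adjustable strategies contributing the region under their
interpolated precision–recall curve. This geometric definition makes
"candidate falls inside the AC" provably equivalent to "some achievable
operating point weakly dominates the candidate", which is how
`is_inferior()` decides whether a new strategy adds capability; an exact
duplicate is inferior. The area is computed exactly by integrating the
upper envelope of the strategies' piecewise-linear precision profiles
(splitting at knots and pairwise intersections); the test suite checks it
against a 1000×1000 grid-counting oracle to within 2·10⁻³.

Adjustable strategies must have strictly increasing recall knots and
non-increasing precision — as recall is opened up, the filtered set grows
and precision falls, so overhead rises monotonically. `operating_point()`
interpolates linearly between knots; a precision target on a flat stretch
resolves to the highest recall achieving it (the larger filtered set).

`select_strategy()` turns the toolbox into a decision: expected TPs are
`n·π·R` (the prevalence π of valuable items is an explicit input — nothing
in the formalism pins it down, so no default is provided), the expected
filtered size is `m = n·π·R / P`, and an option is feasible when the
expected curation time of `m` items plus the strategy's one-off
application cost fits in `T_max` (the cost is charged against the budget
*before* feasibility is judged). Among feasible options the expected-TP
maximizer wins, with deterministic tie-breaks (lower overhead, then
smaller `m`, then name). For an adjustable strategy the chosen operating
point is the budget-exhausting recall, found by root-solving the
(monotone) expected-time function along the curve to 10⁻¹⁰. When nothing
is feasible the result is an explicit infeasibility report naming the
smallest achievable option versus the budget. This is where a 90%
precision / 10% recall filter with an F-measure of just 18% earns its
keep: under a scarce budget its small output is the only one that fits.

## Planning a single project

`rank_and_schedule()` implements the cut-off-free strategy of curating in
descending order of estimated value until time reaches `T_max`, which
needs no estimate of `v`. Two deliberate choices: ties on value go to the
shorter item first (more items per budget), then to the lexicographically
smaller id (determinism); and an item too long for the *remaining* budget
is skipped rather than stopping the schedule — skipping weakly dominates
stopping for the curated value sum, and with uniform item times the greedy
schedule is provably value-optimal (checked against subset enumeration on
instances of up to 12 items).

`apply_value_floor()` enforces an absolute minimum estimated value, set in
advance the way an E-value threshold is set in sequence-similarity
searches. `mark_redundant()` assigns items whose identity key was already
curated (or repeats within the project — first occurrence kept) the value
of an FP, `w_min`, idempotently. `expected_value_rank()` orders items by
`p·w + (1−p)·w_min`, the expected value when an FP is worth the minimum;
this is the one-dimensional reduction of the two-criteria (value,
TP-probability) ranking problem, chosen because it needs no extra
parameters and degrades gracefully (`p ≡ 1` recovers plain value ranking).
`curate()` closes the loop retrospectively, recomputing realized
precision, the overhead variants, value sums and the value-estimation
error from gold labels and true values.

## Allocating time across projects

`allocate_time()` minimizes `Σ_j O_j` subject to `Σ_j T_max^j = T_max`,
with time discretized into quanta so budgets conserve exactly. A project's
`O_j` at a candidate budget is the value-weighted overhead (selectable:
simple overhead) of what its value-ranked schedule would curate under that
budget. A budget too small to curate anything contributes a worst case —
by default the overhead of the project's single least valuable item —
because leaving the degenerate case at zero would let the optimizer
"solve" a project by starving it. The composition space is enumerated
exhaustively when it has at most 10⁴ states; larger instances use greedy
marginal-improvement followed by pairwise exchanges of arbitrarily many
quanta (single-quantum exchanges can stall on step-shaped `O_j(budget)`
profiles). The heuristic is certified against exhaustive enumeration on
random instances with up to 12 quanta and 3 projects in the test suite;
at larger scale it is a heuristic with a guaranteed-exact budget
constraint, not a certified optimum.

## The simulator

`generate_project()` synthesizes the statistical structure the planner
assumes: `n` items, gold TP labels at base rate π, true values either
binary (TPs at `w_max` — the right model for validating count-based
metrics) or beta(2, 5)-distributed on the value scale (a right-skewed
"few gems, many middling items" profile for value-scale tests), per-item
curation times lognormal around per-class means (default `T̄_TP = 2`,
`T̄_FP = 1`, σ_log = 0.25 — TPs cost extra storing/annotating work, FPs
only a read-and-discard), optional Gaussian estimation noise on values,
and TP probabilities from a logistic transform of the label plus latent
noise (slope 2, noise sd 1 by default), which makes them informative but
imperfect, approximately calibrated by construction. All draws descend
from one root seed through per-component streams derived by fixed labels,
so adding a component never perturbs another's draws and identical
config + seed reproduces a project exactly.

`simulate_filter()` realizes an operating point stochastically: TPs kept
with probability `R`, FPs at the rate that makes the *expected* precision
equal the target (unachievable targets — more FPs needed than exist — are
rejected with the feasible envelope). `recovery_experiment()` closes the
validation loop: across target precisions {0.25, 0.4, 0.5, 0.75, 0.85}
the mean realized overhead matches `(1−P)/P` within three standard errors
(the suite runs 200 replicates on 10⁴-item projects), and realized TP
production rates match `1/(T̄_TP(1+O_w))` with `O_w` the time-weighted
overhead.

What the simulator does *not* emulate: real text, corpus structure,
correlated errors between filters, curator fatigue or the quality/quantity
trade-off, and temporal drift of item value after curation. Passing tests
therefore demonstrate internal consistency of the metrics and optimizers
under the stated statistical assumptions, not performance of any concrete
text-mining pipeline on real literature.

## Numerical and scale choices

Desk-scale quantities (the metric family, the use-case arithmetic) are
closed-form and exact. Tolerances that appear in the tests are: 10⁻¹²
for the precision↔overhead round trip, 2·10⁻³ against the grid-counting
area oracle, three standard errors for Monte-Carlo recovery. Problem
sizes in the suite — up to 12-item enumeration for the scheduler, 12
quanta × 3 projects for the allocator, 10⁴ items × 200 replicates for
recovery — were chosen as the largest sizes at which the independent
oracles (full enumeration, dense grids) remain exact, which is what makes
the certification meaningful.

## Limitations

Estimated values enter as point estimates; the framework acknowledges
they may deserve confidence intervals, but no interval propagation into
overhead is defined, so none is implemented. The two-criteria ranking by
value and TP-probability is reduced to a single expected value rather
than a full bi-objective treatment. The allocator's optimality is
certified only at enumeration scale. "ROC" in this package always means
*return on curation*; no receiver-operating-characteristic machinery, and
no training or benchmarking of actual classifiers, is included.
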
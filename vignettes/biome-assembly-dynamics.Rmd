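---
title: "Reconstructing biome assembly dynamics from dated phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing biome assembly dynamics from dated phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biomedyn)
```

## The question and the model

How is a young biome — the Arctic tundra being the motivating case —
assembled over evolutionary time? Two processes build a regional flora:
immigration (lineages dispersing into the region) and in situ speciation
(lineages diversifying once there). Given a collection of dated, ultrametric
phylogenies whose tips are coded for geographic range, `biomedyn`
reconstructs where ancestors lived, classifies the two kinds of
species-level events, and characterizes how their rates changed through
time.

The range-evolution model is dispersal–extinction–cladogenesis (DEC), a
continuous-time Markov process on the set of non-empty area subsets
(ranges). Anagenetically, a range `G` expands to `G + {j}` at rate
`d * sum_{i in G} m[i, j]`, where `m` is a pairwise dispersal-multiplier
matrix that may differ between time slices, and loses any occupied area at
rate `e` per area; a singleton that loses its area enters an absorbing null
range (the lineage-extirpation pathway), which is excluded from tip
observations, cladogenesis, and the root prior. The maximum range size is
set to the maximum observed among extant taxa. At a speciation node the
parent range splits: a singleton is inherited identically; a widespread
range either stays intact in one daughter while the other occupies a
singleton subset (subset sympatry), or splits into a singleton and its
complement (vicariance). All allowed scenarios are weighted equally; the
package has no founder-event ("+J") parameter.

One convention deserves emphasis. The two daughters of a node are treated
as exchangeable: in the likelihood, each *unordered* daughter-range outcome
carries its total probability on whichever assignment matches the data. For
a widespread parent `{A, B}` there are six equally probable ordered
scenarios, so the unordered vicariance outcome `{A} | {B}` has probability
1/3, and a cherry with tips `{A}` and `{B}` under `d = e = 0` has
root-conditional likelihood exactly 1/3. The rate parameters `(d, e)` are
fitted by bounded quasi-Newton maximum likelihood from a fixed start, and
marginal ancestral ranges are obtained by combining down-pass and up-pass
partial likelihoods, with per-node rescaling against underflow.

## Events, curves, and their features

With a two-state regionalization (focal biome `A` vs non-focal `B`), two
event classes are read off the MAP reconstruction:

* **dispersal into the biome** — an edge whose child range contains the
  focal area while the parent range does not. Its age window runs from the
  parent node's 95% HPD older bound to the child node's HPD younger bound
  (point ages where HPDs are absent): the gain happened somewhere on that
  edge.
* **in situ diversification** — a node whose range and both daughters'
  ranges contain the focal area; its window is the node's own HPD.

A node may contribute one event of each class; repeated gains along a path
each count separately; and under a finer regionalization the source of a
dispersal is the single non-focal area of the parent range, with ambiguous
(widespread or empty) parents excluded from per-source tallies rather than
fractionally split.

Event dynamics are summarized as MDE curves ("maximal number of observed
dispersal / in situ diversification events", MDisE / MDivE): time is cut
into 0.1-Ma slices from the oldest interval bound to the present, each
event is counted in *every* slice its credibility interval overlaps, and
the series is smoothed with a centered 0.5-Ma sliding mean, truncated at
the ends so no artificial zeros are padded in. Slices are half-open
(`(younger, older]`, the youngest slice closed at 0) so a point age falls
in exactly one slice, while event intervals themselves are closed. Values
are counts per slice by default; a per-Ma rescaling (x10) is a flag.

The curve's features are its **origination** (the oldest event point age;
the oldest nonzero slice is reported alongside as "support onset") and its
**peak** (the midpoint of the contiguous run of slices attaining the
maximum smoothed value — the oldest run if several tie, flagged `flat`
when the run spans the whole series). Confidence intervals come from 1000
bootstrap pseudoreplicates: by default one age is drawn uniformly within
each event's credibility interval per replicate ("interval" mode, the
natural reading of resampling *from* the raw intervals), with classical
event resampling with replacement available ("resample" mode); CIs are the
2.5/97.5 percentiles, deterministic under a seed.

## Change points

Trends in the smoothed curves are modeled by segmented (piecewise-linear)
regression fitted by iterative linearization: given working breakpoints,
the response is regressed on `{1, x, (x - psi_j)+, I(x > psi_j)}` and each
breakpoint moves by minus the gap-to-slope-difference ratio, with step
halving so the broken-line residual sum of squares never increases, until
updates fall below 1e-6 Ma (at most 100 iterations; non-convergence is
reported, not thrown). Breakpoints are kept at least three grid steps
apart — closer pairs are not identifiable on a 0.1-Ma grid. Their 95% CIs
use the delta-method standard error of the ratio. Models with 1–4
breakpoints are each fitted from the quantile initialization, five seeded
random initializations, and a warm start that augments the previous best
fit (which makes the best RSS monotone in `k`), and the winner minimizes
`BIC = n log(RSS/n) + p log(n)` with `p = 2 + 2k`. A zero-RSS
interpolation short-circuits selection to the smallest such `k`, flagged.
Fits are made on the smoothed series at slice midpoints, matching how the
curves are drawn and read.

## Ancestral habitats

To ask whether immigrants were pre-adapted to open, treeless habitats, a
two-state (open / closed) continuous-time Markov model is fitted by
maximum likelihood (equal-rates by default, all-rates-different
optionally), with tips scored "both" entered as ambiguous observations
rather than a third state. Marginal node probabilities again come from
combined down/up passes, using the closed-form 2x2 transition
probabilities. For every dispersal event the immediate ancestor's MAP
habitat and probability are reported, called "open" or "closed" only above
a configurable probability threshold (default 0.8, a choice of ours —
reported calls below it are "ambiguous"). This likelihood-based
reconstruction is this package's own estimator of ancestral habitat; it
deliberately involves no MCMC.

## The synthetic-data generator

All inputs can be simulated with known truth, which is how the package
validates itself end to end.

* **Trees**: constant-rate birth–death Gillespie simulation stopped at the
  birth that would create the `n + 1`-th extant lineage, extinct lineages
  pruned; under pure birth the expected crown age is
  `sum_{i=2..n} 1/(i * lambda)`, which the tests check empirically.
  Synthetic node-age HPDs have width proportional to node age (jittered,
  with a floor), emulating divergence-dating uncertainty.
* **Range histories**: forward Gillespie simulation of the DEC process
  along branches (slice-aware) with cladogenetic draws at nodes, logging
  every gain of the focal area. Lineages absorbed into the null range die;
  dead subtrees are pruned by default. The logged "true events" apply the
  event definitions to the true node states, so classification run on the
  truth must reproduce them exactly — the central oracle test.
* **Event ensembles**: an inhomogeneous Poisson process over age with
  either a piecewise-constant intensity or (the default) a
  piecewise-linear intensity interpolating values at fixed break ages.
  Each age is wrapped in an interval of width `0.1 * age` (floor 0.2 Ma),
  placed uniformly around it and clipped at 0; types and source regions
  follow configurable mixtures.
* **Habitat histories**: two-state Markov simulation along branches.

The default scenario emulates the study conditions the package targets: a
multi-clade dataset pooling to about 130 events that originate at 10.24 Ma,
with intensity kinks at 7.2, 2.6 and 0.6 Ma, a roughly 4:1
dispersal-to-in-situ ratio, and a dominant single source region carrying
14/26 of the assignable dispersals.

What the generator does *not* emulate matters for interpreting green
tests: real clades share a correlated dating posterior (here intervals are
independent), real reconstructions carry model misspecification that the
forward-DEC truth does not, and real richness varies across clades far
more than the scenario's identical tip counts. Passing recovery tests
therefore demonstrates the estimators' correctness and calibration under
the model, not robustness to violations of it.

## Numerical and design choices

* Ages are Ma before present, larger = older, everywhere — curves,
  intervals, and breakpoints inherit this orientation.
* Matrix exponentials use a cached eigendecomposition per rate matrix
  (small, dense state spaces), falling back to a Padé method when the
  eigenbasis is ill-conditioned; transition-matrix rows are checked to sum
  to one.
* MAP ties break to the first state in the deterministic state order (by
  size, then lexicographic); the null range is always state one.
* Slice boundaries are strictly decreasing toward the present; a branch
  crossing a boundary is integrated piecewise, and adding a boundary with
  identical multipliers on both sides leaves the likelihood unchanged (a
  tested invariant).
* Every stochastic routine takes an explicit seed, restores the caller's
  RNG state, and records the seed in its outputs; pipeline outputs carry a
  provenance header (version, config hash, seed) and identical
  config + seed reruns are byte-identical.

### Change-point identifiability under overlap counting

One design finding is worth spelling out. Interval-overlap counting makes
neighbouring slices strongly correlated (one event raises every slice its
interval touches, and smoothing spreads it further), so the iid-Gaussian
BIC tends to admit a fourth breakpoint about half the time even when the
expected curve has exactly three kinks; and a piecewise-*constant*
intensity produces a step-shaped curve that a continuous piecewise-linear
model cannot represent at all — its largest step absorbs two breakpoints.
Change points of the event-rate *trend* are therefore well-defined only
when the intensity itself is continuous with slope changes, which is why
the generator's default intensity is piecewise linear, and why the
end-to-end recovery test asserts that the selected fit (k = 3 or 4)
brackets each true kink within 0.5 Ma at high event density, rather than
that BIC lands on exactly k = 3. On directly simulated piecewise-linear
curves with iid noise (sigma = 0.05 over 100 slices), selection does
recover k = 3 with each breakpoint within 0.3 Ma in well over 80% of
replicates — that experiment is part of the test suite.

## Problem sizes used in the tests

The suite validates against brute-force enumeration wherever enumeration
is feasible (DEC and habitat marginals on trees of up to five tips and
three areas, to 1e-8; slice counts on a thousand random fixtures; grid
search for one and two breakpoints), and uses seeded simulation studies at
sizes chosen for stable statistics: 20 replicates of 200-tip trees for DEC
rate recovery (d within a factor of two in at least 80%), 50 replicates
for change-point recovery, 100 datasets x 500 bootstrap replicates at 200
events for peak-CI coverage (required to land in the 90–99% band), and 30
dense ensembles for end-to-end kink recovery. The multi-clade pipeline
test runs three 15-tip clades end to end and checks byte-identical
reruns.

## Limitations

* Plain DEC only: no founder-event speciation, no Bayesian island models,
  and marginal (not joint) ancestral ranges; polytomies are rejected
  rather than resolved.
* Curve features are grid-quantized to 0.1 Ma, and the peak of a flat or
  multi-modal curve is a convention (oldest maximal run), not an estimate.
* The delta-method breakpoint CIs assume iid residuals, which overlap
  counting violates; treat them as optimistic on real MDE curves.
* Habitat reconstruction is binary; "both" tips are ambiguity, not a
  state, and rate heterogeneity across lineages is not modeled.
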
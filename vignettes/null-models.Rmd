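---
title: "Permutation null models for animal social networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation null models for animal social networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socialnull)
```

## The problem

Animal social networks are built from non-independent observations: one
individual's edges are other individuals' edges, and small asymmetries in
how individuals are *sampled* readily masquerade as social structure.
Parametric tests on node-level quantities (weighted degree, strength) are
therefore unreliable in both directions -- they can report structure that is
an artefact of sampling (type I error) and miss structure that sampling has
obscured (type II error). The remedy used throughout this package is the
permutation null model: randomise the aspect of the data that the hypothesis
is about, hold everything else fixed, and locate the observed test statistic
in the resulting null distribution.

The basic routine has four steps: (1) build the social network from the
observed data; (2) compute a test statistic -- for node-level hypotheses we
use the OLS slope of the node quantity on the attribute, because the
coefficient describes the data where t or Z describe departure from a
parametric null; (3) randomise the data and rebuild the network; (4) record
the statistic on the randomised data, repeating (3)-(4) at least 1000 times.
`perm_test()` packages the whole routine behind a formula interface;
`run_null_chain()` is the general engine underneath it.

## P-values

With null statistics $s_1,\dots,s_n$ and observed $s_0$,

* $p_{\mathrm{upper}} = \#\{s_q \ge s_0\}/n$,
  $p_{\mathrm{lower}} = \#\{s_q \le s_0\}/n$ (ties count in both tails,
  which is conservative and keeps $p_{\mathrm{upper}}+p_{\mathrm{lower}}\ge 1$);
* the two-tailed p-value is twice the smaller tail, clamped at 1, so a
  result is significant at $P=0.05$ exactly when fewer than 2.5% of the null
  values exceed the observed value, or more than 97.5% do.

An empty null series is an error; null statistics that come out non-finite
(e.g. a slope on a degenerate permuted network) are recorded as missing,
excluded from the denominator, and counted in `n_missing`.

## The null model families

**Node permutation** (`node_permutation()`): all attribute columns are
jointly reassigned by one uniform permutation of individuals; the network is
untouched. It tests whether attributes map non-randomly onto network
positions, *taking the positions as given* -- so any sampling artefact baked
into the positions is baked into the null too. The restricted variant
(`restricted_node_permutation()`) permutes only within classes (e.g. same
trapping site and season), which holds coarse spatial/temporal structure
fixed while still being a network permutation.

**Edge permutation** (`edge_permutation()`): the multiset of nonzero edge
weights is reassigned uniformly to dyads. Provided for completeness; it
preserves the weight distribution but no individual-level structure.

**Pre-network data-stream permutation** (`datastream_swap()`,
`find_checkerboard()`): the workhorse. A checkerboard -- individuals $i,j$
and events $a,b$ with membership pattern $\begin{smallmatrix}1&0\\0&1
\end{smallmatrix}$ -- is flipped, exchanging single observations between
groups while preserving every group size and every individual's number of
sightings. Swaps can be restricted to events in the same period, day or
location and to individuals of the same phenotype
(`swap_restriction()`), so that home range, effort and phenotype structure
are held constant under the null. Candidates are found by rejection
sampling: an ordered pair of 1-cells is drawn uniformly and accepted if the
complementary cells are 0 and the restrictions hold; since each checkerboard
corresponds to exactly one ordered pair, the accepted swap is uniform among
all legal swaps. The attempt budget (default 10,000 candidate draws per
swap) bounds the search on degenerate data; an exhausted budget leaves the
data unchanged, is counted, and triggers a warning from the chain runner --
the chain never loops silently.

**Focal swap** (`focal_swap()`): the data-stream idea adapted to focal
follows, where a "group" is one focal individual plus its associates. Two
samples with different focals are drawn, one associate from each, and the
associates exchange samples -- only if the two focals and two associates are
four distinct individuals and neither associate already occurs in the other
sample. Per-sample associate counts and per-individual occurrence counts are
conserved exactly. `within_class` restrictions apply to the two focal
individuals (extendable to the associates with `class_scope = "all"`).

**Day shuffle** (`trajectory_day_shuffle()`): for autocorrelated movement
data, each individual's day labels are permuted independently, reallocating
whole daily tracks to days. Space use is preserved exactly per individual;
only temporal alignment between individuals -- hence co-occurrence -- is
randomised. The **track identity swap** (`track_identity_swap()`), in which
each day's tracks are reassigned among individuals, is included as a
contrast method: although it operates on pre-network data, it moves whole
chunks of data between individuals and therefore inherits the blind spots of
a node permutation. The package's tests exhibit exactly this failure.

## Serial chains and mixing

Data-stream and focal permutations are cumulative Markov chains: each
recorded network differs from the previous one by `swaps_per_step` swaps
(default 1), mirroring the incremental procedure in which the null network
drifts progressively away from the observed one. Node, edge, day-shuffle and
identity-swap nulls are independent redraws from the original data.

Serial chains demand care. The chain starts *at the observed data*, so early
recorded statistics are nearly the observed statistic, and a short,
tightly-spaced chain records one slowly wandering excursion -- which is
anti-conservative, because the starting point of a random excursion tends to
sit in its tail. In our own calibration experiments on the baseline group
scenario (no effect, no bias; 200 replicates), recording 200 statistics
every 10 swaps after a burn-in of 1,000 gave a type-I error of 0.28 at
nominal 0.05, while recording every 300 swaps after a burn-in of 30,000 gave
0.04 (node permutation: 0.05). The default `burn_in = 0` therefore exists
only to expose the full trajectory: always inspect
`stabilisation_series()` (running null statistic and running p against
permutation number) and choose `burn_in` and `swaps_per_step` so the
recorded series has stabilised and decorrelated. As a rule of thumb the
chain needs on the order of "number of 1-cells x log(number of 1-cells)"
swaps to forget its starting point. For *power* against a strong effect this
matters much less: the headline biased-scenario analyses below use a
burn-in of 1,000 and 2 swaps per recorded statistic and detect the effect
essentially always.

## The synthetic scenarios

The generators exist so that every null model can be exercised, and the
package's statistical claims verified, without field data. They emulate one
biological situation in three observation modes: *females truly have
stronger social bonds than males, and an observation bias then removes a
fraction (default 20%) of female records* -- females are present but
unrecorded. Under that bias the apparent sex difference in the observed
network vanishes, a naive regression and a node permutation find nothing,
and only nulls that carry the observation structure (data-stream, focal
swap, day shuffle) recover the true effect.

**Group scenario** (`simulate_group_data()`). Each of `n_events` (default
200) sampling events has a uniformly drawn seed individual among
`n_individuals` (default 50, half female). Males join any event with
probability `p_base` (default 0.15). Females *concentrate* the same total
sociality on female company: they join female-seeded events with probability
`p_base (1 + e)` and male-seeded events with probability `p_base (1 - e)`,
with `e = female_sociality_effect` in [0, 1] (default 0.4). Two properties
of this design are load-bearing:

* *Margins are sex-symmetric.* Both sexes are observed equally often in
  expectation; females have stronger bonds, not more sightings. Female-female
  dyads co-occur in excess of what the margins predict (by a factor
  $1 + e^2$), which is what gives a margin-preserving null something to
  detect. A mechanism in which females simply join more events would put the
  entire effect into the margins, and a fixed-margin (checkerboard) null
  would -- correctly but uselessly -- see such data as perfectly typical: an
  independent-joining matrix with column-wise rates, conditioned on row and
  column sums, is uniform on the fixed-margin space.
* *At `e = 0` the model is exchangeable.* The baseline scenario used for
  type-I calibration is exactly the null model's own world.

The default `e = 0.4` was fixed by calibrating the generator against the
scenario's two defining conditions: with the full data the female effect is
unambiguous (higher female strength in essentially all replicates), and
after the 20% bias the observed data look sex-neutral (the observed slope
averages about +0.1 on the male dummy, and naive OLS and node permutations
are non-significant in most replicates), while the data-stream null -- whose
fixed margins still expect males to come out ahead, females having lost 20%
of their records -- stabilises around +0.4 to +0.7 and exposes the effect at
P < 0.01.

**Focal scenario** (`simulate_focal_data()`). The same homophily model with
the focal individual as the seed: focals rotate through the population in
shuffled order, associates join with the probabilities above, and the bias
deletes female *associate* records (the follow itself happened, so focal
records stay). Converting the samples with `focal_to_gbi()` reproduces the
group-scenario structure; `focal_swap()` is the matching null.

**GPS scenario** (`simulate_gps_data()`). Individuals walk on a discrete
grid arena, one Moore-neighbourhood step at a time (staying put allowed,
boundaries clip). Males move uniformly; females weight neighbouring cells
that held at least one conspecific at the previous step by
`attraction_multiplier` (default 5 -- five times more likely to move toward
company than to an empty cell). Updates are simultaneous against
previous-step occupancy, avoiding update-order artefacts. The bias deletes
female (day, step) points, leaving `NA`s. Co-occurrence is same cell, same
step (the minimal rule on a grid world; `trajectories_to_gbi()` exposes a
Chebyshev radius for coarser matching).

Arena defaults (5 x 5 cells, 30 individuals, 20 days x 15 steps) are denser
than they may look: a cell is a home-range-sized block, not a GPS fix. The
density was calibrated, once, against the same two conditions as above: the
attraction effect must be real but *moderate* (roughly a 15-25% female
strength excess with full data), so that the 20% deletion masks it in the
observed network. On a sparse arena, encounters are rare and attraction
makes females stick together almost permanently -- an effect so large that
even a mis-specified null detects it, and the methodological contrast the
scenario exists to display (day shuffle detects; identity swap, behaving
like a node permutation, does not) cannot occur.

What the generators deliberately do not emulate: individual heterogeneity
beyond sex (gregariousness, observability), temporal drift in sociality,
group-size-dependent detection, spatial structure in the group scenario, or
fission-fusion dynamics with memory. Passing tests on these scenarios show
that the machinery is correct and that the methods behave as advertised
under the stated mechanism -- not that any particular field dataset
satisfies that mechanism.

## Dyadic regression (QAP / MRQAP)

`mrqap()` fits ordinary least squares over unordered dyads (the upper
triangle -- all networks here are symmetric, so using each dyad once avoids
double-counting). Estimation is identical across methods; only the null
distribution differs:

* **QAP-y**: node-permute the dependent network (simultaneous row/column
  permutation), refit, record each slope.
* **DSP** (double semi-partialing): residualise each predictor on the other
  predictors by dyadic OLS, fold the residuals back into a symmetric matrix,
  node-permute it, substitute it into the design and record the refitted
  coefficient. With one predictor this is statistically equivalent to QAP-y
  (and the tests check that the two agree within Monte-Carlo error).
* **Custom null** (`mrqap_custom_null()`): the null coefficients come from
  refitting the model against an externally supplied series of null
  dependent networks -- typically `null_network_series()`, which harvests a
  data-stream chain. This is how a margin-respecting null is injected into a
  dyadic regression.

Sex-category predictors (`dyad_category_matrix()`; 1 = both males,
2 = mixed, 3 = both females) enter as a single numeric axis, mirroring a
one-coefficient similarity test. On the biased group scenario the standard
QAP/DSP tests find nothing, while against data-stream nulls the observed
sex-category slope is more extreme than 95%+ of the null slopes -- on the
side where female-female dyads are stronger than the fixed margins predict,
i.e. the upper tail of this coding (reversing the category order flips the
tail but not the substance).

## Numerical choices and degenerate inputs

* *SRI*: a never-observed dyad (0/0) has index 0. Because each matrix row is
  one sighting event, the "seen but not together" correction terms of more
  general association indices are identically zero here. Raw co-occurrence
  counts are available via `co_occurrence_network()` / `index = "count"`.
* *Median threshold* (`threshold_at_median()`): the median is taken over
  nonzero edge weights and edges strictly above it are kept, so "the top
  50% of edges remain" has a defined tie rule -- an all-equal network loses
  every edge. An all-zero network is an error.
* *Slope on a constant predictor* is undefined (`NA`), which the chain
  runner converts to a missing null statistic; a constant *response* gives
  slope 0.
* *Binary attribute coding*: alphabetically first level is the reference
  (F = 0, M = 1 for sex), so the reported slope is the second level's mean
  difference.
* *Tie handling in p-values*: ties count in both tails; doubling is clamped
  at 1.
* *Reproducibility*: every stochastic entry point takes a `seed`; a given
  seed reproduces results bit for bit. All draws come from R's global RNG.
* *Stuck chains*: a swap that finds no legal move within the attempt budget
  leaves the data unchanged, is counted (`n_failed_swaps` in spirit --
  reported via a warning with the count), and the statistic is still
  recorded, so degenerate data yield flat null series rather than hangs.

## Problem sizes used by the tests

The shipped test-suite and acceptance script run, among smaller unit
checks: 20 replicates of the biased group scenario at its defaults with
1,000-permutation chains; 200 replicates of the baseline scenario at 200
recorded permutations (300 swaps apart after a 30,000-swap burn-in); 100
random matrices against a brute-force index oracle; 10,000-swap conservation
checks; and 20 replicates of the GPS scenario with 1,000-permutation
day-shuffle and identity-swap nulls. These sizes were chosen so the full
suite completes in minutes on one core while keeping every Monte-Carlo
assertion far from its decision boundary.

## Known limitations

* Serial-chain p-values are approximate for finite chains even after
  burn-in; the stabilisation diagnostics are guidance, not proof of mixing.
  Exact uniform sampling of fixed-margin binary matrices (curveball-style
  algorithms) is out of scope.
* The checkerboard sampler is uniform among *legal* swaps but, like all
  swap chains, explores the restricted fixed-margin space only if that
  space is connected under single swaps; heavy restrictions can fragment
  it, which shows up as failed-swap warnings and flat stabilisation traces.
* Only undirected, non-negative networks are supported; interaction
  (directed) data, half-weight-style indices, centrality metrics beyond
  degree/strength, and ERGM-style model fitting are out of scope.
* The OLS slope is the only node-level statistic with a formula interface;
  arbitrary statistics are available through `run_null_chain()`.
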
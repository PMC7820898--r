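---
title: "From single-cell expression time series to Waddington landscape Petri nets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From single-cell expression time series to Waddington landscape Petri nets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmonet)
```

## The problem and the data design

Most single-cell expression studies sacrifice each cell at measurement, so
temporal orderings must be inferred in pseudo-time from population
snapshots, under assumptions (unidirectionality, history independence) that
the inference itself cannot check. Giant multinucleate plasmodia of
*Physarum polycephalum* escape this limit: their vigorously mixed cytoplasm
makes the cell a homogeneous reaction volume, so small samples taken
repeatedly from one plasmodium form a true time series of that single cell.
The design this package models: a 35-gene panel (10 up-regulated, 10
down-regulated, 4 "pcnA-group" genes that wander independently of the
stimulus, and 11 reference genes), 24 cells observed at 11 hourly time
points, with two biological samples per cell and time point and each sample
measured twice by multiplex RT-PCR — four values per gene, cell and time
point. Cells are either stimulated with a far-red light pulse (which
triggers commitment to sporulation) or kept as dark controls, in two
experiment batches.

## Pipeline

**Normalization.** Within every single measurement the values of the gene
panel are divided by their median (correcting RNA amount and RT-PCR
efficiency); each gene is then divided by the geometric mean of all its
retained values, computed in log space. The order — sample-median first,
gene-geometric-mean second — is fixed. For even gene counts the median is
the mean of the two central order statistics (R's convention).

**Replicate QC.** The x-fold deviation of a measurement from the arithmetic
mean of its replicate group (`r = value / mean(group)`; for a pair
`r1 + r2 = 2` exactly) is summarized as a quantile table in log2 and fold
units (fold = `2^log2`, so the two columns are always consistent).
Measurements failing the two-fold rule (`r` outside `[1/2, 2]`) have their
replicate group removed — a discordant pair identifies no culprit, so the
narrowest defensible unit of removal is the pair itself, not the whole
measurement. A plasmodium is excluded wholesale when one of its samples
disagrees with its sibling sample taken at the same time point by more than
two-fold (median over genes of the ratio of the sample's replicate means to
the per-gene cross-sample median). Comparing siblings *within* a time point
is deliberate: across time points genuine regulation spans ten to more than
a hundred fold, which would swamp any sample-handling artifact the rule is
meant to catch. Surviving replicates are averaged to one value per gene,
cell and time point; where a removed pair leaves a gene with no value at
all at one cell-time point, the pipeline falls back to the unfiltered mean
there, so the expression matrix (and hence every trajectory) stays complete
— the replicate rule shapes the QC statistics, not the completeness of the
design.

**Discretization by SIMPROF.** Cell-time point profiles are clustered
hierarchically (average linkage, Euclidean distance on log10 values) and
the dendrogram is pruned top-down by the similarity-profile permutation
test: at each node the sorted pairwise distances of the group are compared
with their rank-wise expectation under independent permutation of each
gene across the group's rows; the statistic is the L1 distance between
observed and expected profile, and the p-value the fraction of freshly
permuted profiles at least as extreme. Nodes with p above alpha become
terminal clusters — the significant expression states. Defaults: alpha
0.05, 999 + 999 permutations (reduced in some examples and drivers for
speed), all exposed because none of them is fixed by the science. Cluster
IDs are assigned by dendrogram leaf order of each terminal cluster's first
leaf, making runs reproducible; IDs are labels, nothing more.

**Trajectories and the net.** Ordering each cell's states by time gives its
trajectory. The state machine is then purely mechanical: one place per
distinct state, one transition per distinct ordered pair of consecutive
*differing* states, arc weights 1. Consecutive identical states are
self-transits: they create no transition and contribute only to residence
time (any other convention would change the transition count, and the
residence times, for no modeling gain). An auxiliary place C0 holds the
single token initially and feeds each observed initial state through an
immediate transition weighted by the number of cells starting there. Since
every transition has exactly one pre- and one post-place, the token is
conserved, and the single-token net is isomorphic to its reachability graph
— it *is* the Markov chain of expression states. Feasible developmental
paths are exactly the token walks (`accepts()`, `simulate_token_game()`).

**T-invariants.** In a state machine the minimal T-invariants are exactly
the elementary directed cycles of the place/transit graph. They are
enumerated by backtracking restricted to nontrivial strongly connected
components, rooted at each component's smallest place so that every cycle
appears once in canonical rotation; the enumeration is capped (default
10^6) because cycle counts can grow combinatorially in denser nets built
from gene subsets. The enumerator is validated in the test suite against an
independent brute-force oracle on digraphs of up to 12 places.

**Annotations and visual analytics.** Places carry relative frequency
(occurrences over all cell-time points) and relative temporal stability:
mean maximal-run length in sampling intervals, normalized by the maximum
over states. Runs truncated by the start or end of a series count at their
observed length; with 11 time points any censoring correction would be
noisier than the bias it removes. Transitions carry occurrence counts and
the set of (experiment, condition) labels of the cells showing the transit.
Classical MDS (Torgerson scaling via `cmdscale`) embeds the profiles with
percent variance per coordinate (eigenvalue over the sum of positive
eigenvalues; negative eigenvalues are dropped from the denominator, the
classical convention); each coordinate's largest-magnitude loading is made
positive so output is deterministic. Kinetics curves plot, per cell and
gene, `log10` of the occupied state's cluster profile relative to the
profile at t = 0, so every curve starts at zero and is stepwise constant
within residence runs. Distances default to log10-transformed values for
both clustering and MDS, consistent with the log10 heatmap view of the
cluster profiles; a linear mode is exposed.

## The synthetic-data generator

Because no raw data ship with the package, a generator reproduces the
statistical structure the analysis assumes: a ground-truth Markov chain of
states (connected from its initial states; self-stays are probabilities,
not edges; `cycle_fraction = 0` gives an acyclic chain by construction),
per-state expression profiles, and a replicated measurement layer. Profiles
draw a log-uniform baseline and a fold span between 10 and 100 per gene —
the span of genuine differential regulation; up/down genes drift
monotonically along the state progression under far-red and stay flat in
the dark, pcnA-group genes perform a condition-independent random walk, and
reference genes only jitter. Measurement noise is multiplicative:
`2^N(0, sigma_bio)` per biological sample (default 0.1 log2 units) and
`2^N(0, sigma_tech)` per technical replicate. `sigma_tech = 0.43` is
calibrated so that the analytic 95th percentile of the pair fold deviation,
`r_q = 2 / (1 + 2^(-z_q * sigma * sqrt(2)))`, equals 1.333 — the value the
technical replicates of the real measurements show; the 5th percentile then
lands at 0.667, within the measured 0.663–0.681 band. An optional
failed-RT-PCR mode (probability 0.01 of a replicate dropping to 0.1 of its
expected value) emulates the low tail of real deviation histograms and is
off in calibration runs. All randomness flows through one explicit seed per
operation with the global RNG state restored afterwards.

What the generator does *not* emulate: batch effects between experiments,
gene-gene correlation beyond the shared state profile, amplification
efficiency differences, or nucleus-level heterogeneity (the plasmodium is
treated as homogeneous, as the measurements justify). Passing tests on
synthetic data therefore demonstrate the correctness of the pipeline's
logic and calibration, not the biological fidelity of any particular
clustering of real measurements.

## Numerical and design choices

* Geometric means are computed in log space; non-positive values are data
  errors (an optional detection floor can clamp instead).
* Even-count medians follow R's mean-of-central-pair convention.
* The QC pair rule removes the pair, not the single value, on the narrowest
  reading of replicate discordance.
* Permutation p-values are the plain fraction of null statistics at least
  as large as the observed one; all-identical rows give statistic 0 and
  p = 1 by convention. Groups of two rows can never be split: a Euclidean
  distance between two rows is invariant under within-column swaps, so
  their similarity profile carries no evidence. This matters at this
  package's operating point — the reference study discretized 264 profiles
  into 111 states, i.e. typical cluster sizes of 2–3 — and it is why the
  planted-cluster recovery checks in the test suite use clusters of that
  size. For large homogeneous groups the per-node test spends its full
  alpha, so recovering k well-separated blobs *exactly* succeeds with
  probability near `(1 - alpha)^k`; with small groups the test's
  discreteness makes splits rarer and exact recovery correspondingly more
  reliable.
* Cycle enumeration is deterministic: canonical rotation (smallest place
  first), results sorted by length then place sequence.
* ANDL export uses a compact documented dialect (`inst/ANDL-grammar.md`)
  that round-trips through the package's own reader; DOT export replaces
  interactive color editing by plain node attributes (frequency, stability,
  provenance).
* Problem sizes in the drivers and tests (e.g. 20-state chains, 24 cells,
  11 time points; 12-cell zero-noise closure runs; 99–199 permutations in
  the faster paths) are chosen to exercise every stage at the study's scale
  while keeping each driver in the seconds-to-minutes range.

## Known limitations

The clustering distance, linkage, transform and alpha behind the reference
trajectory table are not recorded with it; the defaults here are
reasonable, exposed, and flagged as choices — cluster IDs are treated as
opaque labels and never matched numerically, only the structure of the
resulting net is compared. Gene-subset nets can be built, but their
reference metrics depend on re-clustering raw data that are not packaged,
so they are reproduced structurally, not numerically. History dependence (colored nets) and regulatory-network
inference from the reachability graph are out of scope.

## A minimal run

```{r}
tab <- trajectory_fixture()
net <- residence_stability(build_net(tab), tab)
s <- net_summary(net, n_genes = 35, n_timepoints = 11, n_cells = 24)
c(places = s$n_places, transitions = s$n_transitions,
  t_invariants = s$n_t_invariants, components = s$n_components)
s$rounded$t_per_p
graph_analysis(net)$sinks
simulate_token_game(net, 30, seed = 5, policy = "weighted")
```
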
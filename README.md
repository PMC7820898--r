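# plasmonet

State-machine Petri nets ("Waddington landscape" nets) from true
single-cell gene-expression time series.

Giant multinucleate plasmodia of *Physarum polycephalum* can be sampled
repeatedly without killing the cell, so the expression of a gene panel can
be followed in one and the same cell over real time — no pseudo-time
inference, no unidirectionality assumption. `plasmonet` implements the full
route from such multi-replicate measurements to a discrete dynamic model:

1. **Normalization & QC** — per-measurement median normalization, per-gene
   geometric-mean normalization, x-fold replicate-deviation statistics
   (`r = value / mean(replicate group)`; quantile tables in log2 and fold
   units), a two-fold replicate rule and a plasmodium-exclusion rule.
2. **Discretization** — hierarchical clustering with SIMPROF
   similarity-profile permutation testing; terminal unsplit nodes are the
   significant gene-expression states; per-state geometric-mean profiles.
3. **Trajectories** — per-cell ordered state sequences (TSV round-trip; a
   transcribed 24-cell × 11-time-point table ships as a fixture).
4. **Petri net** — one place per state, one transition per observed transit
   (exactly one pre- and one post-place, arc weights 1, single conserved
   token, auxiliary start place C0 with immediate transitions). The
   single-token net is isomorphic to its reachability graph: it *is* the
   Markov chain of expression states. Analyses: sources/sinks/components,
   relative state frequency and temporal stability, minimal T-invariants
   (= elementary directed cycles, enumerated with an SCC-restricted
   backtracking algorithm), token-game simulation, ANDL and DOT export,
   summary metrics (P/Gene, T/Gene, T/P, ...).
5. **Visual analytics** — classical MDS with percent variance per
   coordinate; discretized kinetics curves
   `log10(profile[s(t), g] / profile[s(0), g])`.
6. **Synthetic data** — a calibrated generator (ground-truth Markov chain,
   per-state profiles, 2 samples × 2 replicates, multiplicative log2
   noise with `sigma_tech = 0.43` so the 95th percentile of the pair fold
   deviation is 1.333) makes the whole pipeline testable end to end.

## Worked example

```r
library(plasmonet)

tab <- trajectory_fixture()                      # 24 cells x 11 hourly states
net <- residence_stability(build_net(tab), tab)
s   <- net_summary(net, n_genes = 35, n_timepoints = 11, n_cells = 24)

s$n_places          # 111  distinct expression states (places, excl. C0)
s$n_transitions     # 159  distinct observed transits
s$rounded$t_per_p   # 1.43 transitions per place
s$n_t_invariants    # 7    minimal T-invariants (elementary cycles)

graph_analysis(net)$sinks
# 1  30  61  71  76  77  78  79  95     <- terminal expression states;
#    {71, 76, 77, 78, 79, 95} are the ones reached by far-red cells

dark <- tab[tab$condition == "dark", ]
graph_analysis(build_net(dark))$n_weak_components
# 3   <- unstimulated cells wander in three disconnected sub-landscapes

simulate_token_game(net, 30, seed = 5, policy = "weighted")
# 24 38 45 42 43 21  7  6  1   <- one feasible developmental path
```

The numbers mean: the 264 measured cell-time points discretize into 111
significantly different expression states linked by 159 observed
reprogramming steps; the few elementary cycles show that cells can revisit
states (the landscape is not a tree), and the far-red stimulus funnels all
stimulated cells into a small set of terminal states.

An analysis version of the same workflow lives under `analysis/`
(`01_simulate.R` … `05_ordination_kinetics.R`): numbered drivers that
generate a synthetic data set with the study's design, preprocess and
cluster it, rebuild the nets (fixture and synthetic) and write all tables
under `results/`.

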
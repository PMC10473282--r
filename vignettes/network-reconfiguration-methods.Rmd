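---
title: "Methods: quantifying functional-connectome reconfiguration across cognitive states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying functional-connectome reconfiguration across cognitive states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(netreconfig)
```

This vignette documents the models, parameter choices, and numerical
decisions behind `netreconfig`, in the spirit of a methods section: what
each stage computes, why the defaults are what they are, and what the
package's passing tests do and do not demonstrate about real data.

## The analysis problem

The pipeline takes per-subject, per-state ROI time-series matrices (rows =
time points, columns = nodes) from several cognitive states — canonically
rest, an easy working-memory task (1-back), and a hard one (2-back) — plus
an a-priori node-to-module table, and asks two families of questions:

1. **Aggregate (static FC).** How similar are the edge-weight patterns
   between states, and how do global topology (small-worldness, clustering,
   efficiency, betweenness, modularity) and per-module segregation change
   with cognitive load?
2. **Time-resolved (dynamic FC).** Within each state, how volatile is the
   modular organization over sliding windows — the SD and speed of the
   dynamic modular segregation index — and how similar are the allegiance
   matrices between states?

A third ingredient, the drift-diffusion decomposition of two-choice
behavior, supplies latent cognitive variables (drift rate `v`, boundary
separation `a`, nondecision time `Ter`) so that network reconfiguration can
be correlated with specific cognitive processes rather than raw accuracy or
reaction time.

## Connectivity construction

Node time series are band-pass filtered with a second-order Butterworth
design applied forward and backward (`signal::filtfilt`), giving zero phase
shift so window boundaries are not displaced; edges are mitigated with
reflective padding. The default band is 0.008–0.25 Hz. At a 2-s sampling
interval the upper edge coincides with the Nyquist frequency, where a
band-pass design is ill-posed; `bandpass()` then degrades to the high-pass
component alone, which is the only part of the band that bites.

Static FC is the Fisher-z transform of pairwise Pearson correlation.
Correlations are clipped at `|r| = 1 - 1e-7` before `atanh`, so duplicated
columns produce a large finite weight (about 8.4) instead of `Inf`; this
keeps downstream ranking and thresholding well defined. Dynamic FC uses
rectangular windows anchored at state onset, advancing by a fixed step
(defaults 40 s / 20 s); the window count is
`floor((T*dt - length)/step) + 1`, so a 300-s state yields 14 windows. No
taper is applied — the windowing is deliberately the plainest version of
the sliding-window estimator.

Between-state similarity (for both FC and allegiance matrices) is the
Pearson correlation of the strictly-upper-triangle vectorizations. The
diagonal is excluded because it is constant by construction (0 for FC, 1
for allegiance) and would only inflate the correlation.

## Thresholding and graph topology

Binary graphs keep the strongest positive Fisher-z edges up to a target
density (default 20 % of node pairs), on top of a maximum-weight spanning
tree backbone — computed as the minimum spanning tree of
`max(weight) - weight` — which guarantees a connected graph at any density
at or above the tree floor of `N - 1` edges. Ties in edge ranking are
broken lexicographically by node ids so the operation is deterministic.
Negative edges never compete for inclusion, and are truncated to zero in
all modularity computations: modular analyses here take only positive
coupling into account, and mixing signed nulls into Q would change its
meaning silently.

Topology metrics on the binarized graph are the mean Watts–Strogatz nodal
clustering coefficient (nodes of degree < 2 score 0), global efficiency
(mean inverse shortest-path length over pairs), and mean unnormalized
betweenness centrality. Small-worldness is
`sigma = (C/<C_null>)/(L/<L_null>)` with 100 degree-preserving
double-edge-swap null networks by default (10·|E| swaps each, resampled
until connected). Two of these choices are genuinely open — the null-model
recipe for sigma and whether betweenness is averaged or summed — and are
therefore explicit, documented defaults rather than hidden constants.

Modularity Q is computed on the weighted (negative-truncated) FC matrix,
not the binarized graph, with the configuration null and resolution
`gamma = 1`:

```
Q = (1/2m) * sum_ij [A_ij - gamma * k_i k_j/(2m)] * delta(c_i, c_j)
```

Maximization uses a Louvain implementation written for this package
(`src/louvain.cpp`): greedy local moving over a dense modularity matrix
followed by community aggregation, iterated to a local maximum, restarted
(default 100 times) from seeded random node orders, keeping the best Q. A
dense-matrix engine was chosen because exactly the same code then serves
the temporal multilayer case (below) by feeding it the supra-modularity
matrix; the `omega = 0` reduction contract between the two modes is exact
by construction. Within a sweep, the candidate community with the largest
gain is accepted, ties going to the lowest community index; node visiting
order is the only randomized element, which keeps single runs reproducible
under a seed while restarts still explore the landscape. On graphs small
enough for exhaustive enumeration over all partitions, 100 restarts attain
the global maximum in ≥ 95 % of random graphs (verified in the test suite).

## Modular segregation

For a module with `E_intra` within-module edges and `E_inter` edges to the
rest of the network, `MSI = (E_intra - E_inter)/E_intra`. MSI is 1 for a
module with no external edges and negative when external edges outnumber
internal ones — the signature of functional integration. With 14 a-priori
modules, the cerebellar (`CER`) and uncertain (`UNC`) labels are excluded
from scoring by default, but their nodes still count toward the `E_inter`
of analyzed modules; exclusion changes which modules are reported, not the
graph. When `E_intra = 0` the index is undefined; the default policy
returns `NA` with a logged message (a hard error is available), because
legitimately sparse modules at low densities should surface as missing
values in the statistics, not abort an entire run.

The dynamic trajectory (dMSI) applies the same index to each window,
binarized at the same density as the static graphs — the natural default
in the absence of a stated alternative, and exposed as a parameter with a
sweep in `run_sensitivity()`. The trajectory is summarized by its sample
(n−1) standard deviation (fluctuation extent) and by its speed, the mean
absolute first difference. A constant trajectory has SD = speed = 0, and a
windowed series whose windows are identical reproduces the static MSI
exactly.

## Multilayer communities, allegiance, consensus

Temporal multilayer detection couples each node to its own copies in
adjacent windows with coupling `omega` (ordinal coupling; all-to-all
coupling is out of scope). The supra-modularity matrix holds each layer's
configuration-null term on the diagonal blocks and `omega` on the
adjacent-layer identity blocks, normalized by
`2*mu = sum_s 2m_s + 2*omega*N*(w-1)`. Generalized Louvain runs on this
matrix; each repetition yields one partition spanning all windows, and the
allegiance matrix `P_ij` counts the fraction of (repetition, window) layers
in which two nodes share a community — exact rationals with denominator
`r*w`, which the tests verify by recounting the stored ensemble.

`omega = 0` is implemented as the degenerate per-window mode: each layer is
clustered independently with the single-layer engine under a shared seed
schedule, so the reduction to per-window Louvain is exact rather than
approximate. Whether coupled (`omega > 0`) or per-window detection better
matches any given study is not decidable in general, so `omega` is a
documented sensitivity knob with default 1.

The window-information trade-off matters here and is easy to miss: with
20-sample windows (40 s at dt = 2 s) and a planted 6-module structure at
within/between correlations 0.5/0.05, single windows are too noisy for
per-window detection — the modularity optimum itself merges modules — and
uncoupled detection recovers the truth poorly. Stronger coupling
(`omega ≈ 5`) pools evidence across layers and restores perfect recovery,
as does lengthening windows to ≥ 60 samples. The planted-recovery tests
therefore use 80-sample windows for the `omega = 1` contract and keep a
separate test demonstrating the coupling rescue at 20-sample windows. For
real data the implication is that per-window community assignments at
40-s windows should not be over-interpreted node by node; the allegiance
average over repetitions and windows is the more stable object.

Consensus clustering re-clusters a thresholded agreement matrix (default
`tau = 0.5`) with seeded restarts until all restarts agree up to label
permutation or `max_iter = 20` is reached (non-convergence is flagged, and
the modal partition returned). It is provided as the validation-path
alternative to plain modularity maximization.

## Behavior: simulation and EZ estimation

Two-choice behavior is modeled as a Wiener diffusion with unit diffusion
coefficient: evidence starts at `z*a` (default unbiased, `z = 0.5`) and
drifts at `v` toward absorbing bounds at 0 and `a`; response time is first
passage plus `Ter`. The simulator uses an Euler–Maruyama scheme (default
`dt_sim = 1 ms`) with a Brownian-bridge correction for within-step boundary
crossings (`P(cross) = exp(-2 d0 d1/dt)` for endpoint distances `d0`,
`d1`); without the correction the plain Euler scheme overestimates
accuracy by about 0.005 at `v = 2, a = 1`, a visible bias at
10,000 trials. Simulated accuracy matches the closed form
`P(upper) = (1 - e^{-2vza})/(1 - e^{-2va})` within Monte-Carlo error.

Estimation inverts the EZ-diffusion closed forms — accuracy, and the mean
and variance of correct-trial RTs, mapped to `(v, a, Ter)` — with the
standard 1/(2n) edge correction when accuracy is exactly 0, 0.5, or 1.
EZ assumes an unbiased start and no inter-trial parameter variability,
which is exactly what the simulator generates, so simulate-then-fit
recovery is a clean test of the inversion (relative errors < 5 % at
10,000 trials, shrinking with n). Hierarchical Bayesian or full
first-passage-likelihood fitting is deliberately out of scope: the
closed-form estimator is deterministic, fast, and sufficient for the
parameter-level contrasts this pipeline feeds into statistics. This is a
methodological choice, and fits of real data with strong starting-point
bias or RT contaminants would need a richer estimator.

## Statistics

The inferential layer mirrors a standard within-subject design: one-way
repeated-measures ANOVA per measure (`F = MS_state/MS_error`,
`df = (k-1), (k-1)(n-1)`, partial eta squared), post hoc two-sided paired
t tests with Cohen's `d = mean(diff)/sd(diff)` following significant main
effects, and Benjamini–Hochberg FDR applied within declared families —
global topology, modular MSI, dMSI SD, and dMSI speed are separate
families, matching how the measures are reported. Brain–behavior Pearson
correlations are exploratory and reported uncorrected, flagged as such.
No sphericity correction is applied by default (the plain df convention);
Greenhouse–Geisser is available behind `gg = TRUE`. With two states the
ANOVA reduces exactly to the squared paired t, which the tests assert.

Head-motion validation regresses mean framewise displacement out of both
the network measure and the behavioral score before correlating
(for similarity measures: the FD of both states plus their interaction).
In the paired-contrast setting of `run_sensitivity()`, FD is removed
slope-only (the state mean is kept), because per-state demeaning would
erase the very state effect under test. On FD-confounded synthetic pairs
the partial correlation collapses to the planted zero while the plain
correlation stays inflated; on unconfounded cohorts conclusions are
unchanged with or without regression.

## The synthetic cohort: what it emulates and what it does not

The generator draws multivariate-normal time series with
exchangeable-within-block covariance: within-module correlation `rho_in`
(default 0.45), between-module correlation `rho_base + integration[state]`
(defaults 0.05 + 0/0.075/0.15 for rest/1-back/2-back — integration
increasing with load), observation noise `sigma = 0.3` (attenuating
observed correlations by `1/(1+sigma^2)`), and per-subject jitter
(SD 0.02) on both correlation levels. The default test geometry is 60
nodes in 6 equal modules, 150 samples at dt = 2 s — chosen so the default
windows give exactly 14 layers per state; 286 nodes and the 14-module
labelling (SOMH … CER, UNC) are supported. Infeasible correlation
combinations are rejected; near-singular covariances are repaired by an
eigenvalue floor at 1e-8 with renormalization to unit diagonal, and every
repair is logged. All generators are pure functions of (configuration,
seed).

Dynamic reorganization is planted by `generate_switching_cohort()`: within
each window-aligned segment, a fixed eligible fraction of nodes (default
50 %) independently adopts another module with probability `switch_rate`
in the generating covariance. The per-segment memberships are recorded in
the ground truth, and the recorded bookkeeping is verified against the
covariances actually used. dMSI SD and speed increase monotonically in
`switch_rate`, which is the planted signature the dynamic tests detect.

What the passing tests show: the estimators implement their definitions
exactly (oracle tests), the planted effects are recovered in the planted
direction with the expected statistics (power tests), and the pipeline is
deterministic given a seed. What they do not show: robustness to
hemodynamic convolution, autocorrelated noise, motion artifacts beyond a
scalar FD covariate, spatial structure, or non-Gaussian heavy tails —
none of which the Gaussian block model emulates. Conclusions about real
fMRI data still require the usual empirical controls; the synthetic cohort
certifies the machinery, not the physiology.

## Problem sizes and defaults used in verification

The shipped tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which each property is comfortably away from its
detection threshold: 60-node cohorts; 50 subjects × 50 seeds (tests) or
20 seeds (script) for the load-integration detection rate; 20 subjects for
the switching contrast; 100 random ≤ 8-node graphs for the
exhaustive-modularity oracle; 10,000 trials for diffusion recovery; 2,000
replicates for the calibration checks. Reference-scale settings (286
nodes, 100 Louvain restarts, 100 multilayer repetitions, 100 sigma nulls)
are the package defaults for real analyses.
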
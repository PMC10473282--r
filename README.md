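# netreconfig

Static and dynamic functional-connectome reconfiguration analysis in R.

## What this package is for

When people move between cognitive states — rest, an easy working-memory
task, a hard one — their whole-brain functional network keeps most of its
architecture but reconfigures subtly: edge weights shift, modules integrate
or segregate, and the time-resolved modular structure becomes more or less
volatile. `netreconfig` implements an end-to-end pipeline for quantifying
those reconfigurations from region-of-interest (ROI) time series and for
relating them to latent cognitive processes estimated from two-choice
behavior. It is aimed at researchers analysing task/rest fMRI ROI data and
at methodologists who want a fully testable reference implementation: a
synthetic-cohort generator with planted ground truth makes every stage
verifiable without any imaging data.

The pipeline covers:

* **Connectivity.** Band-pass filtering (zero-phase Butterworth), static
  functional connectivity `z = atanh(r)` from pairwise Pearson correlation,
  sliding-window dynamic FC (default 40-s windows, 20-s steps), and
  between-state edge-weight similarity (Pearson r over vectorized upper
  triangles).
* **Graph topology.** Density thresholding backed by a maximum-weight
  spanning tree (connectedness guaranteed), mean clustering coefficient,
  global efficiency `E = <1/d(i,j)>`, betweenness centrality,
  small-worldness `sigma = (C/C_null)/(L/L_null)` against degree-preserving
  rewired nulls, and weighted modularity

  `Q = (1/2m) * sum_ij [A_ij - gamma * k_i k_j / (2m)] * delta(c_i, c_j)`

  maximized by a Louvain implementation (C++ core) restarted to find the
  maximal Q.
* **Modular segregation.** Per-module `MSI = (E_intra - E_inter)/E_intra`
  on static graphs, and its dynamic trajectory (dMSI) over windows,
  summarized by SD (fluctuation extent) and speed (mean |first
  difference|). Negative MSI means a module is more integrated than
  segregated.
* **Community dynamics.** Temporal multilayer community detection
  (generalized Louvain with ordinal interlayer coupling `omega`), the
  allegiance matrix `P_ij` = fraction of (repetition x window) layers in
  which nodes i and j share a module, allegiance similarity between states,
  and consensus clustering over partition ensembles.
* **Behavior.** A Wiener diffusion simulator (Brownian-bridge-corrected
  Euler scheme) and closed-form EZ-diffusion estimation of drift rate `v`,
  boundary separation `a`, and nondecision time `Ter` per subject and
  state.
* **Statistics.** One-way repeated-measures ANOVA (`F = MS_state/MS_error`,
  partial eta squared), post hoc paired t with Cohen's d,
  Benjamini-Hochberg FDR within declared measure families, and
  brain-behavior correlations with optional mean-FD residualization.

## Worked example

Generate a synthetic 12-subject cohort with integration increasing from
rest to 2-back, simulate behavior, and run the pipeline:

```r
library(netreconfig)

co  <- generate_cohort(n_subjects = 12, n_nodes = 60, n_timepoints = 150,
                       dt = 2, scenario = nr_scenario(6), seed = 7)
beh <- generate_behavior(12, n_trials = 200, seed = 8)
cfg <- run_config(seed = 9, q_repetitions = 20, ml_repetitions = 5,
                  n_null = 20)
res <- run_pipeline(co, cfg, behavior = beh)

subset(res$similarity, level == "group")
#>              pair         r
#>    rest vs 1-back 0.9616933
#>    rest vs 2-back 0.9539598
#>  1-back vs 2-back 0.9480123
```

Group-level FC is highly similar across states (r > 0.94): the connectome
keeps its overall architecture. The repeated-measures ANOVA still detects
the planted reconfiguration:

```r
subset(res$stats$anova, measure %in% c("mean_msi", "modularity", "efficiency"))
#>           family    measure      F df1 df2    p_adj fdr_significant
#>  global_topology efficiency   5.43   2  22 1.52e-02            TRUE
#>  global_topology modularity 133.10   2  22 2.56e-12            TRUE
#>              msi   mean_msi  19.14   2  22 1.07e-04            TRUE
```

Mean MSI and modularity fall with cognitive load (higher integration),
while global efficiency rises — the planted direction. Fitted diffusion
parameters show the matching behavioral signature (lower drift rate,
higher boundary and nondecision time in the harder state):

```r
res$stats$behavior_t
#>  parameter             pair     t        p cohens_d
#>          v 1-back vs 2-back  6.34 5.56e-05     1.83
#>          a 1-back vs 2-back -5.94 9.77e-05    -1.71
#>        ter 1-back vs 2-back -4.49 9.21e-04    -1.30
```

`run_sensitivity()` repeats the core contrasts over density / window /
step grids with and without FD regression, and `write_cohort()` /
`read_cohort()` round-trip cohorts through plain TSV + JSON for use from
other tools. A thin command-line wrapper with `simulate`, `run`, and
`sweep` verbs is installed at `inst/scripts/netreconfig.R`.

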
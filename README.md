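# dyncore

Dynamic community structure and core-periphery organization of multilayer
functional networks.

## The problem

When a brain (or any multichannel dynamical system) is observed across a
sequence of time windows, its functional network — the matrix of pairwise
statistical associations between regions — reorganizes from window to
window. `dyncore` asks three questions about that reorganization:

1. **Which regions keep their module allegiance and which keep switching?**
   Windows become layers of a multilayer network; communities are found by
   maximizing multilayer modularity

   *Q* = (1/2μ) Σ<sub>ijlr</sub> [ (A<sub>ijl</sub> − γ<sub>l</sub>
   k<sub>il</sub>k<sub>jl</sub>/2m<sub>l</sub>) δ<sub>lr</sub> +
   ω δ<sub>ij</sub> 1(|l−r|=1) ] δ(g<sub>il</sub>, g<sub>jr</sub>),

   and each node's **flexibility** f<sub>i</sub> is the fraction of
   adjacent-layer transitions at which its community label changes.
   Comparing empirical flexibility against a null model that rewires the
   inter-layer couplings splits regions into a temporally stiff **core**,
   a null-consistent **bulk**, and a flexible **periphery**.
2. **Are the temporally stiff regions also the densely connected ones?**
   Each layer gets a continuous **geometrical core score** per node: a
   permutation of nodes over a two-parameter ordered transition vector
   C(α, β) is annealed to maximize the core quality
   R = Σ<sub>i≠j</sub> A<sub>ij</sub> C<sub>p(i)</sub> C<sub>p(j)</sub>.
   Flexibility and core score are then correlated across regions.
3. **Does network reorganization predict learning?** Movement times over
   practice trials are fit with MT(t) = A·e<sup>κt</sup> + B by a robust
   least-absolute-residuals fit; the skewness and kurtosis of each
   subject's flexibility distribution are rank-correlated with the
   learning parameter κ.

A synthetic-data module generates time series, multilayer weight tensors
and behavioral cohorts with planted ground truth (stable-core /
switching-periphery community dynamics, core-periphery weight gradients,
exponential learning curves with heavy-tailed noise), so the whole
pipeline is testable end to end.

## Worked example

Simulate a 10-subject cohort (60 regions, 8 windows, 3 communities; stiff
core, memoryless bulk, anti-persistent periphery; learning curves with a
planted negative moments-to-κ link) and run every stage:

```r
library(dyncore)
manifest <- run_pipeline(list(
  out_dir = "demo_run", seed = 42,
  simulate = list(n_subjects = 10, n_regions = 60, n_layers = 8,
                  n_communities = 3, mode = "tensor", effect_size = 1,
                  core_fraction = 0.3, periphery_switch_prob = 1,
                  periphery_switch_mode = "change", bulk_switch_prob = 1),
  communities = list(gamma = 1, omega = 1, n_opts = 3),
  nullband = list(n_rewirings = 6, n_opts = 1, pooling = "matched"),
  corescore = list(alpha = 0.5, beta = 0.7, n_restarts = 2)))
```

This takes about a minute and prints (via `manifest$results`):

```
roles
     core      bulk periphery
       25        21        14
null band: [0.600, 0.800]
kappa: -0.045 -0.014 -0.058 -0.029 -0.026 -0.021 -0.047 -0.035 -0.024 -0.045
skewness -> kappa: rho = -0.93 (p = 0.000112)
kurtosis -> kappa: rho = -0.93 (p = 0.000112)
flexibility vs core score: r = -0.97 (p = 3.61e-36)
```

Reading the output: the rewiring null concentrates flexibility in the band
[0.60, 0.80], so regions below it form the temporal core and regions above
it the periphery (the planted strata are 18/27/15; subject-to-subject
variation in periphery size blurs the core/bulk boundary slightly). All
ten fitted κ are negative — every synthetic subject "learns" — and both
distribution moments of flexibility correlate negatively with κ, i.e.
subjects with stronger core-periphery separation learn faster, which is
the planted effect. The strong negative flexibility-core-score correlation
says that temporally stiff regions are also the densely connected ones.

Lower-level entry points: `build_tensor()` (MODWT + Welch coherence),
`louvain_multilayer()` / `run_ensemble()` / `flexibility()`,
`rewire_interlayer()` / `null_flexibility_ensemble()` /
`classify_temporal_roles()`, `anneal_assignment()` / `rscore_landscape()` /
`core_scores()`, `fit_learning_curve()`, `moments()` / `spearman_cor()` /
`pearson_cor()`. File formats (TSV + JSON manifests) are documented in
`?write_timeseries`, `?write_tensor`. A CLI is available via
`Rscript -e 'dyncore::dyncore_cli()' <subcommand> --config cfg.json`.

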
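---
title: "Methods: dynamic communities and core-periphery organization in multilayer functional networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic communities and core-periphery organization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package computes

`dyncore` analyzes how the community structure of a weighted functional
network reorganizes across time windows, and how that reorganization
relates to behavior. The pipeline has six stages:

1. **Network construction.** Each region's windowed time series is
   decomposed with the maximal-overlap discrete wavelet transform (MODWT);
   the edge weight between two regions in a window is the band-averaged
   magnitude-squared coherence of their wavelet coefficients. One window =
   one network layer; layers stack into an `N x N x L` adjacency tensor.
2. **Dynamic community detection.** Multilayer modularity
   $$Q = \frac{1}{2\mu} \sum_{ijlr} \Big[ \big(A_{ijl} - \gamma_l
   \tfrac{k_{il} k_{jl}}{2 m_l}\big)\,\delta_{lr} + \omega\,\delta_{ij}\,
   \mathbf{1}[|l-r|=1] \Big]\, \delta(g_{il}, g_{jr})$$
   is maximized with a Louvain-like greedy optimizer. The intra-layer null
   model is Newman–Girvan ($k$ = node strength, $2m_l$ = total layer
   strength); $\gamma_l$ controls community size, $\omega$ the temporal
   smoothness of labels, and $2\mu$ is the total intra-layer strength plus
   total coupling strength.
3. **Flexibility.** $f_i$ = fraction of the $L-1$ adjacent-layer
   transitions at which node $i$ changes community; network flexibility is
   the node mean.
4. **Temporal core / bulk / periphery.** Inter-layer couplings are rewired
   by uniformly random per-interface permutations (intra-layer structure
   untouched); nodes whose empirical flexibility falls below the 2.5th
   percentile of the null flexibility distribution form the temporal core,
   above the 97.5th the periphery, all else the bulk (boundary equality →
   bulk).
5. **Geometrical core score.** Per layer, a permutation of nodes over an
   ordered two-parameter transition vector $C(\alpha,\beta)$ is sought that
   maximizes the core quality $R = \sum_{i \ne j} A_{ij} C_{p(i)} C_{p(j)}$
   (simulated annealing, best of `n_restarts`); a node's core score is its
   transition value under the best order, normalized to max 1.
6. **Learning curves and linking.** Movement times are fit with
   $MT(t) = A e^{\kappa t} + B$ ($A, B > 0$) by least absolute residuals;
   skewness and kurtosis of the per-subject flexibility distribution are
   rank-correlated with $\kappa$, and nodal flexibility is
   Pearson-correlated with the mean geometrical core score.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `scale` | 2 | wavelet scale; at 2 s sampling the band is 0.0625–0.125 Hz |
| `family` | `"d4"` | 4-tap Daubechies MODWT filter, reflection boundary |
| `segment_length`, `overlap` | 32, 0.5 | Welch coherence estimator (Hann taper) |
| `gamma` | 1 | structural resolution (per layer) |
| `omega` | 1 | inter-layer coupling, adjacent layers only |
| `n_runs` | 100 | modularity optimizations averaged per network |
| `n_rewirings` | 100 | null networks per empirical network |
| `alpha`, `beta` | — | transition sharpness and low-segment fraction |
| `n_restarts` | 10 | annealing restarts, best R kept |
| `loss` | `"lar"` | robust L1 learning-curve fit (`"ls"` available) |

The wavelet family, boundary rule and coherence estimator are package
decisions — the underlying method names only the statistic — and all are
recorded in the tensor's metadata. The defaults $\gamma = \omega = 1$ are
configurable and can be swept as a configuration grid.

**β convention.** `beta` is the fraction of nodes in the *low* (periphery)
segment of the transition vector: the first $\lfloor \beta N \rfloor$
entries rise to $(1-\alpha)/2$, the rest from $(1+\alpha)/2$ to 1, so the
boundary jump equals $\alpha$ and a planted core of fraction $c$ is
recovered at $\beta \approx 1 - c$. The opposite convention ("smaller β,
smaller core") exists in the literature; the planted-core recovery test
pins the one used here.

## The synthetic world

The generators state a small explicit world rather than emulating fMRI
physics:

* **Signals.** In each window every node's series is
  $\sqrt{c}\, z_{g(i,l)} + \sqrt{1-c}\,\varepsilon_i$, where $z$ is white
  noise band-limited (by FFT masking) to the scale-2 band and $c$ is
  `coupling_strength`. This plants exactly the band-limited coherence
  structure the estimator measures, and nothing else — no hemodynamics, no
  autocorrelation, no measurement drift. A green coherence test therefore
  establishes estimator correctness, not robustness to fMRI artifacts.
* **Community dynamics.** Nodes are split into a stiff core (label
  constant), a bulk, and a switching periphery. Default semantics follow a
  per-layer resampling probability (bulk default: geometric mean of a 0.02
  floor and the periphery probability). A `"change"` mode makes switching
  anti-persistent (a switching node never keeps its label).
* **Weights-only fixtures.** `generate_adjacency_tensor` bypasses spectral
  estimation: beta-distributed weights whose means encode a
  core–periphery gradient (core-core / core-periphery /
  periphery-periphery means, bulk interpolated halfway) plus an optional
  within/between community contrast.
* **Behavior.** Subject $s$ has a separation score $d_s \in [0,1]$; larger
  $d_s$ shrinks the periphery fraction (raising the skewness and kurtosis
  of the flexibility distribution — a smaller high-flexibility minority
  makes the distribution more right-tailed) and lowers the planted
  $\kappa_s$ linearly in `effect_size`, so moment–$\kappa$ correlations
  are negative by construction. Movement times get additive Laplace noise
  plus multiplicative outliers (factor uniform in $[2,4]$) at the stated
  rate, which is what the L1 fit is for.

## Why the temporal-classification world looks the way it does

The rewiring null has a sharp qualitative behavior on planted-block
tensors: after rewiring, the correspondence of community labels across
layers loses its anchor, so every node's null flexibility concentrates
near the label-matching "scramble" level (about $1 - 1/k$ for $k$
balanced communities), regardless of the node's own dynamics. The null
band is therefore a narrow interval at high flexibility. A world in which
bulk nodes switch rarely (the package default) puts bulk *below* that
band, and three-way classification is impossible — only the core is
recoverable.

The recovery test consequently states its strata *relative to the null*,
which mirrors how the classes are defined in the first place:

* **core** — never switches (flexibility ≈ 0, far below the band);
* **bulk** — memoryless: resamples its community uniformly every layer,
  making it *exactly* null-consistent, with empirical sampling variance
  matched to the band by pooling the same number of replicate subjects;
* **periphery** — anti-persistent: changes community at every transition
  (flexibility ≈ 1, above the band).

Sixteen replicate subjects share one stratum layout (`strata_seed`) with
independent label realizations; empirical flexibility is averaged over
subjects and optimizations, and the band is taken over subject-averaged
(node, rewiring) values so empirical and null means have the same
sampling variance (`pooling = "matched"` in `run_pipeline()`). Four independent worlds gave 0.93–0.98 accuracy; the
acceptance test fixes one.

## Numerical choices

* **Optimizer.** Louvain moves accept only strictly positive gains
  ($>10^{-12}$); node order is randomized per pass from the seed.
  Aggregation alone stalls on coupled multilayer problems (it locks early
  label-matching mistakes across layers), so each aggregation cycle is
  followed by a slot-level refinement pass; cycles repeat until no gain.
  Reported Q is recomputed from the final partition.
* **Annealing.** Initial temperature = standard deviation of $\Delta R$
  over 100 random swaps; geometric cooling 0.995; $100N$ proposals per
  temperature; stop after 20 temperatures without improvement (hard cap
  5000). $C$ is unit-Euclidean-normalized so $R$ is comparable across
  $(\alpha, \beta)$; the diagonal is excluded and ordered pairs counted
  both ways. The first restart starts from the strength-ranked order, so
  the returned R never falls below it.
* **Percentiles** use linear interpolation between order statistics
  (`quantile` type 7).
* **Learning fit.** Parameters are optimized as $(\log A, \kappa, \log B)$
  (positivity by construction) with Nelder–Mead from 8 deterministic
  starts: $\kappa$ grid around a log-linear initial estimate with
  $B_0 = 0.9 \min MT$. Near-constant data are flagged `degenerate`, never
  an error. Exact-permutation Spearman p-values are limited to $n \le 9$.
* **Degenerate inputs.** Zero-strength layers skip the null term; empty
  tensors yield singleton partitions with $Q \le 0$; single-layer
  flexibility, constant-vector correlations and < 3 distinct moment values
  raise classed errors.

## Known limitations

* The generators plant stationary band-limited Gaussian structure; no
  claim is made about robustness to autocorrelated noise, motion
  artifacts, or hemodynamic convolution.
* The null band on small worlds is sensitive to the number of planted
  communities through the scramble level; worlds with very unbalanced
  communities shift it.
* The annealing schedule is tuned for dense weighted layers of ~30–120
  nodes; much larger layers need a longer schedule (all knobs exposed).
* Exact Spearman p-values stop at $n = 9$; beyond that the t
  approximation is used.
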
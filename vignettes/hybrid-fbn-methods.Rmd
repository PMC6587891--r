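---
title: "Hybrid functional brain connectivity networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid functional brain connectivity networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridFBN)
```

## The model

A subject is a matrix $X \in \mathbb{R}^{n \times m}$ of $n$ regional fMRI
time series with $m$ time points. hybridFBN builds two complementary
connectivity networks from $X$ and fuses them.

**First-order network.** $C^1_{ij} = \operatorname{cor}(x_i, x_j)$, the
Pearson correlation of the region time series, with zero diagonal.

**Second-order (triplet) network.** For each centre region $i$, let $N_i$ be
its $k$ nearest neighbours under squared Euclidean distance
$d(x_i, x_j) = \lVert x_i - x_j \rVert^2$. For a neighbour pair
$(u, v) \in N_i \times N_i$ the triplet field

$$S^i_{uv} = d(x_i, x_v) - d(x_i, x_u)$$

is antisymmetric and encodes how the *ranking* of neighbours around $i$
would change if $v$ moved relative to $u$. Summing the field over the
anchor index gives a relative distance

$$d'(x_i, x_v) = \sum_{u \in N_i} S^i_{uv}
              = k \, d(x_i, x_v) - \sum_{u \in N_i} d(x_i, x_u),$$

so $d'$ measures how far $v$ sits from $i$ *relative to the whole
neighbourhood*, not in absolute units. Edge weights are
$C^2_{ij} = \operatorname{minmax}(-d'(x_i, x_j))$ for $j \in N_i$ (zero
otherwise), where the min–max normalisation to $[0, 1]$ is taken jointly
over all computed entries of the subject, so that one global scale is shared
by all centres. The matrix is then symmetrised,
$C^2 \leftarrow (C^2 + C^{2\top})/2$, with a zero diagonal. Ties in the
$k$-NN ranking resolve to the smaller region index; a degenerate subject in
which every computed value is equal yields an all-zero network with a
warning.

**Hybrid fusion.** $C = \mu C^1 + (1 - \mu) C^2$ with $\mu \in [0, 1]$;
$\mu = 1$ recovers the Pearson network exactly and $\mu = 0$ the
second-order network. An optional absolute threshold $t$ zeroes entries with
$|C_{ij}| < t$ *after* fusion.

## Classification pipeline

Each subject's network is vectorised over the $n(n-1)/2$ region pairs in
row-major $(i < j)$ order. The pipeline in `hfbn_fit()` is:

1. **Non-negative elastic net.** Edges are selected by
   $\min_{\beta \ge 0} \tfrac12 \lVert y - F\beta \rVert^2
   + \lambda_1 \sum_j \beta_j + \tfrac12 \lambda_2 \lVert \beta \rVert^2$
   with labels coded $\pm 1$. The solver is cyclic coordinate descent with
   non-negative soft-thresholding (implemented in C++; tolerance $10^{-8}$,
   at most $10^4$ sweeps). Edges with $\beta_j > 0$ are retained.
2. **Kernel discriminant analysis.** On the selected edges, a Gaussian
   kernel $K(a, b) = \exp(-\gamma \lVert a - b \rVert^2)$ Fisher
   discriminant projects subjects to one dimension. The direction is the
   closed form $\alpha = (N + \varepsilon I)^{-1} (m_1 - m_2)$, where $m_c$
   are kernel class means and $N$ the within-class kernel scatter; the sign
   is fixed so that patients project higher. Defaults: $\gamma$ is the
   inverse median pairwise squared distance, and
   $\varepsilon = 10^{-3}\operatorname{tr}(N)/n$ scales with the scatter.
3. **Nearest-neighbour classification.** Test subjects take the label of
   the nearest training subject in the 1-D projection (ties to the smaller
   training index). Scores are standardised by the training mean and sd.

`run_repeated_cv()` wraps this in stratified 10-fold cross-validation
repeated 20 times (defaults), with a derived per-repeat seed. The penalty is
tuned inside each training fold by 5-fold inner CV over
$\lambda \in 10^{\{-3,\dots,0\}}$ with $\lambda_1 = \lambda_2$ tied; tying
keeps the inner search one-dimensional and cheap while still spanning three
orders of magnitude of shrinkage. Reported metrics are ACC, SEN, SPE, PPV,
NPV, F1, BAC, and the rank-based AUC (equivalent to the all-pairs
Mann–Whitney statistic with half credit for ties), with AUC computed from
pooled out-of-fold scores standardised per training fold. Paired AUCs are
compared with the DeLong placement-value test (`delong_compare()`).

`greedy_grid_search()` tunes $(k, \mu, t)$ coordinate-wise — $k$ first at
$\mu = 0.5, t = 0$, then $\mu$, then $t$ — scoring each candidate by
single-repeat stratified CV accuracy at a fixed small penalty. This is
deliberately cohort-level model selection (the selected triple is then
evaluated by full repeated CV); scores from the search itself are
optimistically biased and reported only as `score`.

## Graph topology

`compute_topology()` reports fourteen graph metrics. Connectivity strength
is computed on the weighted network (mean row sum of $|C|$); all others are
computed on the binarized graph with an edge iff $|C_{ij}| \ge t$ (so
$t = 0$ yields the complete graph). Path-based metrics on a disconnected
graph use the largest connected component, with a warning. Notable
definitional choices:

- *Local efficiency* of node $v$: average inverse distance between $v$'s
  neighbours through the graph with $v$ removed (the corrected
  Latora–Marchiori definition, matching igraph).
- *Betweenness* (node and edge) is raw Brandes betweenness with each
  unordered pair counted once, not normalised.
- *Closeness* is the normalised $(n-1)/\sum_j d(v, j)$, and *radiality* is
  $\operatorname{diam} + 1 - \bar d_v$.
- *Assortativity* is the Pearson correlation of endpoint degrees over
  directed edges; a regular graph gives `NaN` with a warning.
- *Structural consistency* removes a fraction $p_H = 0.1$ of edges, corrects
  the remaining spectrum to first order
  ($\Delta\lambda_k = v_k^\top \Delta A v_k$), and measures the fraction of
  removed edges recovered among the top-ranked unobserved pairs, averaged
  over 20 seeded repeats.
- *Power-law exponent* is the continuous-approximation MLE
  $\hat\alpha = 1 + N / \sum \ln(d / (d_{\min} - \tfrac12))$ with
  $d_{\min}$ the smallest positive degree. This estimator is known to be
  biased upward-of-truth at very small $d_{\min}$; it is accurate for
  $d_{\min} \gtrsim 5$.

## Biomarkers

`sac_scores()` ranks edges by the absolute difference of group mean
connectivity, min–max normalised so the top edge scores exactly 1 (a
two-sample $t$ statistic is available via `stat = "t"`).
`region_weights()` accumulates, per region, the scores of the top edges
incident to it and renormalises. `subnet_extract()` restricts group mean
networks to a region subset.

## Synthetic cohorts

`generate_cohort()` draws each subject's time series from a multivariate
normal with a block-structured correlation matrix (within-block and
between-block levels), plus i.i.d. observation noise. Perturbations are
per-edge correlation deltas: `base_perturbation` applies to both groups,
`perturbation` to patients only. Targets that lose positive definiteness are
repaired by eigenvalue flooring and renormalisation to unit diagonal; edits
that push any correlation past $|0.99|$ are rejected as not repairable.

Two packaged scenarios (both 40 patients + 40 controls, 20 regions, 150
time points) define the package's study conditions:

- `separated_cohort_scenario()`: ten between-block edges raised by $+0.35$
  in patients — a strong, first-order-visible planted signal.
- `ordinal_perturbation_scenario()`: small edits (all $|\delta| \le 0.1$)
  that swap nearest-neighbour *rankings* around several centres without
  large magnitude changes — the regime the second-order network is built
  for.

These sizes were chosen as the package's own desk-scale defaults: large
enough for stable 10-fold stratification and clear planted-signal recovery,
small enough that the full repeated-CV pipeline runs in seconds.
`shuffle_labels()` produces the matched null.

## Scope and limitations

- The generator emulates *covariance structure only*: it is stationary
  Gaussian with i.i.d. noise, and does not model haemodynamics, temporal
  autocorrelation, motion artefacts, or site effects. Claims verified on it
  concern the pipeline's statistical machinery, not clinical performance.
- Classification metrics on real clinical cohorts depend on
  acquisition and preprocessing choices outside this package's scope.
- `greedy_grid_search()` is coordinate-wise, not exhaustive, and its
  selection score is cohort-level; nested-CV generalisation estimates for
  the *selected* configuration must come from a fresh `run_repeated_cv()`.
- The power-law MLE is reported descriptively; no goodness-of-fit test is
  attached.

## A worked example

```{r example, eval = FALSE}
co <- generate_cohort(separated_cohort_scenario(seed = 1))
metrics <- run_repeated_cv(co, plan = cv_plan(n_folds = 10, n_repeats = 20,
                                              seed = 1))
print(metrics)

nets <- lapply(co$subjects, pearson_network)
sac <- sac_scores(nets[co$labels == "patient"],
                  nets[co$labels == "control"])
head(as.data.frame(sac))
```
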
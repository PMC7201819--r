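---
title: "Immune evolutionary fuzzy clustering: model, operators, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune evolutionary fuzzy clustering: model, operators, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mieaclust)
```

## The clustering model

`mieaclust` minimizes the fuzzy c-means (FCM) objective

$$J(X; U, V) \;=\; \sum_{k=1}^{n}\sum_{i=1}^{c} u_{ik}^{\,m}\, D_{ik}^2,
\qquad D_{ik}^2 = \lVert x_k - v_i \rVert^2,$$

over cluster prototypes $V = (v_1,\dots,v_c) \in \mathbb{R}^{c\times p}$ and a
fuzzy partition $U = [u_{ik}]_{c\times n}$ constrained to
$u_{ik}\in[0,1]$, $\sum_i u_{ik} = 1$ for every sample $k$, and
$0 < \sum_k u_{ik} < n$ for every cluster $i$. The fuzzifier $m \in (1,\infty)$
controls how soft the partition is: $m \to 1$ approaches hard k-means,
large $m$ flattens all memberships toward $1/c$. The default $m = 2$ is the
standard choice and the one all defaults are calibrated for.

Given prototypes, the optimal memberships have the closed form

$$u_{ik} = \Bigl[\sum_{j=1}^{c}
  \bigl(D_{ik}^2 / D_{jk}^2\bigr)^{1/(m-1)}\Bigr]^{-1},$$

with a degenerate branch when a sample coincides with one or more centers
($I_k = \{i : D_{ik} = 0\} \neq \emptyset$): all membership mass goes to the
coincident centers and every other membership is zero. Two numerical
choices here:

* **Tie-breaking.** When several centers coincide with a sample
  ($|I_k| > 1$) the constraint only fixes the *sum* of their memberships to
  1; we split the mass uniformly ($1/|I_k|$), the symmetric choice.
* **Zero threshold.** A squared distance at or below $10^{-12}$ is treated
  as exactly zero, so near-singular columns take the degenerate branch
  instead of overflowing the reciprocal-ratio formula. In the regular
  branch every column is additionally divided by its smallest squared
  distance before exponentiation (the ratios are scale-free), keeping all
  intermediate powers in $(0, 1]$ even for fuzzifiers close to 1.

Alternating these two updates — memberships from centers, then centers as
the $u^m$-weighted means — is classic FCM (`fcm_refine()`). It descends
monotonically but is a local method: from a poor start it can merge or
misplace clusters. That failure mode is the motivation for the
evolutionary layer.

## The immune evolutionary layer

`run_miea()` searches the prototype space with a real-coded genetic
algorithm. A chromosome is the row-major concatenation of the $c$ centers
($l = c \times p$ genes), so the encoding does not grow with the sample
count. Fitness is

$$f = \frac{1}{J + 1} \in (0, 1],$$

a strictly decreasing bijection of the objective, so maximizing fitness
minimizes $J$.

One generation, in order:

1. **Evaluation.** Every chromosome is decoded and scored through the FCM
   pipeline (distances, membership update, objective, fitness).
2. **Vaccine upkeep.** Whenever the elite improves, a new *vaccine* is
   extracted from it: `ceiling(vaccine_fraction * l)` distinct gene
   positions chosen uniformly, carrying the elite's values. In a
   generation where the elite did not improve, the vaccine's positions are
   refreshed from the unchanged elite with probability `p_u` (default
   0.5) — this is our reading of a "vaccine update probability" that would
   otherwise have no role after initialization.
3. **Selection, crossover, mutation.** Parents are drawn with replacement
   by roulette-wheel (fitness-proportionate) or linear-rank selection;
   adjacent pairs recombine with probability `p_c` (one-point by default;
   two-point and uniform available); each gene then mutates with
   probability `p_m` by uniform re-randomization within its feature's
   observed range. The classical "inversion" mutation is defined for
   binary strings; for real-coded genes we use the reset form, and provide
   an optional segment-reversal operator (`mutation = "segment_reversal"`)
   for readers who want the literal inversion.
4. **Vaccination and immune selection.** Each offspring is vaccinated with
   probability `p_v` (the vaccine's values overwrite its genes at the
   vaccine's positions) and the vaccinated version is kept only if its
   fitness is not worse — a deterministic greedy acceptance. This is the
   anti-degradation mechanism that distinguishes an immune GA from a plain
   GA: good partial solutions spread, but never at the cost of an
   individual's fitness. Annealing-style acceptance would also fit; greedy
   is simpler and directly testable.
5. **Elitism.** The elite replaces the worst offspring unchanged, so the
   best objective per generation is non-increasing by construction.

The loop stops when the elite objective has changed by less than `tau`
(default $10^{-6}$) for `patience` (default 10) consecutive generations,
or at `max_gens` (default 100).

### Final refinement

By default (`refine = TRUE`) the decoded elite is polished with
`fcm_refine()` after the loop, run to numerical convergence
(`tol = min(tau, 1e-10)`). The reason is structural: swap crossover and
vaccination only *recombine and copy* existing gene values, and uniform
reset mutation rarely lands near an optimum, so the evolutionary search
reliably identifies the right basin but not its floor. Descent from the
evolved elite supplies the missing local convergence. The division of
labor is therefore: global, restart-free search by the immune GA; local
convergence by alternating optimization. `refine = FALSE` gives the
strictly chromosome-only algorithm; `J_history` always records the raw
(unpolished) elite trajectory either way.

### Parameters that matter

| parameter | meaning | default | notes |
|---|---|---|---|
| `c` | cluster count | — | fixed a priori, $1 \le c \le n-1$ |
| `m` | fuzzifier (dimensionless) | 2 | softness of the partition |
| `p_n` | population size | 30 | |
| `p_c` | crossover probability | 0.95 | operating range [0.75, 0.95] |
| `p_m` | per-gene mutation probability | 5e-3 | operating range [1e-3, 1e-2] |
| `p_v` | vaccination probability (per offspring) | 0.3 | |
| `p_u` | vaccine refresh probability | 0.5 | used when the elite is stagnant |
| `vaccine_fraction` | share of genes donated | 0.25 | |
| `tau`, `patience` | stop rule on elite J | 1e-6, 10 | |
| `max_gens` | generation cap | 100 | |

Whether vaccination should touch every offspring or only a subpopulation
is genuinely open; we apply the `p_v` Bernoulli draw independently per
offspring.

### Scaling

`run_miea(scale = TRUE)` (the default) min-max scales every feature to
$[0,1]$ before optimizing and maps the prototypes back to data units in
the result. Two reasons: Euclidean distances (and Relief weights) are
meaningful only on commensurate ranges, and the fitness $1/(J+1)$ gives
roulette selection usable pressure only when $J$ is of order 1 — on raw
data $J$ can be in the hundreds and all fitnesses collapse toward 0.
`J` and `U` in the result refer to the scaled space.

## Chunked objective evaluation

`partitioned_objective()` evaluates $J$ in contiguous row blocks and sums
the per-block partials — the single-machine equivalent of a map/reduce
fitness evaluation. Because the membership update is column-separable the
decomposition is exact; we still allow $10^{-9}$ relative slack for
summation-order effects.

## Relief feature weighting

`relief_weights()` implements classic Relief (Kira–Rendell): sample an
instance $R$, find its nearest hit (same class) and nearest miss (other
class) by Euclidean distance over all min-max-scaled features, and update
each feature's weight by `diff(d, R, miss) - diff(d, R, hit)` with
`diff` the absolute difference of scaled values, finally dividing by the
number of sampled instances so weights lie in $[-1, 1]$. A feature
independent of the class drifts to 0; a separating feature scores
positive. Because single runs depend on the sampled instances,
`averaged_weights()` repeats the procedure (20 runs by default, seeds
`base_seed + r`) and averages. `select_features()` prunes either by
threshold ($w_d < t$ removed) or by removing the `k` smallest weights
(ties: lower index removed first). Sampling is without replacement when
`n_samples <= n`. The multiclass ReliefF extension (k nearest neighbors,
per-class miss weighting) is deliberately out of scope; with more than
two classes the nearest miss is simply the nearest instance of any other
class.

## External validation

With reference labels available, `contingency()` tabulates classes
against clusters ($n_{ij}$), and two crisp scores are computed from it:

* **Clustering F-measure.** Per pair, recall $r = n_{ij}/n_i$, precision
  $p = n_{ij}/n_j$, $F(i,j) = 2rp/(r+p)$; the dataset score is the
  class-size-weighted best match
  $F = \sum_i (n_i/n)\, \max_j F(i,j) \in (0, 1]$, invariant to cluster
  relabeling, equal to 1 exactly at perfect recovery. The weighting by
  class proportion is the standard reading consistent with the upper
  bound of 1. Empty clusters are skipped in the per-class maxima.
* **Majority-mapping accuracy.** Each cluster is mapped to its most
  frequent reference class; the score is the fraction of correctly mapped
  samples, $\sum_j \max_i n_{ij} / n$.

Hard labels for both come from the membership argmax per sample (ties to
the lowest cluster index), the standard defuzzification. Note that
neither score dominates the other in general; both are reported.

## The synthetic generator, and what tests do not show

`generate_mixture()` draws labeled samples from isotropic Gaussian
components at configurable means, spreads and mixing weights, optionally
padding the table with uniform noise features that carry no class signal.
Every component is guaranteed at least one sample (reassigning only from
components with duplicates to spare), so labels always span all classes.
The test fixtures are deliberately modest: the center-recovery fixture
uses three components at $(0,0)$, $(5,5)$, $(0,5)$ with spread 0.2 and
$n = 300$; the harder comparison fixture uses four components on a
$6\times6$ square with spread 1.0 and $n = 400$, where clusters overlap;
weighting fixtures use 60–500 samples. These sizes keep the full suite
under a minute while still exercising overlap, noise features, and
multi-seed stochastic properties.

What the generator does *not* emulate: anisotropic or correlated
covariances, heavy tails, class imbalance beyond the mixing weights,
discrete/ordinal attributes (clinical tables are often 1–10 integer
scales), and missing-data mechanisms beyond the `"?"` marker handled at
load time. Passing tests therefore demonstrate correctness of the
machinery and recovery under well-specified Gaussian conditions — not
performance claims on real clinical data.

## Known limitations

* The cluster count `c` is fixed a priori; no model selection is
  attempted.
* The immune GA is a global heuristic: no convergence guarantee exists
  beyond elitism's monotone best-objective, and on overlapping mixtures
  its practical advantage over a single FCM start is in avoiding the
  occasional bad basin, not in reaching lower objective values within a
  basin (the final descent step does that for both).
* Relief here is the two-class-style original; with many classes and
  strong imbalance ReliefF would be preferable.
* `fcm_refine` re-seeds a center from a random data point if a cluster
  loses all effective mass; this keeps runs alive but makes that
  particular trajectory non-monotone in pathological cases (none observed
  under the tested conditions).
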
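# mieaclust

Fuzzy clustering of numeric tabular data — clinical measurement tables,
UCI-style CSV files, or simulated mixtures — driven by a **modified immune
evolutionary algorithm (MIEA)**. Plain fuzzy c-means (FCM) is a descent
method and can fall into local minima from a poor start; MIEA wraps the
FCM objective in a real-coded genetic algorithm whose population searches
the space of cluster centers globally, reinforced by an immune mechanism
(vaccination with gene fragments from the current best solution, accepted
only when fitness does not degrade) that speeds convergence without
losing diversity to degradation.

The package is aimed at analysts who want a restart-free, fully seeded,
reproducible fuzzy clustering pipeline on modest tabular data, with
feature relevance weighting and external validation built in.

## The model

The optimization target is the FCM objective

```
J(X; U, V) = sum_k sum_i  u_ik^m * ||x_k - v_i||^2
```

over prototypes `V` (c centers in R^p) and a fuzzy partition `U`
(`u_ik` in [0,1], columns summing to 1), with fuzzifier `m > 1`
(default 2). Memberships given centers have the closed form
`u_ik = 1 / sum_j (D_ik^2 / D_jk^2)^(1/(m-1))`, with all mass assigned to
coincident centers when a sample sits exactly on one. A chromosome is the
concatenation of the `c` centers (length `c*p`); its fitness is
`f = 1/(J+1)`. Each generation applies roulette/rank selection,
crossover, mutation, vaccination and immune selection, with elitism; the
decoded elite is finally polished by alternating-optimization FCM.

Alongside the optimizer the package provides:

* **Relief feature weighting** (`relief_weights()`,
  `averaged_weights()`, `select_features()`): nearest-hit/nearest-miss
  relevance scores on min-max-scaled features, averaged over repeated
  runs, with threshold or bottom-k pruning.
* **External validation** (`f_measure()`, `majority_accuracy()`): the
  class-size-weighted clustering F-measure
  `F = sum_i (n_i/n) max_j 2 r p / (r + p)` and majority-mapping
  accuracy, computed from a class-by-cluster contingency table.
* **A labeled Gaussian-mixture simulator** (`mixture_spec()`,
  `generate_mixture()`) with optional pure-noise features, so every
  result in this README is reproducible from a seed.
* **UCI-style CSV I/O** (`load_table()`, `write_table()`): optional ID
  and class-label columns, `"?"` missing markers with drop or
  mean-impute policies.

## Worked example

```r
library(mieaclust)

spec <- mixture_spec(rbind(c(0, 0), c(5, 5), c(0, 5)), spreads = 0.2)
ds   <- generate_mixture(spec, n = 300, seed = 42)
ds
#> labeled_dataset: n = 300 samples, p = 2 features, 3 classes

res <- run_miea(ds, miea_config(c = 3, seed = 42))
res
#> MIEA clustering: c = 3 clusters, J = 0.612558, f = 0.6201, 16 generations
#> prototypes (data units):
#>         [,1]   [,2]
#> [1,]  4.9958 4.9703
#> [2,]  0.0098 0.0175
#> [3,] -0.0165 4.9697

ev <- evaluate_clustering(ds$labels, res$hard_labels)
sprintf("F-measure: %.3f  majority accuracy: %.3f", ev$F, ev$accuracy)
#> "F-measure: 1.000  majority accuracy: 1.000"
```

The three recovered prototypes sit within a few hundredths of the
generating means (0,0), (5,5), (0,5); `J` is the objective on the
internally min-max-scaled data; the F-measure of 1 says the hard labels
reproduce the generating partition exactly (up to cluster numbering).

Feature weighting on a mixture with one separating and one pure-noise
feature:

```r
noisy  <- generate_mixture(mixture_spec(rbind(0, 5), spreads = 0.5,
                                        noise_features = 1L), 60, seed = 1)
averaged_weights(noisy, repeats = 20, base_seed = 1)
#> Relief weight report (20 runs averaged):
#>     V1 noise1
#> 0.6041 0.0351
```

The informative feature scores high; the noise feature is near zero and
would be pruned by `select_features(..., "bottom_k", k = 1)`.

A command-line front end composing `simulate | weights | cluster |
evaluate` ships in `inst/cli/mieaclust`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","mieaclust",package="mieaclust"))')" \
  simulate --out d.csv --truth t.json --means '0,0;5,5;0,5' --n 300 --seed 42
```

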
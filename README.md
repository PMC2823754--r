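# hme3m

Identifies the routes through a known metabolic network that discriminate
a binary biological response, and classifies new observations with them.

Metabolic networks are directed graphs of compounds whose edges are
reactions catalyzed by genes.  Given gene-expression samples labeled with
two conditions, the package extracts, for every sample, each simple
directed path from a start compound to an end compound whose genes are
over-expressed, encodes it as a binary vector over the network's edges,
and fits a supervised Markov mixture of experts to the labeled paths:

    p(y | x) = sum_m  p(m | x, theta) * p(y | x, beta_m)

* the **gate** `p(m | x, theta)` is a mixture of first-order Markov
  chains over network paths — component `m` has one transition
  probability `theta[t, m]` per edge, normalized over the edges leaving
  each compound, so `p(x | theta_m)` is the product of the traversed
  edges' probabilities and each component concentrates on a *dominant
  pathway*;
* the **experts** `p(y | x, beta_m)` are ridge-penalized logistic
  regressions (penalty `lambda`, intercept unpenalized) fitted by damped
  iteratively reweighted ridge regression with learning rate `alpha`,
  weighted by the EM responsibilities.

The result is both an accurate classifier and an interpretable map: the
fitted `theta` column of a component highlights the dominant path it
captured, exportable to GraphML/DOT for rendering on the network.

The package also ships the full validation machinery: a layered-network
simulation benchmark with planted dominant paths and controlled noise,
repeated stratified and inverse cross-validation, paired significance
tests, rank-based ROC/AUC diagnostics, and PLR/SVM baselines run on
identical folds.

## Worked example

```r
library(hme3m)

net <- make_network("small")            # layered DAG, 12 edges, 8 paths
d   <- simulate_pathways(net, n_per_class = 200, noise = 0.2, seed = 1)
fit <- fit_hme3m(d, net, M = 2, lambda = 1, alpha = 0.5, seed = 1)
fit
#> <hme3m> supervised Markov mixture of experts
#>   M = 2, P = 12 edges, N = 400 paths
#>   logLik = -812.0232 after 100 EM iteration(s)
#>   pi: 0.671 0.329
```

The two mixture components have captured the two path bundles (prior
weights 0.67/0.33), and the dominant-path report reads component 1's
high-probability route off the network — edge by edge, with the
catalyzing gene and its transition probability:

```r
dominant_path_report(fit, m = 1, threshold = 0.5)
#> # A tibble: 7 x 6
#>    edge source target gene  label    theta
#>   <int> <chr>  <chr>  <chr> <chr>    <dbl>
#> 1     1 S      L1N1   g001  e01_g001 0.564
#> 2     4 L1N1   L2N2   g004  e04_g004 0.528
#> 3     5 L1N2   L2N1   g005  e05_g005 0.855
#> 4     8 L2N1   L3N2   g008  e08_g008 0.799
#> 5     9 L2N2   L3N1   g009  e09_g009 1.000
#> 6    11 L3N1   E      g011  e11_g011 1
#> 7    12 L3N2   E      g012  e12_g012 1
```

(`theta >= 0.5` edges, ordered along the traversal; compounds with a
single exit always carry probability 1.)  Cross-validated accuracy at
20% planted noise sits where the design predicts (about
`(1 - 0.2) + 0.2/2 = 90%`, since noise paths carry no class signal):

```r
cv <- cross_validate(hme3m_spec(M = 2), d, net, folds = 10, runs = 2,
                     seed = 1)
glance(cv)
#> # A tibble: 1 x 5
#>   model       median_ccr ccr_range mean_ccr n_folds
#>   <chr>            <dbl>     <dbl>    <dbl>   <int>
#> 1 HME3M (M=2)         90      12.5     89.6      20
```

`autoplot(fit)` draws the per-component transition probabilities,
`tidy(fit)` returns them (and the expert coefficients) as tibbles, and
`export_gate_graphml()` / `export_gate_dot()` write them as edge
attributes for graph tools.  For expression data, the pipeline is
`binarize_expression()` → `build_pathway_dataset()` → `fit_hme3m()`; a
command-line wrapper with `simulate` / `extract` / `fit` / `evaluate` /
`export` subcommands lives at `inst/cli/hme3m-cli.R`.

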
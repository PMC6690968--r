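# linkess

Link-clustering analysis of essential genes in protein–protein interaction
(PPI) networks.

## The problem

In PPI networks, gene essentiality is classically tied to centrality: hubs
tend to be essential because they integrate the network globally. Yet many
essential genes (EGs) are not central at all, and those are the ones most
likely to be *contextually* essential — lethal to knock out in some cell
lines or conditions but not others, which makes them interesting as selective
therapeutic targets. `linkess` is for systems biologists who want to separate
these two kinds of essentiality from network structure alone, and to verify
the structural signatures that distinguish them.

## The model

Every node gets two scores:

- **k** — degree (number of interaction partners);
- **w** — *μCXC*, the mean over a node's incident edges of the product of the
  two endpoint clustering coefficients, `CXC(i,j) = C_i · C_j` with
  `C_i = 2T_i / (k_i(k_i−1))`. High *w* marks nodes whose links sit inside
  densely clustered neighbourhoods. In heterogeneous networks, *w* is nearly
  uncorrelated with all four standard centralities (degree, betweenness,
  closeness, eigenvector), so it measures a genuinely different axis.

Essentiality probabilities `P_E(k)` and `P_E(w)` come from leave-one-out
single-predictor logistic regressions; cutoffs `k_c`, `w_c` maximize
Matthews' correlation coefficient over all thresholds. An EG below both
cutoffs stays *unclassified*; otherwise it is **k-dependent** when
`P_E(k) > P_E(w)` and **w-dependent** when `P_E(k) < P_E(w)`.

Around that classification the package implements the full structural
pipeline: binned measure–essentiality correlations; PCA of topology measures
over EGs; degree-preserved network randomization, excess-clustering pruning
curves and their area-vs-random summary; hypergeometric term enrichment, term
overlap networks with shuffle z-tests and n-clique bias statistics; Walktrap
community hierarchies with the per-node link-density impact
`ΔD = (l_after − l_s) / (n_s(n_s−1)/2)`; and a broadness statistic over
gene × cell-line fitness screens with a binned χ² comparison. A synthetic
benchmark generator plants hubs, dense modules, labels, annotations and a
fitness matrix so the whole pipeline is testable offline.

## Worked example

```r
library(linkess)

# synthetic benchmark: hubs + dense peripheral modules, with planted labels
d <- generate_synthetic(synthetic_spec(seed = 1))
topo <- compute_table(d$network) # k, w, and 11 topology measures per node

cls <- classify_egs(topo, d$labels)
cls
#> Essential-gene classification (580 labeled nodes, 144 EGs)
#>   k-dependent: 79 (54.9% of EGs)   w-dependent: 39 (27.1%)   unclassified: 26 (18.1%)
#>   cutoffs: k_c = 12.5 (MCC 0.642), w_c = 0.4529 (MCC 0.345)
```

Both axes predict essentiality (binned Pearson correlations against the
fraction of essential genes per bin), yet they are almost uncorrelated with
each other (`cor(topo$k, topo$w)` ≈ −0.06):

```r
binned_correlation(setNames(topo$k, topo$node), d$labels)
#> Binned measure-essentiality correlation
#>   bins: 48 (580 labeled nodes)
#>   Pearson R = 0.778, p = 7.71e-11 **
binned_correlation(setNames(topo$w, topo$node), d$labels)
#>   Pearson R = 0.7308, p = 3.71e-09 **
```

w-dependent EGs hit small, low-hierarchy communities much harder than
k-dependent EGs, and the contrast vanishes at the top of the hierarchy:

```r
ms <- build_hierarchy(d$network) # Walktrap merge dendrogram
group_delta_density(d$network, ms, cls, f_H_grid = c(0.1, 1.0))
#>   f_H           class mean_delta_d       se   n
#>   0.1     k-dependent    -0.198    0.0547   18
#>   0.1     w-dependent    -0.420    0.0156   34
#>   1.0     k-dependent    -1.45e-04 8.1e-06  79
#>   1.0     w-dependent    -2.89e-05 5.2e-07  39
```

At `f_H = 0.1` (fine communities) removing a w-dependent gene deletes on
average 42% of its community's possible links versus 20% for k-dependent
genes; at `f_H = 1.0` both effects are negligible. And w-dependent genes are
essential in far fewer cell lines of the fitness screen than k-dependent
genes (`binned_group_comparison()` χ² p ≈ 3e-19 on this benchmark) — the
contextual-essentiality signature.

`autoplot(cls)` draws the k–w plane coloured by class;
`autoplot(pruning_curve(...))` and `plot_group_delta_density(...)` plot the
pruning and community-impact results.

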
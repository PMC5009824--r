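# sonrank

Ranking essential proteins in a protein–protein interaction (PPI) network by
integrating **s**ubcellular localization, **o**rthology and **n**etwork
centrality.

## The problem

Essential proteins are indispensable for survival; finding them
experimentally (gene knockout, RNAi) is slow and expensive, so they are
routinely prioritized computationally from PPI networks. Classical
centrality measures fail on low-connectivity essential proteins — the
majority class in the yeast interactome. The SON score addresses this by
combining one topological and two protein-intrinsic signals, each
normalized into [0, 1]:

* **NNC** — edge-clustering-coefficient centrality:
  `NC(i) = Σ_{j∈N_i} Z_ij / min(k_i−1, k_j−1)` (triangles on each incident
  edge over the maximum possible), normalized by the network maximum;
* **NSL** — a localization score: proteins are contrasted by NNC (top vs
  bottom 5%), each subcellular location gets a correlation coefficient
  `LCC(l) = f_l/h_l − 1` (or `1 − h_l/f_l` when `f_l < h_l`), and a
  protein's score sums the LCC of its locations, shifted and rescaled;
* **NOS** — conservation: the number of reference species holding a
  seed-pair ortholog, normalized by the network maximum.

The sorting score is the linear combination

```
pr(i) = (1 − α)·NOS(i) + α·[(1 − β)·NSL(i) + β·NNC(i)]
```

with defaults α = 0.7, β = 0.3, i.e. effective weights of 30% orthology,
49% localization, 21% centrality. Proteins are ranked by `pr` descending
and the top K% are the candidate essentials.

## Worked example

No external data is needed: the package ships a benchmark generator that
plants essentiality signal in all three channels (scale-free network with
degree-coupled labels, enriched ortholog counts, location memberships with
positively and negatively associated compartments).

```r
library(sonrank)

bench <- simulate_benchmark(n_proteins = 1000, seed = 7)
fit <- son(bench$network, bench$localization, bench$orthologs)
fit
#> SON essentiality ranking
#>   network: 1000 proteins, 4985 interactions
#>   alpha = 0.70, beta = 0.30 (weights: NOS 30%, NSL 49%, NNC 21%)
#>   top-ranked proteins:
#>  protein degree     NNC    NSL    NOS     pr rank
#>    P0002    114 1.00000 0.7419 0.7347 0.7940    1
#>    P0007     90 0.74857 0.7419 0.7959 0.7595    2
#>    P0219     10 0.00000 0.9355 1.0000 0.7584    3
#>    P0008     79 0.64911 0.7419 0.8571 0.7570    4
#>    P0001     40 0.29181 0.9355 0.7143 0.7340    5
#>    P0098     14 0.07689 0.9355 0.8163 0.7194    6
```

Note the third-ranked protein: degree 10, NNC exactly 0 — invisible to any
topology-only measure — pulled to the top by its localization and
conservation scores. Evaluating against the planted gold standard:

```r
evaluate_ranking(fit, bench$essential, network = bench$network)
#> Evaluation of SON ranking: 1000 proteins, 224 gold-standard essentials in ranking
#> essential proteins in top-K%:
#>  1%  5% 10% 15% 20% 25%
#>   4  26  47  65  85 106
#> PR AUC: 0.3955   jackknife area: 0.6605
#> by connectivity (degree threshold 10 ):
#>  percent low high total
#>        1   1    3     4
#>        5  14   12    26
#>       10  22   25    47
#>       15  29   36    65
#>       20  40   45    85
#>       25  56   50   106
```

The top 10% (100 proteins) contains 47 of the 224 essentials — precision
0.47 against a prevalence of 0.22 — and roughly half of the recovered
essentials are low-connectivity (degree ≤ 10). The same report run on the
centrality-only ranking (`evaluate_ranking(nnc_scores(bench$network), ...)`)
gives PR AUC 0.3414 and jackknife area 0.5909, both below SON's 0.3955 and
0.6605: the integrated score beats its strongest single component.

Baselines (`baseline_centrality()`: DC, BC, CC, SC, EC, IC), a parameter
grid scan (`son_grid()`), file readers/writers and a command-line wrapper
(`inst/cli/son.R` with `score`, `evaluate`, `simulate`, `grid` subcommands)
round out the toolkit. See the vignette in `vignettes/son-method.Rmd` for
the full model description and design rationale.

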
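# dtnet

Topological profiling and candidate prediction of drug targets in
protein–protein interaction (PPI) networks.

## The problem

Approved drugs act on a small set of target proteins. dtnet asks whether
known targets occupy a distinctive position in the human interactome and,
where they do, uses that position to rank untested proteins as candidate
targets. The package is aimed at systems-biology and drug-discovery
analysts who have (a) an interaction edge list, (b) a list of known target
identifiers, and optionally (c) a per-protein table of chemical–physical
properties.

## The method

On the maximal connected component of the simple undirected graph
$G = (V, E)$, dtnet computes for every protein: degree $k_i$, betweenness
$Btwn(v) = \sum_{s \ne v \ne t} \sigma_{st}(v)/\sigma_{st}$ and its
min–max normalization $NB(v)$, eigenvector centrality ($Ax = \lambda x$ by
power iteration), local clustering, eccentricity
$\varepsilon(v) = \max_u d(v, u)$, average distance with the diameter
substitution ($d(v_i, v_j) = D_G$ for unreachable pairs), and coreness by
iterative $k$-core pruning.

On top of these it implements the three analysis stages:

* **Mesoscale enrichment.** Louvain modularity maximization of
  $Q = \frac{1}{2m}\sum_{ij}[A_{ij} - k_i k_j/2m]\,\delta(c_i, c_j)$,
  then per-community target-like ratios $rd(i) = D(i)/PT(i)$ (with
  $D(i) = i_D/|D|$, $PT(i) = i_{PT}/|PT|$) and per-coreness-shell ratios
  $rc_D(k) = p_k^D/DR$, $rc_{PT}(k) = p_k^{PT}/PR$.
* **Knockout experiments.** Delete the target set, re-extract the largest
  component, recompute metrics, and summarize the change (means, modal
  shifts, and the maximum ECDF gap between before/after distributions).
* **Candidate prediction.** With no curated non-target catalogue, a
  categorical naive Bayes over community and coreness (add-one smoothing,
  fixed 0.5 prior) scores the featured pending proteins; the lowest-scoring
  half becomes the negative training set. A linear SVM on the standardized
  chemical–physical properties is evaluated by stratified 10-fold
  cross-validation (pooled confusion matrix; accuracy, PPV, NPV) and called
  on the remaining pending proteins to yield candidates.

A degree-corrected planted-partition generator (`synthetic_spec()`,
`generate_study()`) produces labeled networks and feature tables with the
structure this analysis assumes — power-law degree tail, ~1.2% targets
concentrated in a few communities, degree-matched target planting — so the
whole pipeline is testable without database downloads.

## Worked example

The package ships a 16-protein hand-checkable fixture:

```r
library(dtnet)

net <- largest_connected_component(
  read_edge_list(system.file("extdata", "tiny_edges.tsv", package = "dtnet")))
labels <- assign_labels(net,
  read_labels(system.file("extdata", "tiny_targets.txt", package = "dtnet")),
  read_labels(system.file("extdata", "tiny_featured.txt", package = "dtnet")))
labels
#> <labeled_proteome>
#>   targets (D):              3
#>   pending, featured (PT1):  5
#>   pending, unfeatured (PT2):8
#>   total (P): 16   DR = 0.1875   PR = 0.8125

part <- detect_communities(net, seed = 1, min_report_size = 3)
glance(part)
#> # A tibble: 1 × 4
#>   n_communities n_main modularity  seed
#>           <int>  <int>      <dbl> <int>
#> 1             3      3      0.580     1

community_enrichment(part, labels)
#> # A tibble: 3 × 7
#>   community n_target n_pending target_share pending_share    rd target_like
#>   <chr>        <int>     <int>        <dbl>         <dbl> <dbl> <lgl>
#> 1 1                0         6        0             0.462   0   FALSE
#> 2 2                3         2        1             0.154   6.5 TRUE
#> 3 3                0         5        0             0.385   0   FALSE
```

All three known targets sit in community 2, whose target share (1.0) is 6.5
times its pending share (0.154): a target-like community ($rd > 1$). The
knockout stage quantifies how little the network changes when the targets
are removed:

```r
knockout_experiment(net, labels, metrics = c("degree", "eccentricity"))
#> # A tibble: 2 × 10
#>   metric       mean_before mean_after median_before median_after mode_before ...
#> 1 degree              3.5        2.92           4              3           4
#> 2 eccentricity        6.56       6.23           6.5            6           6
```

For a full synthetic study — generation, profiling, enrichment, knockout,
negative-set selection, cross-validated prediction — see the vignette
`vignettes/drug-target-topology.Rmd` and `run_pipeline()`, which writes
every stage as a seed-stamped TSV. A thin command-line wrapper with
`run`/`simulate`/`profile` subcommands is installed at
`inst/cli/dtnet.R`.

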
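# mlnetpath

Multilayer network integration and Boolean path discovery for multi-omics
cohorts.

## The problem

Deeply phenotyped cohorts in complex disease — the motivating case is
multiple sclerosis — measure the same subjects across biological scales:
SNP dosages and polygenic burden scores (genomics), kinase phosphorylation
(phosphoproteomics), immune cell subtype frequencies (cytomics), brain and
retinal imaging, and clinical outcomes.  `mlnetpath` is for analysts who
want to integrate such tables into one multilayer network and extract
*paths* — ordered chains of features across scales — that explain how
molecular variation propagates to the phenotype.

The package implements, as tested and reusable R functions:

* **Topological networks** — within- and between-layer edges weighted by
  normalized mutual information
  `I(X,Y) = Σ p(i,j) log[ p(i,j) / (pₓ(i) p_y(j)) ]` on 10 equally spaced
  bins, thresholded by a z-test against 1000 permutation surrogates at
  p < 0.05; weighted densities, degree tables, hubs, and Mann-Whitney
  degree comparisons.
* **A signed dynamic network** — Pearson edges (p < 0.05, weight `r`)
  within layers and between adjacent layers of the hierarchy genomics →
  proteomics → cytomics → imaging → clinical, with optional embedding of
  the SNP subnetwork through a TF→target regulatory reference.
* **Boolean simulations** — synchronous signed-threshold dynamics
  (`next = sign(Σ w·σ)`, σ = ±1, ties keep state) with 5% per-node noise, a
  driven input forced to a 10-on/10-off square wave for 100 steps, and
  100-replicate ensembles.
* **Path discovery** — per-edge maximum lagged cross-correlation `Cn`
  averaged over replicates; path score = Σ 1/C̄n along the path; top-10
  loopless paths per (input, output) pair via Yen's algorithm; percentile
  confidence intervals and jackknife stability; the full combinatorial
  screen (3,350 pairs at the study's cardinalities).
* **Negative controls** — degree-preserving double-edge-swap permutations
  (10 attempts per edge, weights travel with the endpoints), path
  occurrence counting across 100 permuted screens, and the <1% retention
  filter.
* **A synthetic cohort generator** — mixed marginals per layer, plantable
  cross-layer correlation chains, block missingness, exact weighted burden
  scores (152 non-HLA + 17 HLA loci at full scale), and a synthetic
  regulatory reference; it provides the ground truth for every calibration
  test.

## Worked example

Plant a five-layer dependency chain in a synthetic cohort, build the signed
network, drive the burden score, and rank paths to a clinical output:

```r
library(mlnetpath)

layers <- default_layers("test")
chain  <- chain_spec(c("MSGB_nonHLA", "MK03", "Total_T", "mRNFL", "EDSS"), 0.9)
cohort <- generate_cohort(layers, n_subjects = 300, chains = list(chain), seed = 42)

net <- build_dynamic_network(cohort)
#> ml_network: 30 nodes, 39 edges
#>   layers: clinical(4), cytomics(5), genomics(11), imaging(4), proteomics(6)
#>   hierarchy: genomics > proteomics > cytomics > imaging > clinical

ens <- run_ensemble(net, "MSGB_nonHLA", sim_config(seed = 7))
w   <- edge_correlation_weights(ens, net)
top <- k_shortest_paths(w, "MSGB_nonHLA", "EDSS", k = 10)
for (p in top[1:3]) cat(sprintf("%.2f  %s\n", p$score, path_string(p$nodes)))
#> 6.80  MSGB_nonHLA > MK03 > Total_T > mRNFL > EDSS
#> 8.08  MSGB_nonHLA > SNP004 > MK03 > Total_T > mRNFL > EDSS
#> 8.12  MSGB_nonHLA > SNP003 > MK03 > Total_T > mRNFL > EDSS
```

The planted chain is recovered as the best-scoring path (low score = the
chain of most strongly co-varying node pairs).  Replicate ensembles give
uncertainty and stability:

```r
ci <- path_confidence_interval(w, top[[1]]$nodes)
cat(sprintf("95%% CI of the top score: [%.2f, %.2f] over %d replicates\n",
            ci$low, ci$high, ci$n_used))
#> 95% CI of the top score: [5.40, 10.76] over 100 replicates

jackknife_stability(w, "MSGB_nonHLA", "EDSS", seed = 3)
#>  90  80
#> 9.6 9.7
```

On average 9.6 of the top-10 paths are unchanged when recomputed from 90 of
the 100 replicates.  `combinatorial_screen()` repeats this for every
(input, output) pair, `permutation_path_counts()` + `filter_paths()` screen
the results against degree-preserving nulls, and `run_pipeline()` /
`summarize_run()` execute and report all stages with one seed and a
checksummed manifest.  The methods, parameter choices and their rationale
are documented in `vignettes/multilayer-paths.Rmd`.

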
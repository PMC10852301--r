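---
title: "Multilayer networks and Boolean path discovery: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilayer networks and Boolean path discovery: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlnetpath)
```

# The problem

Complex diseases such as multiple sclerosis span biological scales: risk
alleles act through signaling proteins and immune cell populations, whose
dysregulation manifests as tissue damage visible on imaging and, ultimately,
as clinical disability.  `mlnetpath` treats a deeply phenotyped cohort as a
five-layer system — genomics (SNP dosages plus polygenic burden scores),
phosphoproteomics, cytomics, imaging, clinical — and asks two questions:

1. **Topology** — which features co-vary, within and across layers, once
   linear *and* nonlinear dependence is accounted for?
2. **Dynamics** — along which multiscale *paths* does a perturbation of a
   molecular input propagate to a phenotype output?

The first question is answered with mutual-information networks screened
against permutation surrogates; the second with noisy Boolean simulations on
a signed Pearson-correlation network, cross-correlation path scoring, and
degree-preserving permutation nulls.

# Topological networks

## Mutual information with surrogate thresholding

For a feature pair $(X, Y)$ each variable is split into 10 equally spaced
bins over its observed range and the plug-in estimator

$$I(X,Y) = \sum_{ij} p(i,j)\,\log\frac{p(i,j)}{p_x(i)\,p_y(j)}$$

is computed in nats.  Discrete variables with fewer than 10 distinct values
(allele dosages, ordinal clinical scores) use their observed values as bins:
equal-width bins would only create empty cells without changing any
probability.

The estimator is biased upward on finite samples, so a raw threshold on $I$
is meaningless.  Instead the subject order of each variable is permuted
independently 1000 times; the resulting surrogate distribution of MI values
is treated as Gaussian and the observed value must pass a one-sided z-test
at $p < 0.05$.  This is a per-pair rule by design — no multiple-testing
correction is applied, matching the published procedure.  Accepted edges
carry the *normalized* MI as weight.  The normalization is not fully
specified by its source beyond lying in $[0,1]$; we use
$I/\sqrt{H(X)\,H(Y)}$, which is symmetric and equals exactly 1 for identical
variables.  Natural logarithms are used throughout (the normalization is
base-free).

Two subject-filtering regimes exist on purpose: individual-layer networks
use pairwise-complete subjects per pair (maximizing the sample per test,
as different omics have different coverage), while the combined
density analysis uses the complete-case subset across all five layers so
that within- and between-layer densities are comparable.

Weighted density is $\sum w / n_\text{possible}$ with
$n_\text{possible} = n(n-1)/2$ within a layer and $|A|\,|B|$ between
layers.  Degree (unweighted edge count), per-layer means, and top-3 hubs
(ties broken lexicographically, so output is deterministic) summarize the
topology; degree distributions are compared with the two-sided Mann-Whitney
test, as the distributions are far from normal.

## What MI buys over Pearson

A noiseless quadratic dependence ($y = x^2$ with zero-mean $x$) produces a
Pearson correlation near zero but a large mutual information; the test suite
verifies that the surrogate-thresholded MI edge is accepted at $n = 200$
while the Pearson edge is not.  This is the motivation for using MI on the
heterogeneous mix of dosages, concentrations, volumes, and ordinal scales.

# The signed dynamic network

Boolean modeling needs edge *signs*, which MI cannot supply.  The dynamic
network therefore uses Pearson correlation: an edge is placed when the
two-sided test gives $p < 0.05$, weighted by $r \in [-1, 1]$.  Edges are
restricted to within-layer pairs and pairs of *adjacent* layers of the
hierarchy genomics → proteomics → cytomics → imaging → clinical; the
all-pairs mode remains available for topology only.  Burden scores and raw
SNPs are both present as genomics nodes by default (either can be switched
off), since reported paths traverse both kinds of node.

## Embedding the SNP network in a regulatory reference

SNP–SNP edges are additionally constrained by prior knowledge.  From a
TF → target reference restricted to the genes mapped by the SNPs, the
candidate gene graph contains the direct regulatory links plus an edge
between any two genes sharing a transcription factor (information that
would otherwise be lost by subsetting).  Genes are then replaced by their
SNPs — all pairs among SNPs of one gene, all cross pairs for connected
genes — and finally only candidates that also appear in the observed
Pearson SNP network are kept, with the observed weights.  The embedded edge
set is therefore always a subset of the data-driven one, with identical
signs; both properties are asserted in the tests.

# Boolean dynamics

Node states are binary (active/inactive).  Updates are synchronous: node
$i$'s next state is decided by the signed weighted sum over its neighbors
with states coded $\pm 1$,

$$s_i(t+1) = \begin{cases}
\text{active} & \sum_j w_{ij}\,\sigma_j(t) > 0\\
\text{inactive} & \sum_j w_{ij}\,\sigma_j(t) < 0\\
s_i(t) & \text{otherwise,}
\end{cases}
\qquad \sigma_j = \pm 1 .$$

In the canonical worked case — an inactive node with one active neighbor on
a $+0.8$ edge and one active neighbor on a $-0.5$ edge — the score is
$+0.3$ and the node becomes active.

Two conventions deserve comment because the update rule is stated in the
literature only by example:

* **$\pm 1$ neighbor coding.**  With $0/1$ coding an inactive neighbor
  contributes nothing, so a node fed by a single positive edge latches
  active after the first pulse and never tracks the falling edge of its
  driver.  With $\pm 1$ coding a positively coupled follower reproduces its
  driver exactly one step later and a negatively coupled follower its
  complement — the behavior the path analysis relies on.  Both codings give
  the identical $+0.3$ worked example.
* **Ties keep the previous state.**  A zero net input (isolated nodes, or
  exactly balanced neighborhoods) leaves the node unchanged, injecting no
  arbitrary bias.

Each simulation starts from a uniform random state (each node active with
probability 50%), runs 100 steps, and drives one input node with a square
wave of 10 steps active / 10 steps inactive; the drive overwrites the input
node at every step, so its trace is exactly periodic with period 20.  After
the deterministic update every non-driven node flips with probability 5%.
The noise level matters: without noise most nodes freeze, cross-correlations
saturate near 1, and edges cannot be ranked; 5% keeps enough variation to
discriminate strong from weak couplings.  100 replicate simulations are run
per input, with replicate seeds derived from one master seed so the whole
ensemble is reproducible bit for bit.

# Path scoring and ranking

For every *existing* network edge $(u, v)$ the maximum cross-correlation
$C_n$ between the two $\pm 1$ state signals is computed over lags
$0\ldots10$ (one drive half-period; the maximum over both orientations is
taken since edges are undirected, and information flows forward in time
from the driven input).  The full 100-step traces are used without burn-in:
the drive owns the input from step 0, and discarding steps would bias the
lag structure.  Per-replicate values are averaged and the edge weight in
the *path graph* is $1/\bar{C_n}$, so strong co-variation means low weight.
No new edges are ever created; edges with $\bar{C_n} \le 0.01$ are removed
(their inverse diverges and they carry no signal), and negative mean
correlations are excluded for the same reason — path scores must be sums of
positive terms.

A path's score is the sum of its edge weights; it favors short paths made
of strongly co-varying pairs.  The top $k = 10$ loopless paths per
(input, output) pair are found with Yen's algorithm, implemented in-package
so that ties break deterministically by lexicographic node sequence;
equivalence with exhaustive simple-path enumeration is asserted on random
graphs.  Path search is deliberately layer-unconstrained on the
hierarchical graph: within-layer hops (SNP → SNP, protein → protein) are
legitimate path segments.

Uncertainty: each replicate yields its own path score (replicates with a
non-positive $C_n$ on a path edge are excluded and counted), and the 95%
percentile band of these scores is reported.  Stability: the replicate
ensemble is jackknifed (10 draws of 90, then 80, of the 100 replicates),
the top-10 recomputed each time, and the mean overlap with the
full-ensemble top-10 reported.  On a strongly planted synthetic chain the
overlap is 9–10 of 10, mirroring the behavior reported for the original
cohort data.

The combinatorial screen enumerates every (input, output) pair — inputs are
burden scores, proteins, and cells; outputs are cells, imaging, and
clinical variables; at the study's cardinalities $(3 + 25 + 22) \times
(22 + 25 + 20) = 3350$ pairs.  One ensemble is simulated per input and
reused across its outputs.

# Negative controls

Specificity is assessed against degree-preserving network permutations:
double edge swaps, 10 attempts per edge, each rejected if it would create a
self-edge or duplicate an existing pair (attempts, not successes, are
counted, so rigid graphs terminate; a triangle is returned unchanged).
Weights travel with the rewired endpoints, preserving the weight multiset.
The full screen is re-run on each of 100 permuted networks — by default
with the same simulation seeds, isolating the effect of topology — and for
every original path we count the permuted screens whose top paths contain
the exact same node sequence.  Paths occurring in $\ge 1\%$ of permuted
screens are discarded (the inequality is strict: 1 of 100 is removed).
Swaps are unrestricted with respect to layers: a swap may turn an
inter-layer edge into a within-layer one, matching the generic published
description of the procedure.

# The synthetic cohort generator

No individual-level data from the original study is available, so the
package ships a generator that emulates the *statistical shape* of such a
cohort and doubles as the ground-truth harness for the tests.

* **Cardinalities.**  Full scale mirrors the study: 152 non-HLA + 17 HLA
  SNPs and 3 burden scores, 25 proteins, 22 cell subtypes, 25 imaging and
  20 clinical variables.  The test scale (6 + 2 SNPs, 3 scores, 6, 5, 4, 4)
  keeps simulation suites fast without changing any mechanism.
* **Marginals.**  The source data's marginal distributions are not
  published, so these are modeling choices: dosages by thresholding a
  Gaussian latent at Hardy-Weinberg cutpoints (MAF drawn uniformly from
  0.1–0.5); lognormal protein and cell levels ($e^{0.3 z}$, a coefficient
  of variation near 30%, typical of MFI ratios and cell frequencies);
  Gaussian imaging variables; clinical variables alternating Gaussian and
  a 0–8 ordinal score.  Burden scores are *computed* from the simulated
  dosages with the weighted-sum score, never simulated directly, so the
  exact partition identity total = HLA + non-HLA holds by construction.
* **Planted chains.**  Cross-layer dependency chains are generated by
  Gaussian-copula propagation: each link's feature is conditionally
  Gaussian given the *observed* value of its predecessor, with the target
  link correlation as the conditional coefficient, then pushed through the
  layer's marginal transform.  For (near-)continuous marginals the realized
  Pearson link correlation matches the target to within a few percent; the
  coarse dosage thresholding attenuates it more strongly, which is why the
  generator contract (links within ±0.1 of the target at $n = 500$) is
  stated for chains over continuous features.  A burden score may only
  start a chain (it is a derived column).
* **Missingness** is per subject-layer block — a subject lacks an entire
  layer — reproducing the complete-case structure of multi-omics cohorts
  (the study's five-layer analyses rest on 67 complete-case subjects).
* **Not emulated:** linkage disequilibrium between SNPs, batch and center
  effects, longitudinal structure, treatment effects, and realistic
  missing-not-at-random patterns.  Passing tests therefore demonstrate
  method correctness and calibration on known ground truth, not clinical
  validity on real cohorts.

# Numerical and design choices

* Surrogate permutations shuffle *both* variables independently (as
  published); marginal bin occupancies are permutation-invariant, which the
  implementation exploits for speed.
* Zero-variance inputs yield MI 0 / "degenerate", not an exception, so
  screening loops never abort on a constant feature.
* The one-sided surrogate z-test requires $z > 0$; a zero surrogate
  standard deviation marks the pair degenerate and rejects it.
* Dijkstra/Yen use a $10^{-12}$ tolerance when comparing path scores for
  tie-breaking; weights from inverse correlations are continuous, so exact
  ties essentially only arise in constructed examples.
* Replicate and stage seeds are derived from one master seed and recorded,
  so any single trace can be reproduced in isolation.
* Problem sizes in the shipped tests: type-I calibration on 1000
  independent pairs at $n = 200$; oracle equivalence on 50 random graphs of
  at most 7 nodes; planted-chain recovery over 20 cohorts of $n = 300$ at
  the test scale with 100-replicate ensembles; permutation invariants over
  100 permuted graphs.

# Orchestration

`run_pipeline()` executes synth/load → topological networks → dynamic
network (with optional GRN embedding) → combinatorial screen → permutation
nulls → report, writing every artifact (TSV/GraphML/JSON) plus a
checksummed manifest under one output directory; `summarize_run()` returns
the report tables, including each node's *path degree* — the share of
retained paths it appears in, overall and per input layer.  All stages are
ordinary exported functions, so any stage can be re-run on prior outputs
from R.

# Known limitations

* The MI estimator's positive bias is handled by calibration (surrogates),
  not bias correction; normalized MI values are comparable within, not
  across, sample sizes.
* Per-pair $\alpha = 0.05$ without correction reproduces the published
  rule but implies a known false-edge rate; downstream permutation nulls,
  not edge-level corrections, provide specificity.
* The Boolean abstraction discards dose-response information; edge signs
  from cross-sectional correlations need not be causal directions.
* Yen's algorithm is exact but $O(k\,n^3)$ in the worst case with the dense
  matrix used here; it is comfortable for networks of a few hundred nodes,
  which covers the study's scale.
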
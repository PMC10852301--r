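Package: mlnetpath
Title: Multilayer Network Integration and Boolean Path Discovery for
    Multi-Omics Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds multilayer networks from multi-omics cohort data
    (genomics, phosphoproteomics, cytomics, imaging, clinical) and
    discovers multiscale paths from molecular inputs to phenotype
    outputs.  Within- and between-layer edges are inferred by binned
    mutual information against permutation-surrogate nulls, or by
    Pearson correlation for a signed network used in dynamics.  Noisy
    synchronous Boolean simulations with a periodically driven input
    probe information flow; paths are scored by summed inverse
    cross-correlations, ranked with Yen's k-shortest loopless paths,
    screened combinatorially over all input-output pairs, and filtered
    against degree-preserving network permutation nulls.  Includes a
    synthetic cohort generator with plantable cross-layer correlation
    chains, a weighted polygenic burden score (HLA / non-HLA
    partitions), and a synthetic gene-regulatory reference for
    embedding SNP networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
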
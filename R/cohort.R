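#' Layer specification
#'
#' Describes one layer of the multilayer cohort: its name, feature names, and
#' which features are eligible as path inputs (driven nodes) and/or outputs
#' (path targets).  Default roles follow the study design: inputs are the
#' genetic-burden scores, proteins and cell subtypes; outputs are cells,
#' imaging and clinical variables.
#'
#' Genomics features whose names start with `"MSGB"` are treated as
#' genetic-burden score columns computed from the SNP dosages (not simulated
#' directly); the three canonical names are `MSGB_total`, `MSGB_HLA` and
#' `MSGB_nonHLA`.
#'
#' @param name layer name, one of `"genomics"`, `"proteomics"`, `"cytomics"`,
#'   `"imaging"`, `"clinical"`.
#' @param features character vector of feature names (unique).
#' @param input,output logical vectors (recycled) flagging role eligibility.
#' @return a `layer_spec` object.
#' @export
layer_spec <- function(name, features,
                       input = FALSE, output = FALSE) {
  name <- match.arg(name, layer_hierarchy())
  features <- as.character(features)
  if (anyDuplicated(features)) stop("duplicate feature names in layer ", name)
  structure(list(name = name,
                 features = features,
                 input = rep_len(as.logical(input), length(features)),
                 output = rep_len(as.logical(output), length(features))),
            class = "layer_spec")
}

#' The ordered layer chain of the multilayer hierarchy
#' @return character vector of the five layer names, bottom to top.
#' @export
layer_hierarchy <- function() {
  c("genomics", "proteomics", "cytomics", "imaging", "clinical")
}

protein_names <- function(n) {
  base <- c("MK03", "GSK3AB", "HSPB1", "IKBA", "STAT6", "RS6", "KS6B1",
            "MP2K1", "STAT1", "STAT3", "P38", "AKT1", "CREB1", "ERK1",
            "JUN", "SRC", "WNK1", "PTN11", "TF65", "FAK1", "MK01",
            "MP2K2", "RS6KA1", "STAT5", "GSK3B")
  base[seq_len(n)]
}

cell_names <- function(n) {
  base <- c("Total_T", "Th17", "CD8_Treg", "B_Memory", "CD56_neg",
            "CD4_T", "CD8_T", "B_cells", "NK_cells", "Th1_classic",
            "Th1_17", "Th1_nonclassic", "Total_Treg", "T_naive_CD4",
            "CD8_T_naive", "B_mature", "B_regulatory", "NK_effector",
            "NK_regulatory", "CD56_bright", "NKT", "Monocytes")
  base[seq_len(n)]
}

imaging_names <- function(n) {
  base <- c("mRNFL", "INL", "NBV", "NGMV", "pRNFL", "GCIPL", "NWMV",
            "T2LV", "T1LV", "thalamus_vol")
  c(base, sprintf("IMG%02d", seq_len(max(0L, n - length(base)))))[seq_len(n)]
}

clinical_names <- function(n) {
  base <- c("EDSS", "ARMSS", "T25WT", "SDMT", "HCVA", "LCVA", "NHPT",
            "relapses", "disease_duration", "MSSS")
  c(base, sprintf("CLIN%02d", seq_len(max(0L, n - length(base)))))[seq_len(n)]
}

#' Default five-layer specifications
#'
#' `"full"` mirrors the study's cardinalities: 152 non-HLA + 17 HLA SNPs and
#' 3 burden scores in genomics, 25 proteins, 22 cell subtypes, 25 imaging and
#' 20 clinical variables.  `"test"` is a reduced set (6 + 2 SNPs, 3 scores,
#' 6, 5, 4, 4) for fast simulation studies.
#'
#' @param scale `"full"` or `"test"`.
#' @return a named list of [layer_spec()] objects in hierarchy order.
#' @export
default_layers <- function(scale = c("test", "full")) {
  scale <- match.arg(scale)
  dims <- if (scale == "full") {
    list(non_hla = 152L, hla = 17L, prot = 25L, cyto = 22L,
         img = 25L, clin = 20L)
  } else {
    list(non_hla = 6L, hla = 2L, prot = 6L, cyto = 5L, img = 4L, clin = 4L)
  }
  snps <- c(sprintf("SNP%03d", seq_len(dims$non_hla)),
            sprintf("HLA%02d", seq_len(dims$hla)))
  scores <- c("MSGB_total", "MSGB_HLA", "MSGB_nonHLA")
  genomics <- layer_spec("genomics", c(scores, snps),
                         input = c(rep(TRUE, 3L), rep(FALSE, length(snps))),
                         output = FALSE)
  list(
    genomics   = genomics,
    proteomics = layer_spec("proteomics", protein_names(dims$prot),
                            input = TRUE, output = FALSE),
    cytomics   = layer_spec("cytomics", cell_names(dims$cyto),
                            input = TRUE, output = TRUE),
    imaging    = layer_spec("imaging", imaging_names(dims$img),
                            input = FALSE, output = TRUE),
    clinical   = layer_spec("clinical", clinical_names(dims$clin),
                            input = FALSE, output = TRUE)
  )
}

#' Planted cross-layer dependency chain
#'
#' An ordered list of features spanning (same or adjacent) layers, with a
#' target Pearson correlation per consecutive link.  The cohort generator
#' propagates a Gaussian latent along the chain so that each link attains its
#' target correlation in expectation (monotone marginal transforms such as
#' dosage thresholding attenuate the realized correlation slightly; see the
#' vignette).
#'
#' @param features ordered character vector of feature names (>= 2).
#' @param strength per-link correlation in (-1, 1); recycled to
#'   `length(features) - 1`.
#' @param noise_scale multiplier on the conditional noise (default 1 keeps
#'   the target correlation exact on the latent scale).
#' @return a `chain_spec` object.
#' @export
chain_spec <- function(features, strength = 0.9, noise_scale = 1) {
  features <- as.character(features)
  if (length(features) < 2L) stop("a chain needs at least 2 features")
  strength <- rep_len(strength, length(features) - 1L)
  if (any(abs(strength) >= 1)) stop("chain strengths must lie in (-1, 1)")
  structure(list(features = features, strength = strength,
                 noise_scale = noise_scale),
            class = "chain_spec")
}

#' Generate weights for the genetic burden score
#'
#' Synthetic per-locus effect sizes (log-odds scale) with an HLA / non-HLA
#' partition.  Non-HLA effects are small (0.03-0.3); HLA effects are larger
#' (0.1-0.9), reflecting the dominant contribution of the HLA class II
#' region to MS risk.
#'
#' @param loci character vector of locus identifiers; default matches the
#'   full-scale layer specification (152 non-HLA + 17 HLA).
#' @param hla logical vector flagging HLA loci; default: names starting with
#'   `"HLA"`.
#' @param seed integer RNG seed.
#' @return data.frame with columns `locus`, `beta`, `hla`.
#' @export
msgb_weights <- function(loci = NULL, hla = NULL, seed = 1L) {
  if (is.null(loci)) {
    loci <- c(sprintf("SNP%03d", 1:152), sprintf("HLA%02d", 1:17))
  }
  if (anyDuplicated(loci)) stop("duplicate loci")
  if (is.null(hla)) hla <- startsWith(loci, "HLA")
  hla <- rep_len(as.logical(hla), length(loci))
  set.seed(seed)
  beta <- ifelse(hla, stats::runif(length(loci), 0.1, 0.9),
                 stats::runif(length(loci), 0.03, 0.3))
  data.frame(locus = loci, beta = beta, hla = hla, stringsAsFactors = FALSE)
}

#' Compute the weighted genetic burden score
#'
#' Per-subject weighted sum of risk-allele dosages: `score_s = sum_i beta_i *
#' dosage_{s,i}` over the chosen locus subset.  The total score equals the
#' HLA plus the non-HLA partial scores elementwise.
#'
#' @param genotypes subjects x loci matrix of allele dosages in `{0, 1, 2}`
#'   (column names are locus ids; `NA` rows propagate to `NA` scores).
#' @param weights data.frame from [msgb_weights()].
#' @param subset `"all"`, `"hla"` or `"non_hla"`.
#' @return named numeric vector of per-subject scores.
#' @export
compute_msgb <- function(genotypes, weights,
                         subset = c("all", "hla", "non_hla")) {
  subset <- match.arg(subset)
  if (subset == "all") {
    # computed as the sum of the partial scores so that the partition
    # identity total = hla + non_hla holds exactly, not just numerically
    return(compute_msgb(genotypes, weights, "hla") +
             compute_msgb(genotypes, weights, "non_hla"))
  }
  w <- if (subset == "hla") weights[weights$hla, , drop = FALSE] else
    weights[!weights$hla, , drop = FALSE]
  missing_loci <- setdiff(w$locus, colnames(genotypes))
  if (length(missing_loci)) {
    stop("loci absent from genotype matrix: ",
         paste(missing_loci, collapse = ", "))
  }
  g <- genotypes[, w$locus, drop = FALSE]
  vals <- g[!is.na(g)]
  if (length(vals) && (any(vals %% 1 != 0) || any(vals < 0 | vals > 2))) {
    stop("dosages must be integers in [0, 2]")
  }
  drop(g %*% w$beta)
}

# marginal transform per layer: latent N(0,1) -> observed value
marginal_transform <- function(z, layer, feature, maf = NULL,
                               ordinal = FALSE) {
  switch(layer,
    genomics = {
      # HWE genotype frequencies -> dosage by thresholding the latent
      q0 <- (1 - maf)^2
      q1 <- q0 + 2 * maf * (1 - maf)
      cuts <- stats::qnorm(c(q0, q1))
      as.numeric(findInterval(z, cuts))
    },
    proteomics = exp(0.3 * z),   # lognormal phosphorylation level, CV ~ 0.31
    cytomics = exp(0.3 * z),     # lognormal cell frequency
    imaging = z,                 # standardized volume / thickness
    clinical = if (ordinal) pmin(pmax(round(2 + 1.5 * z), 0), 8) else z
  )
}

#' Generate a synthetic multilayer cohort
#'
#' Simulates subjects x features tables for the five layers with mixed
#' marginals (allele dosages by latent thresholding under Hardy-Weinberg
#' proportions, lognormal protein and cell levels, Gaussian imaging,
#' Gaussian + ordinal clinical scores), optional planted cross-layer
#' correlation chains, and per subject-layer block missingness (a subject is
#' missing an entire layer, yielding a well-defined complete-case subset).
#' Burden-score columns in the genomics layer are computed from the simulated
#' dosages with [compute_msgb()].
#'
#' Features not on any chain are mutually independent (burden scores are
#' deterministic functions of the dosages and therefore correlate with their
#' own SNPs).  Chain latents are propagated left to right, each feature
#' conditionally Gaussian given the observed value of its predecessor, so
#' each link attains its target correlation in expectation.
#'
#' @param layers named list of [layer_spec()] objects (see
#'   [default_layers()]).
#' @param n_subjects number of subjects (>= 10).
#' @param chains list of [chain_spec()] objects; chain features must be
#'   unique across chains, consecutive features must lie in the same or
#'   adjacent layers, and a burden-score column may only appear as the first
#'   feature of a chain.
#' @param missing_rate probability in `[0, 1)` that a subject is missing a
#'   given layer.
#' @param seed integer RNG seed (identical seed, identical cohort).
#' @param weights optional burden-score weights (data.frame as from
#'   [msgb_weights()]); defaults to weights generated for the layer's SNPs.
#' @return an `ml_cohort`: list with `subjects`, `layers` (named list of
#'   value matrices), `spec`, `roles` (`input` / `output` feature names),
#'   `weights` and `feature_layer` (named lookup).
#' @export
generate_cohort <- function(layers, n_subjects, chains = list(),
                            missing_rate = 0, seed = NULL, weights = NULL) {
  if (n_subjects < 10L) stop("n_subjects must be >= 10")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)")
  }
  if (inherits(chains, "chain_spec")) chains <- list(chains)
  all_feats <- unlist(lapply(layers, `[[`, "features"), use.names = FALSE)
  if (anyDuplicated(all_feats)) stop("feature names must be unique across layers")
  feature_layer <- stats::setNames(
    rep(vapply(layers, `[[`, "", "name"),
        vapply(layers, function(l) length(l$features), 0L)),
    all_feats)

  score_feats <- all_feats[startsWith(all_feats, "MSGB") &
                             feature_layer[all_feats] == "genomics"]
  snp_feats <- setdiff(names(feature_layer)[feature_layer == "genomics"],
                       score_feats)

  # validate chains
  hier <- layer_hierarchy()
  successors <- character()
  for (ch in chains) {
    unknown <- setdiff(ch$features, all_feats)
    if (length(unknown)) {
      stop("chain references unknown feature(s): ",
           paste(unknown, collapse = ", "))
    }
    pos <- match(feature_layer[ch$features], hier)
    if (any(abs(diff(pos)) > 1L)) {
      stop("consecutive chain features must lie in the same or adjacent layers")
    }
    if (any(ch$features[-1L] %in% score_feats)) {
      stop("a burden score may only be the first feature of a chain")
    }
    successors <- c(successors, ch$features[-1L])
  }
  if (anyDuplicated(unlist(lapply(chains, `[[`, "features")))) {
    stop("chain features must be unique across chains")
  }

  if (!is.null(seed)) set.seed(seed)

  if (is.null(weights)) {
    weights <- msgb_weights(loci = snp_feats,
                            seed = sample.int(.Machine$integer.max, 1L))
  }
  maf <- stats::setNames(stats::runif(length(snp_feats), 0.1, 0.5), snp_feats)

  subjects <- sprintf("S%04d", seq_len(n_subjects))
  values <- matrix(NA_real_, n_subjects, length(all_feats),
                   dimnames = list(subjects, all_feats))

  clin_feats <- names(feature_layer)[feature_layer == "clinical"]
  ordinal_clin <- clin_feats[seq_along(clin_feats) %% 2L == 1L]

  gen_feature <- function(feat, z) {
    lay <- feature_layer[[feat]]
    marginal_transform(z, lay, feat,
                       maf = if (lay == "genomics") maf[[feat]] else NULL,
                       ordinal = feat %in% ordinal_clin)
  }

  # independent features first (everything except chain successors and scores)
  base_feats <- setdiff(all_feats, c(successors, score_feats))
  for (feat in base_feats) {
    values[, feat] <- gen_feature(feat, stats::rnorm(n_subjects))
  }

  # burden scores from the dosages
  if (length(score_feats)) {
    geno <- values[, snp_feats, drop = FALSE]
    for (sc in score_feats) {
      sub <- switch(sc,
                    MSGB_total = "all", MSGB_HLA = "hla",
                    MSGB_nonHLA = "non_hla",
                    stop("unrecognized burden-score column: ", sc))
      values[, sc] <- compute_msgb(geno, weights, sub)
    }
  }

  # propagate chains left to right, conditioning on observed predecessors
  for (ch in chains) {
    for (j in seq_along(ch$strength)) {
      prev <- values[, ch$features[j]]
      rho <- ch$strength[j]
      z <- rho * as.numeric(scale(prev)) +
        ch$noise_scale * sqrt(1 - rho^2) * stats::rnorm(n_subjects)
      z <- as.numeric(scale(z))
      values[, ch$features[j + 1L]] <- gen_feature(ch$features[j + 1L], z)
    }
  }

  layer_mats <- lapply(layers, function(l) {
    values[, l$features, drop = FALSE]
  })
  names(layer_mats) <- vapply(layers, `[[`, "", "name")

  # block missingness: a subject lacks an entire layer
  if (missing_rate > 0) {
    for (lay in names(layer_mats)) {
      drop_row <- stats::runif(n_subjects) < missing_rate
      layer_mats[[lay]][drop_row, ] <- NA_real_
    }
  }

  roles <- list(
    input = unlist(lapply(layers, function(l) l$features[l$input]),
                   use.names = FALSE),
    output = unlist(lapply(layers, function(l) l$features[l$output]),
                    use.names = FALSE)
  )

  structure(list(subjects = subjects, layers = layer_mats, spec = layers,
                 roles = roles, weights = weights,
                 feature_layer = feature_layer),
            class = "ml_cohort")
}

#' @export
print.ml_cohort <- function(x, ...) {
  cat("ml_cohort:", length(x$subjects), "subjects\n")
  for (lay in names(x$layers)) {
    m <- x$layers[[lay]]
    cc <- sum(stats::complete.cases(m))
    cat(sprintf("  %-10s %3d features, %d complete subjects\n",
                lay, ncol(m), cc))
  }
  invisible(x)
}

#' Subjects with complete data across the given layers
#' @param cohort an `ml_cohort`.
#' @param layers character vector of layer names (default: all).
#' @return character vector of subject ids.
#' @export
complete_subjects <- function(cohort, layers = names(cohort$layers)) {
  ok <- rep(TRUE, length(cohort$subjects))
  for (lay in layers) {
    ok <- ok & stats::complete.cases(cohort$layers[[lay]])
  }
  cohort$subjects[ok]
}

#' Generate a synthetic gene-regulatory reference
#'
#' A TF -> target edge list over synthetic gene identifiers plus a SNP ->
#' gene map (several SNPs may map to one gene), emulating the structure of a
#' tissue-specific regulatory-network database used to embed SNP networks.
#'
#' @param n_tfs number of transcription factors (0 allowed: empty edge list).
#' @param n_genes number of target genes.
#' @param snps_per_gene integer scalar (constant per gene) or vector of
#'   length `n_genes`; ignored when `snp_names` is given.
#' @param seed RNG seed.
#' @param snp_names optional SNP identifiers to map; each is assigned to one
#'   gene uniformly at random.
#' @param tfs_per_gene range of regulators sampled per gene.
#' @return a `grn_reference`: list with `edges` (data.frame `tf`, `target`)
#'   and `snp_to_gene` (data.frame `snp`, `gene`).
#' @export
generate_grn <- function(n_tfs, n_genes, snps_per_gene = 2L, seed = 1L,
                         snp_names = NULL, tfs_per_gene = 1:2) {
  if (n_tfs < 0 || n_genes <= 0) stop("counts must be positive")
  set.seed(seed)
  tfs <- if (n_tfs > 0) sprintf("TF%02d", seq_len(n_tfs)) else character()
  genes <- sprintf("G%03d", seq_len(n_genes))
  edges <- if (n_tfs > 0) {
    do.call(rbind, lapply(genes, function(g) {
      k <- sample(tfs_per_gene, 1L)
      data.frame(tf = sample(tfs, min(k, n_tfs)), target = g,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(tf = character(), target = character(), stringsAsFactors = FALSE)
  }
  if (is.null(snp_names)) {
    counts <- rep_len(snps_per_gene, n_genes)
    snp_names <- sprintf("SNP%03d", seq_len(sum(counts)))
    gene_of <- rep(genes, counts)
  } else {
    gene_of <- sample(genes, length(snp_names), replace = TRUE)
  }
  structure(list(edges = edges,
                 snp_to_gene = data.frame(snp = snp_names, gene = gene_of,
                                          stringsAsFactors = FALSE)),
            class = "grn_reference")
}

#' Write / read a cohort as per-layer TSV tables
#'
#' One delimited table per layer with a `subject_id` column, plus a JSON
#' manifest recording layer membership and input/output roles.
#'
#' @param cohort an `ml_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir` (write) or an `ml_cohort` (read), invisibly for write.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (lay in names(cohort$layers)) {
    df <- data.frame(subject_id = cohort$subjects,
                     cohort$layers[[lay]], check.names = FALSE)
    utils::write.table(df, file.path(dir, paste0(lay, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    layers = lapply(cohort$layers, colnames),
    roles = cohort$roles,
    subjects = cohort$subjects
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  if (!is.null(cohort$weights)) {
    utils::write.table(cohort$weights, file.path(dir, "msgb_weights.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  layer_names <- names(manifest$layers)
  layer_mats <- lapply(layer_names, function(lay) {
    df <- utils::read.delim(file.path(dir, paste0(lay, ".tsv")),
                            check.names = FALSE,
                            colClasses = c(subject_id = "character"))
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$subject_id
    m
  })
  names(layer_mats) <- layer_names
  feature_layer <- stats::setNames(
    rep(layer_names, vapply(layer_mats, ncol, 0L)),
    unlist(lapply(layer_mats, colnames), use.names = FALSE))
  wpath <- file.path(dir, "msgb_weights.tsv")
  weights <- if (file.exists(wpath)) utils::read.delim(wpath) else NULL
  structure(list(subjects = manifest$subjects, layers = layer_mats,
                 spec = NULL, roles = manifest$roles, weights = weights,
                 feature_layer = feature_layer),
            class = "ml_cohort")
}

#' Write / read a gene-regulatory reference as 2-column TSVs
#' @param grn a `grn_reference`.
#' @param dir output directory.
#' @export
write_grn <- function(grn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(grn$edges, file.path(dir, "grn_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(grn$snp_to_gene, file.path(dir, "snp_to_gene.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_grn
#' @export
read_grn <- function(dir) {
  structure(list(
    edges = utils::read.delim(file.path(dir, "grn_edges.tsv"),
                              stringsAsFactors = FALSE),
    snp_to_gene = utils::read.delim(file.path(dir, "snp_to_gene.tsv"),
                                    stringsAsFactors = FALSE)
  ), class = "grn_reference")
}
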
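#' Pearson correlation edge test
#'
#' An edge is accepted when the two-sided p-value of the correlation test is
#' below `alpha`; the correlation coefficient itself (signed, in \[-1, 1\])
#' becomes the edge weight.  No multiple-testing correction is applied; the
#' per-pair rule is intentional.
#'
#' @param x,y numeric vectors (>= 4 pairwise-complete observations).
#' @param alpha significance level (default 0.05).
#' @return list with `r`, `p_value`, `accepted`, `degenerate`.
#' @export
pearson_edge <- function(x, y, alpha = 0.05) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, accepted = FALSE,
                degenerate = TRUE))
  }
  ct <- stats::cor.test(x, y)
  r <- unname(ct$estimate)
  p <- ct$p.value
  accepted <- is.finite(p) && p < alpha
  # a numerically perfect correlation can give p = 0 with r = +/-1
  if (abs(r) >= 1 - 1e-12) accepted <- TRUE
  list(r = r, p_value = p, accepted = accepted, degenerate = FALSE)
}

#' Build the signed five-layer network used for Boolean dynamics
#'
#' Pearson edges (at `alpha`) within every layer, and between layers only
#' when the layers are adjacent in the hierarchy chain genomics ->
#' proteomics -> cytomics -> imaging -> clinical.  Computed on the subjects
#' with complete data in all included layers, so the signed weights are
#' mutually consistent.  The genomics layer contains both the burden scores
#' and the raw SNP dosages (drop either with the flags).
#'
#' @param cohort an `ml_cohort` with all five layers.
#' @param hierarchy ordered layer chain (default [layer_hierarchy()]).
#' @param alpha per-pair significance level.
#' @param include_snps,include_scores keep SNP / burden-score nodes in the
#'   genomics layer.
#' @return a signed `ml_network` with the hierarchy attached.
#' @export
build_dynamic_network <- function(cohort, hierarchy = layer_hierarchy(),
                                  alpha = 0.05, include_snps = TRUE,
                                  include_scores = TRUE) {
  missing_layers <- setdiff(hierarchy, names(cohort$layers))
  if (length(missing_layers)) {
    stop("cohort is missing layer(s): ", paste(missing_layers, collapse = ", "))
  }
  cc <- complete_subjects(cohort, hierarchy)
  if (length(cc) < 4L) stop("fewer than 4 complete-case subjects")

  mats <- lapply(hierarchy, function(lay) {
    m <- cohort$layers[[lay]][cc, , drop = FALSE]
    if (lay == "genomics") {
      is_score <- startsWith(colnames(m), "MSGB")
      keep <- (is_score & include_scores) | (!is_score & include_snps)
      m <- m[, keep, drop = FALSE]
    }
    m
  })
  names(mats) <- hierarchy

  pearson_scan <- function(ma, mb = NULL) {
    within <- is.null(mb)
    if (within) mb <- ma
    rows <- list()
    for (i in seq_len(ncol(ma))) {
      j0 <- if (within) i + 1L else 1L
      if (j0 > ncol(mb)) next
      for (j in j0:ncol(mb)) {
        pe <- pearson_edge(ma[, i], mb[, j], alpha = alpha)
        if (isTRUE(pe$accepted)) {
          rows[[length(rows) + 1L]] <-
            data.frame(from = colnames(ma)[i], to = colnames(mb)[j],
                       weight = pe$r, method = "Pearson",
                       stringsAsFactors = FALSE)
        }
      }
    }
    if (length(rows)) do.call(rbind, rows) else empty_edges()
  }

  edges <- list()
  for (lay in hierarchy) {
    if (ncol(mats[[lay]]) >= 2L) edges[[length(edges) + 1L]] <- pearson_scan(mats[[lay]])
  }
  for (i in seq_len(length(hierarchy) - 1L)) {
    edges[[length(edges) + 1L]] <-
      pearson_scan(mats[[hierarchy[i]]], mats[[hierarchy[i + 1L]]])
  }
  edges <- do.call(rbind, edges)

  nodes <- do.call(rbind, lapply(hierarchy, function(lay) {
    data.frame(id = colnames(mats[[lay]]), layer = lay,
               stringsAsFactors = FALSE)
  }))
  ml_network(nodes, edges, hierarchy = hierarchy)
}

#' Embed a SNP network through a gene-regulatory reference
#'
#' Constructs the candidate gene graph from the regulatory reference
#' restricted to the mapped genes: direct TF -> target links among mapped
#' genes, plus an edge between any two genes sharing a transcription factor.
#' Genes are then replaced by their SNPs (all-pairs edges among SNPs mapped
#' to the same gene, and all cross pairs for connected genes).  Finally only
#' candidate edges that also appear in the Pearson SNP network are kept,
#' carrying the Pearson weights.
#'
#' @param snp_network a signed `ml_network` whose nodes are SNPs.
#' @param grn a `grn_reference` mapping every SNP in `snp_network` to a gene.
#' @return a signed `ml_network` over the same SNPs whose edge set is a
#'   subset of `snp_network`'s.
#' @export
embed_grn <- function(snp_network, grn) {
  snps <- snp_network$nodes$id
  map <- grn$snp_to_gene
  unmapped <- setdiff(snps, map$snp)
  if (length(unmapped)) {
    stop("SNP(s) not mapped to a gene: ", paste(unmapped, collapse = ", "))
  }
  map <- map[map$snp %in% snps, , drop = FALSE]
  genes <- unique(map$gene)

  # gene-level candidate edges: direct regulatory links among mapped genes
  ge <- grn$edges
  direct <- ge[ge$tf %in% genes & ge$target %in% genes, c("tf", "target")]
  names(direct) <- c("a", "b")
  # shared-TF edges: all pairs of mapped targets of one TF
  shared <- do.call(rbind, lapply(split(ge$target, ge$tf), function(tg) {
    tg <- sort(unique(tg[tg %in% genes]))
    if (length(tg) < 2L) return(NULL)
    cmb <- utils::combn(tg, 2L)
    data.frame(a = cmb[1L, ], b = cmb[2L, ], stringsAsFactors = FALSE)
  }))
  gene_pairs <- unique(rbind(direct, shared))
  gene_pairs <- gene_pairs[gene_pairs$a != gene_pairs$b, , drop = FALSE]

  snps_of <- split(map$snp, map$gene)
  cand <- character()
  # same-gene SNPs: all pairs
  for (g in names(snps_of)) {
    s <- sort(snps_of[[g]])
    if (length(s) >= 2L) {
      cmb <- utils::combn(s, 2L)
      cand <- c(cand, edge_key(cmb[1L, ], cmb[2L, ]))
    }
  }
  # connected genes: all SNP cross pairs
  if (!is.null(gene_pairs) && nrow(gene_pairs)) {
    for (r in seq_len(nrow(gene_pairs))) {
      sa <- snps_of[[gene_pairs$a[r]]]
      sb <- snps_of[[gene_pairs$b[r]]]
      if (is.null(sa) || is.null(sb)) next
      grid <- expand.grid(sa, sb, stringsAsFactors = FALSE)
      grid <- grid[grid[[1L]] != grid[[2L]], , drop = FALSE]
      cand <- c(cand, edge_key(grid[[1L]], grid[[2L]]))
    }
  }
  cand <- unique(cand)

  keep <- edge_key(snp_network$edges$from, snp_network$edges$to) %in% cand
  ml_network(snp_network$nodes, snp_network$edges[keep, , drop = FALSE],
             hierarchy = snp_network$hierarchy)
}

#' Replace the SNP-SNP edges of a dynamic network by their GRN embedding
#'
#' Convenience wrapper: extracts the SNP subnetwork of a five-layer signed
#' network, embeds it with [embed_grn()], and splices the retained SNP-SNP
#' edges back (all other edges unchanged).
#'
#' @param network signed five-layer `ml_network`.
#' @param grn a `grn_reference` covering the network's SNPs.
#' @return the network with its SNP-SNP edge set restricted.
#' @export
apply_grn <- function(network, grn) {
  is_snp <- network$nodes$layer == "genomics" &
    !startsWith(network$nodes$id, "MSGB")
  snp_ids <- network$nodes$id[is_snp]
  snp_edge <- network$edges$from %in% snp_ids & network$edges$to %in% snp_ids
  sub <- ml_network(network$nodes[is_snp, , drop = FALSE],
                    network$edges[snp_edge, , drop = FALSE])
  kept <- embed_grn(sub, grn)
  ml_network(network$nodes,
             rbind(network$edges[!snp_edge, , drop = FALSE], kept$edges),
             hierarchy = network$hierarchy)
}
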
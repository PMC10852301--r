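#' Configuration for topological (mutual-information) network construction
#'
#' @param n_bins histogram bins for the MI estimator.
#' @param n_surrogates permutation surrogates per pair.
#' @param alpha per-pair significance level of the surrogate z-test.
#' @return a list of settings.
#' @export
topo_config <- function(n_bins = 10L, n_surrogates = 1000L, alpha = 0.05) {
  list(n_bins = n_bins, n_surrogates = n_surrogates, alpha = alpha)
}

# run the surrogate test for every (i, j) pair of columns between two
# matrices (within-mode when b is NULL), returning accepted MI edges
mi_edge_scan <- function(mat_a, mat_b = NULL, config, pairwise = TRUE) {
  within <- is.null(mat_b)
  if (within) mat_b <- mat_a
  fa <- colnames(mat_a); fb <- colnames(mat_b)
  rows <- list()
  for (i in seq_along(fa)) {
    js <- if (within) seq_len(ncol(mat_b)) > i else seq_len(ncol(mat_b)) > 0
    for (j in which(js)) {
      x <- mat_a[, i]; y <- mat_b[, j]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 5L) next
      dec <- surrogate_edge_test(x[ok], y[ok], n_bins = config$n_bins,
                                 n_surrogates = config$n_surrogates,
                                 alpha = config$alpha)
      if (isTRUE(dec$accepted)) {
        rows[[length(rows) + 1L]] <-
          data.frame(from = fa[i], to = fb[j], weight = dec$normalized_mi,
                     method = "MI", stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else empty_edges()
}

#' Build the mutual-information network of one layer
#'
#' Places an edge (weight = normalized MI) between every within-layer
#' feature pair that passes the surrogate-permutation z-test.  Subjects are
#' filtered pairwise-complete per pair, maximizing the sample available to
#' each test.
#'
#' @param cohort an `ml_cohort`.
#' @param layer layer name.
#' @param config settings from [topo_config()].
#' @param seed optional RNG seed for the surrogate permutations.
#' @return an `ml_network` over the layer's features.
#' @export
build_layer_network <- function(cohort, layer, config = topo_config(),
                                seed = NULL) {
  if (!layer %in% names(cohort$layers)) stop("unknown layer: ", layer)
  m <- cohort$layers[[layer]]
  if (sum(stats::complete.cases(m)) < 5L) {
    stop("fewer than 5 complete subjects in layer ", layer)
  }
  if (!is.null(seed)) set.seed(seed)
  nodes <- data.frame(id = colnames(m), layer = layer,
                      stringsAsFactors = FALSE)
  edges <- if (ncol(m) >= 2L) mi_edge_scan(m, NULL, config) else empty_edges()
  ml_network(nodes, edges)
}

#' Build mutual-information edges between two layers
#'
#' Tests every cross-layer feature pair on the subjects complete in both
#' layers.  Used both for the adjacent-only hierarchical wiring and for the
#' all-pairs connectivity (density) analysis.
#'
#' @param cohort an `ml_cohort`.
#' @param layer_a,layer_b layer names.
#' @param config settings from [topo_config()].
#' @param seed optional RNG seed.
#' @return edge data.frame (`from`, `to`, `weight`, `method`).
#' @export
build_interlayer_edges <- function(cohort, layer_a, layer_b,
                                   config = topo_config(), seed = NULL) {
  for (lay in c(layer_a, layer_b)) {
    if (!lay %in% names(cohort$layers)) stop("unknown layer: ", lay)
  }
  cc <- complete_subjects(cohort, c(layer_a, layer_b))
  if (length(cc) == 0L) {
    stop("no subjects with complete data in both layers")
  }
  if (!is.null(seed)) set.seed(seed)
  ma <- cohort$layers[[layer_a]][cc, , drop = FALSE]
  mb <- cohort$layers[[layer_b]][cc, , drop = FALSE]
  mi_edge_scan(ma, mb, config)
}

#' Weighted network density within or between node sets
#'
#' Ratio of the sum of edge weights to the number of possible connections:
#' `n (n - 1) / 2` within one set, `|a| * |b|` between two disjoint sets.
#'
#' @param network an `ml_network`.
#' @param node_set_a,node_set_b character vectors of node ids; omit
#'   `node_set_b` (or pass the same set) for within-set density.
#' @return a single density value (in `[0, 1]` when all weights are <= 1).
#' @export
network_density <- function(network, node_set_a, node_set_b = NULL) {
  e <- network$edges
  if (is.null(node_set_b) || setequal(node_set_a, node_set_b)) {
    n <- length(unique(node_set_a))
    if (n < 2L) stop("within-set density needs at least 2 nodes")
    keep <- e$from %in% node_set_a & e$to %in% node_set_a
    return(sum(e$weight[keep]) / (n * (n - 1) / 2))
  }
  if (length(intersect(node_set_a, node_set_b))) {
    stop("between-set density requires disjoint node sets")
  }
  if (!length(node_set_a) || !length(node_set_b)) stop("empty node set")
  cross <- (e$from %in% node_set_a & e$to %in% node_set_b) |
    (e$from %in% node_set_b & e$to %in% node_set_a)
  sum(e$weight[cross]) / (length(unique(node_set_a)) *
                            length(unique(node_set_b)))
}

#' Degree table, per-layer average degree, and hubs
#'
#' Degree is the unweighted edge count per node.  Hubs are the
#' highest-degree nodes per layer (top 3 by default), ties broken
#' lexicographically by node id.
#'
#' @param network an `ml_network`.
#' @param n_hubs number of hubs reported per layer.
#' @return list with `degrees` (data.frame `id`, `layer`, `degree`),
#'   `layer_means` (named numeric) and `hubs` (data.frame).
#' @export
degree_stats <- function(network, n_hubs = 3L) {
  if (nrow(network$nodes) == 0L) stop("empty network")
  deg <- table(factor(c(network$edges$from, network$edges$to),
                      levels = network$nodes$id))
  degrees <- data.frame(id = network$nodes$id, layer = network$nodes$layer,
                        degree = as.integer(deg[network$nodes$id]),
                        stringsAsFactors = FALSE)
  layer_means <- tapply(degrees$degree, degrees$layer, mean)
  hubs <- do.call(rbind, lapply(split(degrees, degrees$layer), function(d) {
    d <- d[order(-d$degree, d$id), , drop = FALSE]
    utils::head(d, n_hubs)
  }))
  rownames(hubs) <- NULL
  list(degrees = degrees, layer_means = c(layer_means), hubs = hubs)
}

#' Mann-Whitney comparison of two degree distributions
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test with the direction of
#' the shift reported.  Samples in which every value is tied across both
#' groups are flagged degenerate.
#'
#' @param degrees_a,degrees_b numeric vectors of node degrees.
#' @return list with `statistic` (U), `p_value`, `direction`
#'   (`"a_greater"`, `"b_greater"` or `"none"`), `degenerate`.
#' @export
compare_degree_distributions <- function(degrees_a, degrees_b) {
  if (!length(degrees_a) || !length(degrees_b)) stop("empty sample")
  if (length(unique(c(degrees_a, degrees_b))) == 1L) {
    return(list(statistic = length(degrees_a) * length(degrees_b) / 2,
                p_value = 1, direction = "none", degenerate = TRUE))
  }
  wt <- suppressWarnings(stats::wilcox.test(degrees_a, degrees_b,
                                            alternative = "two.sided",
                                            exact = FALSE))
  dir <- if (stats::median(degrees_a) > stats::median(degrees_b)) {
    "a_greater"
  } else if (stats::median(degrees_a) < stats::median(degrees_b)) {
    "b_greater"
  } else "none"
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       direction = dir, degenerate = FALSE)
}
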
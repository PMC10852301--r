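#' Degree-preserving permutation of a network
#'
#' Randomizes the topology by repeated double-edge swaps: two edges
#' `(a, b)` and `(c, d)` are rewired to `(a, d), (c, b)` (or `(a, c),
#' (d, b)`), which leaves every node's degree unchanged.  A proposed swap is
#' rejected — and simply skipped — if it would create a self-edge or
#' duplicate an existing edge.  `swaps_per_edge * |E|` swap *attempts* are
#' made, so the procedure always terminates even on rigid graphs (a
#' triangle, for example, admits no valid swap and is returned unchanged).
#' Each edge's weight travels with its rewired endpoints, so the weight
#' multiset is preserved exactly.
#'
#' @param network an `ml_network` with at least 2 edges.
#' @param swaps_per_edge swap attempts per original edge (default 10).
#' @param seed RNG seed.
#' @return a permuted `ml_network` with the same nodes, degree sequence and
#'   weight multiset.
#' @export
degree_preserving_permutation <- function(network, swaps_per_edge = 10L,
                                          seed = NULL) {
  e <- network$edges
  if (nrow(e) < 2L) stop("need at least 2 edges to permute")
  if (!is.null(seed)) set.seed(seed)
  from <- e$from; to <- e$to
  key_set <- new.env(parent = emptyenv())
  for (k in edge_key(from, to)) assign(k, TRUE, envir = key_set)
  n_e <- nrow(e)
  attempts <- swaps_per_edge * n_e
  for (a in seq_len(attempts)) {
    idx <- sample.int(n_e, 2L)
    i <- idx[1L]; j <- idx[2L]
    # two possible rewirings; pick one at random for an unbiased walk
    if (stats::runif(1) < 0.5) {
      nf1 <- from[i]; nt1 <- to[j]
      nf2 <- from[j]; nt2 <- to[i]
    } else {
      nf1 <- from[i]; nt1 <- from[j]
      nf2 <- to[i]; nt2 <- to[j]
    }
    if (nf1 == nt1 || nf2 == nt2) next
    k1 <- edge_key(nf1, nt1); k2 <- edge_key(nf2, nt2)
    if (k1 == k2) next
    old1 <- edge_key(from[i], to[i]); old2 <- edge_key(from[j], to[j])
    # reject any rewiring that would duplicate an existing unordered pair
    # (including re-creating either of the two edges being swapped)
    if (exists(k1, envir = key_set) || exists(k2, envir = key_set)) next
    rm(list = c(old1, old2), envir = key_set)
    assign(k1, TRUE, envir = key_set)
    assign(k2, TRUE, envir = key_set)
    from[i] <- nf1; to[i] <- nt1
    from[j] <- nf2; to[j] <- nt2
  }
  out <- data.frame(from = from, to = to, weight = e$weight,
                    method = e$method, stringsAsFactors = FALSE)
  ml_network(network$nodes, out, hierarchy = network$hierarchy)
}

#' Path occurrence counts across permuted-network screens
#'
#' Re-runs the full Boolean screen on each of `n_perm` degree-preserving
#' permutations of the network and counts, for every original top path, how
#' many permuted screens report the exact same node sequence among their
#' own top paths for the same input-output pair.  By default the permuted
#' screens reuse the original simulation seeds so that only the topology
#' changes between the original and each null screen.
#'
#' @param network the original signed `ml_network`.
#' @param original a `path_ensemble` from [combinatorial_screen()] on
#'   `network`.
#' @param config the [screen_config()] used for the original screen.
#' @param n_perm number of permuted networks (default 100).
#' @param swaps_per_edge swap attempts per edge per permutation.
#' @param seed RNG seed for the permutations.
#' @param reuse_seeds reuse the original simulation seeds in the permuted
#'   screens (set `FALSE` for fully independent simulations).
#' @return a `permutation_report`: data.frame with `input`, `output`,
#'   `path`, `count`, `n_perm`.
#' @export
permutation_path_counts <- function(network, original, config = original$config,
                                    n_perm = 100L, swaps_per_edge = 10L,
                                    seed = 1L, reuse_seeds = TRUE) {
  orig <- unique(original$paths[, c("input", "output", "path")])
  counts <- integer(nrow(orig))
  set.seed(seed)
  perm_seeds <- sample.int(.Machine$integer.max - 1L, n_perm)
  sim_seeds <- if (reuse_seeds) rep(config$sim$seed, n_perm) else
    sample.int(.Machine$integer.max - 1L, n_perm)
  inputs <- original$inputs
  outputs <- original$outputs
  for (p in seq_len(n_perm)) {
    perm <- degree_preserving_permutation(network, swaps_per_edge,
                                          seed = perm_seeds[p])
    cfg <- config
    cfg$sim$seed <- sim_seeds[p]
    cfg$ci_level <- NA  # CIs are irrelevant for null counting
    screen <- combinatorial_screen(perm, inputs, outputs, cfg)
    hit <- paste(orig$input, orig$output, orig$path, sep = "\r") %in%
      paste(screen$paths$input, screen$paths$output, screen$paths$path,
            sep = "\r")
    counts <- counts + hit
  }
  out <- data.frame(orig, count = counts, n_perm = n_perm,
                    stringsAsFactors = FALSE)
  class(out) <- c("permutation_report", class(out))
  out
}

#' Filter paths by their permutation-null occurrence
#'
#' Retains a path only when it appeared in strictly fewer than
#' `threshold * n_perm` of the permuted screens (the specificity filter:
#' paths that also arise on randomized topologies are discarded).  A count
#' exactly at the threshold (e.g. 1/100 at 1%) is removed.
#'
#' @param ensemble a `path_ensemble`.
#' @param report a `permutation_report` covering every path in `ensemble`.
#' @param threshold maximum null occurrence fraction (default 0.01).
#' @return the filtered `path_ensemble` (with a `retained` report attached
#'   as attribute `"report"`).
#' @export
filter_paths <- function(ensemble, report, threshold = 0.01) {
  key <- function(df) paste(df$input, df$output, df$path, sep = "\r")
  m <- match(key(ensemble$paths), key(report))
  if (anyNA(m)) stop("report does not cover every path in the ensemble")
  frac <- report$count[m] / report$n_perm[m]
  retained <- frac < threshold
  out <- ensemble
  out$paths <- ensemble$paths[retained, , drop = FALSE]
  rownames(out$paths) <- NULL
  report$retained <- (report$count / report$n_perm) < threshold
  attr(out, "report") <- report
  out
}

#' Write a permutation report as TSV
#' @param report a `permutation_report`.
#' @param path output TSV path.
#' @param threshold retention threshold recorded in the `retained` column.
#' @export
write_permutation_report <- function(report, path, threshold = 0.01) {
  report$retained <- (report$count / report$n_perm) < threshold
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
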
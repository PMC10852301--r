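#' Maximum lagged cross-correlation between two binary state signals
#'
#' Signals are coded as +/-1 (logical input is converted).  `Cn` is the
#' maximum over lags `0..max_lag` of the sample correlation between
#' `sig_a(t)` and `sig_b(t + lag)`; information is taken to flow forward in
#' time from the first signal, so only non-negative lags are scanned.  Ties
#' are broken by the smallest lag.  A constant signal yields `Cn = 0` with a
#' degenerate flag.
#'
#' @param sig_a,sig_b equal-length numeric (+/-1) or logical vectors.
#' @param max_lag largest lag scanned (must be < length / 2).
#' @return list with `cn`, `lag`, `degenerate`.
#' @export
max_cross_correlation <- function(sig_a, sig_b, max_lag = 10L) {
  a <- if (is.logical(sig_a)) 2 * sig_a - 1 else as.numeric(sig_a)
  b <- if (is.logical(sig_b)) 2 * sig_b - 1 else as.numeric(sig_b)
  n <- length(a)
  if (length(b) != n) stop("signals must have equal length")
  if (max_lag >= n / 2) stop("max_lag must be below half the signal length")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(list(cn = 0, lag = 0L, degenerate = TRUE))
  }
  best <- -Inf; best_lag <- 0L
  for (lag in 0:max_lag) {
    aa <- a[seq_len(n - lag)]
    bb <- b[seq_len(n - lag) + lag]
    if (stats::sd(aa) == 0 || stats::sd(bb) == 0) next
    r <- stats::cor(aa, bb)
    if (r > best + 1e-12) {
      best <- r; best_lag <- lag
    }
  }
  if (!is.finite(best)) return(list(cn = 0, lag = 0L, degenerate = TRUE))
  list(cn = best, lag = best_lag, degenerate = FALSE)
}

#' Cross-correlation edge weights from a trace ensemble
#'
#' For every edge of the original network, the per-replicate maximum
#' cross-correlation `Cn` between the two nodes' +/-1 state signals is
#' computed (maximized over both orientations since edges are undirected),
#' then averaged over replicates.  The inverse of the mean, `1 / mean(Cn)`,
#' becomes the path weight, so strong co-variation means low weight.  Edges
#' whose mean `Cn` does not exceed `epsilon` are dropped (their inverse
#' diverges and they carry no usable signal); no new edges are ever created.
#'
#' @param ensemble a `trace_ensemble` over the network's nodes.
#' @param network the signed `ml_network` the traces were simulated on.
#' @param max_lag lag range for [max_cross_correlation()].
#' @param epsilon minimum mean `Cn` for an edge to stay in the path graph.
#' @return a `path_weights` object: list with `graph` (an `ml_network` whose
#'   weights are the inverse mean correlations), `edges` (data.frame with
#'   `from`, `to`, `mean_cn`, `weight`), and `cn_matrix`
#'   (edges x replicates, rownames are canonical edge keys).
#' @export
edge_correlation_weights <- function(ensemble, network, max_lag = 10L,
                                     epsilon = 0.01) {
  if (!length(ensemble$traces)) stop("empty ensemble")
  e <- network$edges
  if (!all(ensemble$node_ids %in% network$nodes$id) ||
      !all(c(e$from, e$to) %in% ensemble$node_ids)) {
    stop("ensemble and network node sets differ")
  }
  signs <- lapply(ensemble$traces, function(tr) 2 * tr - 1)
  n_rep <- length(signs)
  ui <- match(e$from, rownames(signs[[1L]]))
  vi <- match(e$to, rownames(signs[[1L]]))
  cn <- matrix(NA_real_, nrow(e), n_rep,
               dimnames = list(edge_key(e$from, e$to), NULL))
  for (r in seq_len(n_rep)) {
    cn[, r] <- edge_max_cn(signs[[r]], ui, vi, max_lag)
  }
  mean_cn <- rowMeans(cn)
  keep <- mean_cn > epsilon
  edges_df <- data.frame(from = e$from, to = e$to, mean_cn = mean_cn,
                         weight = ifelse(keep, 1 / mean_cn, NA_real_),
                         stringsAsFactors = FALSE)
  graph_edges <- if (any(keep)) {
    data.frame(from = e$from[keep], to = e$to[keep],
               weight = 1 / mean_cn[keep], method = "inverse_cn",
               stringsAsFactors = FALSE)
  } else empty_edges()
  structure(list(graph = ml_network(network$nodes, graph_edges,
                                    hierarchy = network$hierarchy),
                 edges = edges_df, cn_matrix = cn,
                 max_lag = max_lag, epsilon = epsilon),
            class = "path_weights")
}

# vectorized per-edge maximum lagged cross-correlation: for every edge
# (ui[k], vi[k]) the max over lags 0..max_lag and both orientations of the
# windowed sample correlation; constant windows contribute nothing and a
# fully degenerate edge yields 0, matching max_cross_correlation()
edge_max_cn <- function(s, ui, vi, max_lag) {
  n <- ncol(s)
  best <- rep(-Inf, length(ui))
  for (lag in 0:max_lag) {
    X <- s[, seq_len(n - lag), drop = FALSE]
    Y <- s[, seq_len(n - lag) + lag, drop = FALSE]
    Xc <- X - rowMeans(X)
    Yc <- Y - rowMeans(Y)
    sx <- sqrt(rowSums(Xc * Xc))
    sy <- sqrt(rowSums(Yc * Yc))
    fwd <- rowSums(Xc[ui, , drop = FALSE] * Yc[vi, , drop = FALSE]) /
      (sx[ui] * sy[vi])
    rev <- rowSums(Xc[vi, , drop = FALSE] * Yc[ui, , drop = FALSE]) /
      (sx[vi] * sy[ui])
    best <- pmax(best, ifelse(is.finite(fwd), fwd, -Inf),
                 ifelse(is.finite(rev), rev, -Inf))
  }
  ifelse(is.finite(best), best, 0)
}

# lexicographic order on character vectors (prefix sorts first)
lex_less <- function(a, b) {
  k <- min(length(a), length(b))
  for (i in seq_len(k)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

# deterministic Dijkstra returning the lexicographically smallest among the
# minimum-cost paths; W is a symmetric weight matrix with Inf for non-edges
dijkstra_path <- function(W, ids, src, dst, blocked_nodes = integer(),
                          blocked_W = NULL) {
  n <- nrow(W)
  Wl <- if (is.null(blocked_W)) W else blocked_W
  dist <- rep(Inf, n); dist[src] <- 0
  paths <- vector("list", n); paths[[src]] <- src
  done <- rep(FALSE, n); done[blocked_nodes] <- TRUE
  if (done[src] || done[dst]) return(NULL)
  repeat {
    open <- which(!done & is.finite(dist))
    if (!length(open)) return(NULL)
    u <- open[which.min(dist[open])]
    if (u == dst) {
      return(list(path = paths[[u]], dist = dist[u]))
    }
    done[u] <- TRUE
    nbr <- which(is.finite(Wl[u, ]) & !done)
    for (v in nbr) {
      nd <- dist[u] + Wl[u, v]
      cand <- c(paths[[u]], v)
      if (nd < dist[v] - 1e-12) {
        dist[v] <- nd; paths[[v]] <- cand
      } else if (abs(nd - dist[v]) <= 1e-12 &&
                 lex_less(ids[cand], ids[paths[[v]]])) {
        paths[[v]] <- cand
      }
    }
  }
}

#' Yen's k shortest loopless paths
#'
#' Enumerates up to `k` simple (loopless) paths between `source` and
#' `target` in non-decreasing order of path score (the sum of edge
#' weights).  Ties are broken deterministically by the lexicographic node
#' sequence.  Fewer than `k` paths are returned when fewer exist; no path
#' yields an empty list rather than an error.
#'
#' @param graph an `ml_network` (or `path_weights` object) with strictly
#'   positive edge weights.
#' @param source,target node ids (`source != target`).
#' @param k maximum number of paths (default 10).
#' @return a `path_list`: list of `list(nodes, score)` in rank order.
#' @export
k_shortest_paths <- function(graph, source, target, k = 10L) {
  if (inherits(graph, "path_weights")) graph <- graph$graph
  ids <- graph$nodes$id
  if (source == target) stop("source and target must differ")
  s <- match(source, ids); t <- match(target, ids)
  if (is.na(s) || is.na(t)) stop("source or target not in graph")
  e <- graph$edges
  if (any(e$weight <= 0)) stop("path weights must be strictly positive")
  W <- matrix(Inf, length(ids), length(ids))
  if (nrow(e)) {
    i <- match(e$from, ids); j <- match(e$to, ids)
    W[cbind(i, j)] <- e$weight
    W[cbind(j, i)] <- e$weight
  }

  first <- dijkstra_path(W, ids, s, t)
  if (is.null(first)) {
    return(structure(list(), class = "path_list"))
  }
  A <- list(first)
  B <- list()
  path_id <- function(p) paste(p, collapse = ",")
  seen <- stats::setNames(TRUE, path_id(first$path))

  while (length(A) < k) {
    prev <- A[[length(A)]]$path
    for (i in seq_len(length(prev) - 1L)) {
      spur <- prev[i]
      root <- prev[seq_len(i)]
      Wl <- W
      for (p in A) {
        if (length(p$path) > i && identical(p$path[seq_len(i)], root)) {
          Wl[p$path[i], p$path[i + 1L]] <- Inf
          Wl[p$path[i + 1L], p$path[i]] <- Inf
        }
      }
      blocked <- root[-length(root)]
      sp <- dijkstra_path(W, ids, spur, t, blocked_nodes = blocked,
                          blocked_W = Wl)
      if (is.null(sp)) next
      full <- c(root[-length(root)], sp$path)
      pid <- path_id(full)
      if (isTRUE(unname(seen[pid]))) next
      root_cost <- if (i > 1L) {
        sum(W[cbind(root[-length(root)], root[-1L])])
      } else 0
      B[[length(B) + 1L]] <- list(path = full, dist = root_cost + sp$dist)
      seen[pid] <- TRUE
    }
    if (!length(B)) break
    ord <- order(vapply(B, `[[`, 0, "dist"))
    best <- ord[1L]
    # lexicographic tie-break among equal-score candidates
    for (o in ord[-1L]) {
      if (B[[o]]$dist > B[[best]]$dist + 1e-12) break
      if (lex_less(ids[B[[o]]$path], ids[B[[best]]$path])) best <- o
    }
    A[[length(A) + 1L]] <- B[[best]]
    B[[best]] <- NULL
  }

  structure(lapply(A, function(p) {
    list(nodes = ids[p$path], score = p$dist)
  }), class = "path_list")
}

#' Format a node sequence as a path string
#' @param nodes character vector of node ids.
#' @return single string with nodes joined by `" > "`.
#' @export
path_string <- function(nodes) paste(nodes, collapse = " > ")

#' Percentile confidence interval of a path score
#'
#' The path score is recomputed per replicate from that replicate's `Cn`
#' values, giving an empirical distribution; the interval is the
#' 2.5th/97.5th percentile band (at the default 95% level).  Replicates in
#' which any path edge has a non-positive `Cn` are excluded and counted.
#'
#' @param weights a `path_weights` object.
#' @param path character vector of node ids (a path in the weighted graph).
#' @param level confidence level (default 0.95).
#' @return list with `low`, `high`, `scores`, `n_used`, `n_excluded`.
#' @export
path_confidence_interval <- function(weights, path, level = 0.95) {
  if (length(path) < 2L) stop("path needs at least 2 nodes")
  keys <- edge_key(path[-length(path)], path[-1L])
  missing_e <- setdiff(keys, rownames(weights$cn_matrix))
  if (length(missing_e)) {
    stop("path edge(s) not present in the weighted graph")
  }
  cn <- weights$cn_matrix[keys, , drop = FALSE]
  usable <- colSums(cn <= 0) == 0L
  n_excluded <- sum(!usable)
  if (sum(usable) < 2L) stop("fewer than 2 usable replicates")
  scores <- colSums(1 / cn[, usable, drop = FALSE])
  qs <- stats::quantile(scores, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  list(low = qs[1L], high = qs[2L], scores = unname(scores),
       n_used = sum(usable), n_excluded = n_excluded)
}

#' Jackknife stability of the top-k path list
#'
#' Repeatedly subsamples the replicate ensemble, recomputes the mean
#' cross-correlations and the resulting top-k paths, and reports the mean
#' number of paths (out of k) identical to the full-ensemble top-k — a
#' stability check on the ranking.
#'
#' @param weights a `path_weights` object (full ensemble).
#' @param source,target node ids of the screened pair.
#' @param subsample_sizes replicate subsample sizes (default 90 and 80 of
#'   the 100 replicates).
#' @param n_draws random draws per subsample size.
#' @param k paths per list.
#' @param seed RNG seed for the draws.
#' @return named numeric vector: mean overlap (out of `k`) per subsample
#'   size.
#' @export
jackknife_stability <- function(weights, source, target,
                                subsample_sizes = c(90L, 80L),
                                n_draws = 10L, k = 10L, seed = 1L) {
  n_rep <- ncol(weights$cn_matrix)
  if (any(subsample_sizes > n_rep)) {
    stop("subsample sizes must not exceed the number of replicates")
  }
  full_top <- k_shortest_paths(weights$graph, source, target, k)
  full_ids <- vapply(full_top, function(p) path_string(p$nodes), "")

  rerank <- function(cols) {
    mcn <- rowMeans(weights$cn_matrix[, cols, drop = FALSE])
    keep <- mcn > weights$epsilon
    e <- weights$edges
    sub_edges <- if (any(keep)) {
      data.frame(from = e$from[keep], to = e$to[keep],
                 weight = 1 / mcn[keep], method = "inverse_cn",
                 stringsAsFactors = FALSE)
    } else empty_edges()
    g <- ml_network(weights$graph$nodes, sub_edges)
    top <- k_shortest_paths(g, source, target, k)
    vapply(top, function(p) path_string(p$nodes), "")
  }

  set.seed(seed)
  out <- vapply(subsample_sizes, function(m) {
    mean(vapply(seq_len(n_draws), function(d) {
      cols <- if (m == n_rep) seq_len(n_rep) else sample.int(n_rep, m)
      sum(full_ids %in% rerank(cols))
    }, 0))
  }, 0)
  stats::setNames(out, as.character(subsample_sizes))
}

#' Enumerate the input-output pairs of a combinatorial screen
#'
#' @param inputs,outputs character vectors of eligible node ids.
#' @return data.frame with columns `input`, `output`
#'   (`length(inputs) * length(outputs)` rows).
#' @export
enumerate_screen_pairs <- function(inputs, outputs) {
  if (!length(inputs) || !length(outputs)) stop("empty role set")
  pairs <- expand.grid(input = inputs, output = outputs,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs[order(match(pairs$input, inputs), match(pairs$output, outputs)), ,
        drop = FALSE] -> pairs
  rownames(pairs) <- NULL
  pairs
}

#' Screen configuration for the combinatorial path search
#' @param sim a [sim_config()].
#' @param k top paths kept per input-output pair.
#' @param max_lag,epsilon see [edge_correlation_weights()].
#' @param ci_level confidence level for per-path intervals (`NA` skips CIs).
#' @return a list of settings.
#' @export
screen_config <- function(sim = sim_config(), k = 10L, max_lag = 10L,
                          epsilon = 0.01, ci_level = 0.95) {
  list(sim = sim, k = as.integer(k), max_lag = as.integer(max_lag),
       epsilon = epsilon, ci_level = ci_level)
}

#' Combinatorial screen over all input-output pairs
#'
#' For every input node one driven replicate ensemble is simulated and its
#' cross-correlation weights computed once, then reused across all outputs;
#' for every (input, output) pair the top-k loopless paths are ranked by
#' path score, with percentile confidence intervals from the per-replicate
#' scores.
#'
#' @param network signed `ml_network`.
#' @param inputs,outputs character vectors of node ids (e.g. the cohort's
#'   role sets: burden scores + proteins + cells as inputs; cells + imaging
#'   + clinical as outputs).
#' @param config a [screen_config()].
#' @return a `path_ensemble`: list with `paths` (data.frame: `input`,
#'   `output`, `rank`, `path`, `score`, `ci_low`, `ci_high`), `n_pairs`,
#'   `inputs`, `outputs`, `config`.
#' @export
combinatorial_screen <- function(network, inputs, outputs,
                                 config = screen_config()) {
  if (!length(inputs) || !length(outputs)) stop("empty role set")
  absent <- setdiff(c(inputs, outputs), network$nodes$id)
  if (length(absent)) {
    stop("role node(s) not in network: ", paste(absent, collapse = ", "))
  }
  set.seed(config$sim$seed)
  input_seeds <- sample.int(.Machine$integer.max - 1L, length(inputs))
  rows <- list()
  for (ii in seq_along(inputs)) {
    inp <- inputs[ii]
    cfg <- config$sim
    cfg$seed <- input_seeds[ii]
    ens <- run_ensemble(network, inp, cfg)
    w <- edge_correlation_weights(ens, network, max_lag = config$max_lag,
                                  epsilon = config$epsilon)
    for (out in setdiff(outputs, inp)) {
      top <- k_shortest_paths(w$graph, inp, out, config$k)
      if (!length(top)) next
      for (r in seq_along(top)) {
        ci <- c(NA_real_, NA_real_)
        if (!is.na(config$ci_level)) {
          ci_try <- tryCatch(
            path_confidence_interval(w, top[[r]]$nodes, config$ci_level),
            error = function(e) NULL)
          if (!is.null(ci_try)) ci <- c(ci_try$low, ci_try$high)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          input = inp, output = out, rank = r,
          path = path_string(top[[r]]$nodes), score = top[[r]]$score,
          ci_low = ci[1L], ci_high = ci[2L], stringsAsFactors = FALSE)
      }
    }
  }
  paths <- if (length(rows)) do.call(rbind, rows) else
    data.frame(input = character(), output = character(), rank = integer(),
               path = character(), score = numeric(), ci_low = numeric(),
               ci_high = numeric(), stringsAsFactors = FALSE)
  structure(list(paths = paths,
                 n_pairs = length(inputs) * length(outputs),
                 inputs = inputs, outputs = outputs, config = config),
            class = "path_ensemble")
}

#' @export
print.path_ensemble <- function(x, ...) {
  cat("path_ensemble:", x$n_pairs, "input-output pairs,",
      nrow(x$paths), "ranked paths\n")
  invisible(x)
}

#' Write a path ensemble as TSV / JSON
#' @param ensemble a `path_ensemble`.
#' @param path output file (`.tsv` or `.json` by `format`).
#' @param format `"tsv"` or `"json"`.
#' @export
write_paths <- function(ensemble, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(ensemble$paths, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(list(n_pairs = ensemble$n_pairs,
                              inputs = ensemble$inputs,
                              outputs = ensemble$outputs,
                              paths = ensemble$paths),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Build the validation network from regression-significance triples
#'
#' Converts a table of significant (protein, cell, phenotype) regression
#' models into an unweighted network: an edge between the protein and the
#' cell and between the cell and the phenotype for every triple; an
#' indirect imaging-clinical edge between two phenotypes sharing a cell;
#' cell-clinical edges are then removed; finally only edges that also occur
#' as consecutive pairs in the supplied top paths are kept.
#'
#' @param triples data.frame with columns `protein`, `cell`, `phenotype`.
#' @param top_paths a `path_ensemble`, or a character vector of
#'   `" > "`-joined path strings.
#' @param nodes data.frame (`id`, `layer`) or `ml_network` providing layer
#'   labels (phenotypes must be labeled `imaging` or `clinical`).
#' @param intersect keep only edges present in `top_paths` (the final rule;
#'   disable to inspect the pre-intersection network).
#' @return an unweighted `ml_network` (method `"validation"`).
#' @export
build_validation_network <- function(triples, top_paths, nodes,
                                     intersect = TRUE) {
  if (inherits(nodes, "ml_network")) nodes <- nodes$nodes
  lookup <- stats::setNames(nodes$layer, nodes$id)
  used <- unique(unlist(triples[c("protein", "cell", "phenotype")]))
  unknown <- setdiff(used, names(lookup))
  if (length(unknown)) {
    stop("triple references unknown node(s): ", paste(unknown, collapse = ", "))
  }
  bad_ph <- unique(triples$phenotype[
    !lookup[triples$phenotype] %in% c("imaging", "clinical")])
  if (length(bad_ph)) {
    stop("phenotype node(s) must be imaging or clinical: ",
         paste(bad_ph, collapse = ", "))
  }

  keys <- c(edge_key(triples$protein, triples$cell),
            edge_key(triples$cell, triples$phenotype))
  # indirect imaging-clinical edges through a shared cell
  for (cl in unique(triples$cell)) {
    ph <- unique(triples$phenotype[triples$cell == cl])
    if (length(ph) < 2L) next
    cmb <- utils::combn(sort(ph), 2L)
    lay_a <- lookup[cmb[1L, ]]; lay_b <- lookup[cmb[2L, ]]
    cross <- (lay_a == "imaging" & lay_b == "clinical") |
      (lay_a == "clinical" & lay_b == "imaging")
    if (any(cross)) {
      keys <- c(keys, edge_key(cmb[1L, cross], cmb[2L, cross]))
    }
  }
  keys <- unique(keys)

  parts <- strsplit(keys, "\r", fixed = TRUE)
  ed <- data.frame(from = vapply(parts, `[`, "", 1L),
                   to = vapply(parts, `[`, "", 2L),
                   stringsAsFactors = FALSE)
  # prune cell-clinical edges
  la <- lookup[ed$from]; lb <- lookup[ed$to]
  cc <- (la == "cytomics" & lb == "clinical") |
    (la == "clinical" & lb == "cytomics")
  ed <- ed[!cc, , drop = FALSE]

  if (intersect) {
    strs <- if (inherits(top_paths, "path_ensemble")) {
      top_paths$paths$path
    } else {
      as.character(top_paths)
    }
    path_keys <- unique(unlist(lapply(strsplit(strs, " > ", fixed = TRUE),
                                      function(p) {
      if (length(p) < 2L) return(character())
      edge_key(p[-length(p)], p[-1L])
    })))
    ed <- ed[edge_key(ed$from, ed$to) %in% path_keys, , drop = FALSE]
  }

  node_df <- nodes[nodes$id %in% used, , drop = FALSE]
  edges <- if (nrow(ed)) {
    data.frame(from = ed$from, to = ed$to, weight = NA_real_,
               method = "validation", stringsAsFactors = FALSE)
  } else empty_edges()
  ml_network(node_df, edges)
}
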
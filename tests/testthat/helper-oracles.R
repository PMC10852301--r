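# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the implementation under test.

# plug-in mutual information via cut()/table(), in nats
oracle_mi <- function(x, y, n_bins = 10) {
  bin <- function(v) {
    if (length(unique(v)) < n_bins) {
      factor(v)
    } else {
      cut(v, breaks = seq(min(v), max(v), length.out = n_bins + 1),
          include.lowest = TRUE)
    }
  }
  p <- table(bin(x), bin(y)) / length(x)
  px <- rowSums(p); py <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / (px[i] * py[j]))
    }
  }
  unname(s)
}

# exhaustive enumeration of all simple paths between two nodes of an
# undirected weighted edge list; returns them sorted by (score, node seq)
oracle_all_paths <- function(edges, source, target) {
  nbr <- list()
  for (r in seq_len(nrow(edges))) {
    a <- edges$from[r]; b <- edges$to[r]; w <- edges$weight[r]
    nbr[[a]] <- rbind(nbr[[a]], data.frame(to = b, w = w))
    nbr[[b]] <- rbind(nbr[[b]], data.frame(to = a, w = w))
  }
  out <- list()
  walk <- function(path, score) {
    tip <- path[length(path)]
    if (tip == target) {
      out[[length(out) + 1L]] <<- list(nodes = path, score = score)
      return(invisible())
    }
    nb <- nbr[[tip]]
    if (is.null(nb)) return(invisible())
    for (r in seq_len(nrow(nb))) {
      if (nb$to[r] %in% path) next
      walk(c(path, nb$to[r]), score + nb$w[r])
    }
  }
  walk(source, 0)
  if (!length(out)) return(out)
  key <- vapply(out, function(p) paste(p$nodes, collapse = " "), "")
  ord <- order(vapply(out, `[[`, 0, "score"), key)
  out[ord]
}

# scalar lagged max cross-correlation, written independently with cor()
oracle_max_cn <- function(a, b, max_lag = 10) {
  vals <- sapply(0:max_lag, function(L) {
    n <- length(a)
    suppressWarnings(cor(a[1:(n - L)], b[(1 + L):n]))
  })
  max(vals, na.rm = TRUE)
}

# random connected-ish weighted graph for path-oracle tests
random_test_graph <- function(n_nodes, p = 0.5) {
  ids <- LETTERS[seq_len(n_nodes)]
  cmb <- utils::combn(ids, 2)
  keep <- runif(ncol(cmb)) < p
  # always keep a spine so source and target stay connected
  spine <- paste(ids[-n_nodes], ids[-1])
  keep <- keep | paste(cmb[1, ], cmb[2, ]) %in% spine
  edges <- data.frame(from = cmb[1, keep], to = cmb[2, keep],
                      weight = round(runif(sum(keep), 0.5, 3), 3),
                      method = "test", stringsAsFactors = FALSE)
  ml_network(data.frame(id = ids, layer = "test"), edges)
}

# small planted-chain cohort and its signed network, shared across tests
planted_chain_features <- function() {
  c("MSGB_nonHLA", "MK03", "Total_T", "mRNFL", "EDSS")
}

planted_chain_cohort <- function(seed = 42, n = 300, strength = 0.9) {
  generate_cohort(default_layers("test"), n,
                  chains = list(chain_spec(planted_chain_features(), strength)),
                  seed = seed)
}

# hand-built trace ensemble (all replicates identical unless noise given)
constant_ensemble <- function(network, input_node, n_replicates = 20,
                              seed = 1) {
  cfg <- sim_config(noise_prob = 0.05, n_replicates = 1L, seed = seed)
  tr <- run_driven_simulation(network, input_node, cfg, replicate_seed = seed)
  structure(list(traces = rep(list(tr$trace), n_replicates),
                 drive = tr$drive, input_node = input_node,
                 node_ids = rownames(tr$trace), seeds = rep(seed, n_replicates),
                 config = cfg),
            class = "trace_ensemble")
}
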
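#' Simulation settings for the driven Boolean dynamics
#'
#' Defaults follow the study protocol: 100 synchronous update steps, 5%
#' per-node noise, a square-wave drive of 10 steps active / 10 steps
#' inactive, and 100 replicate simulations per driven input.
#'
#' @param n_steps number of update steps per replicate.
#' @param noise_prob per-node flip probability applied after each
#'   deterministic update (never to the driven node).
#' @param drive_period_half half-period of the input square wave, in steps.
#' @param n_replicates replicate simulations per input.
#' @param seed master RNG seed; replicate seeds are derived from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_steps = 100L, noise_prob = 0.05,
                       drive_period_half = 10L, n_replicates = 100L,
                       seed = 1L) {
  stopifnot(noise_prob >= 0, noise_prob <= 1, n_steps > 0,
            drive_period_half > 0, n_replicates > 0)
  list(n_steps = as.integer(n_steps), noise_prob = noise_prob,
       drive_period_half = as.integer(drive_period_half),
       n_replicates = as.integer(n_replicates), seed = as.integer(seed))
}

# signed adjacency matrix (nodes x nodes) of an ml_network
signed_adjacency <- function(network) {
  ids <- network$nodes$id
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  e <- network$edges
  if (nrow(e)) {
    i <- match(e$from, ids); j <- match(e$to, ids)
    A[cbind(i, j)] <- e$weight
    A[cbind(j, i)] <- e$weight
  }
  A
}

#' Net activation input of a node
#'
#' Signed weighted sum over the node's neighbors with states coded +/-1: an
#' active neighbor contributes its signed edge weight, an inactive neighbor
#' the negated weight.  A positive total drives the node active on the next
#' step, a negative total inactive, and zero (e.g. an isolated node) leaves
#' it unchanged.  The +/-1 coding makes a single positively coupled
#' follower reproduce its driver exactly — including the falling edge — and
#' a negatively coupled one its complement.
#'
#' @param node node id.
#' @param states named logical vector of current activation states.
#' @param network a signed `ml_network`.
#' @return the summed score.
#' @export
net_input <- function(node, states, network) {
  if (!node %in% network$nodes$id) stop("unknown node: ", node)
  e <- network$edges
  inc <- e$from == node | e$to == node
  if (!any(inc)) return(0)
  nb <- ifelse(e$from[inc] == node, e$to[inc], e$from[inc])
  sum(e$weight[inc] * (2 * as.numeric(states[nb]) - 1))
}

#' One synchronous Boolean update step
#'
#' Deterministic phase: every node whose net input is positive becomes
#' active, negative becomes inactive, zero keeps its previous state.  Noise
#' phase: every non-driven node flips independently with probability
#' `noise_prob`; the driven node (if any) is then overwritten with
#' `drive_value`.  Uses the current RNG stream.
#'
#' @param states named logical vector over all nodes.
#' @param network a signed `ml_network` (or a precomputed signed adjacency
#'   matrix with matching dimnames).
#' @param noise_prob per-node flip probability.
#' @param driven optional id of the driven node.
#' @param drive_value logical state forced onto the driven node.
#' @return the next named logical state vector.
#' @export
boolean_step <- function(states, network, noise_prob = 0,
                         driven = NULL, drive_value = NULL) {
  A <- if (is.matrix(network)) network else signed_adjacency(network)
  score <- drop(A %*% (2 * as.numeric(states[colnames(A)]) - 1))
  nxt <- states[colnames(A)]
  nxt[score > 0] <- TRUE
  nxt[score < 0] <- FALSE
  if (noise_prob > 0) {
    flip <- stats::runif(length(nxt)) < noise_prob
    if (!is.null(driven)) flip[names(nxt) == driven] <- FALSE
    nxt[flip] <- !nxt[flip]
  }
  if (!is.null(driven)) nxt[driven] <- drive_value
  nxt
}

# square-wave drive signal over steps 1..n_steps (TRUE = active first)
drive_signal <- function(n_steps, half = 10L) {
  (((seq_len(n_steps) - 1L) %/% half) %% 2L) == 0L
}

#' Run one driven Boolean simulation
#'
#' All nodes start active with probability 50%; the input node is then
#' forced to a square wave (`drive_period_half` steps active, the same
#' inactive) throughout the run, while every other node follows the noisy
#' synchronous threshold dynamics.
#'
#' @param network signed `ml_network`.
#' @param input_node id of the driven node.
#' @param config a [sim_config()].
#' @param replicate_seed RNG seed for this replicate.
#' @param adjacency optional precomputed signed adjacency matrix.
#' @return list with `trace` (nodes x n_steps logical matrix), `init`,
#'   `drive`, `input_node`, `seed`.
#' @export
run_driven_simulation <- function(network, input_node, config = sim_config(),
                                  replicate_seed = config$seed,
                                  adjacency = NULL) {
  A <- if (is.null(adjacency)) signed_adjacency(network) else adjacency
  ids <- colnames(A)
  if (!input_node %in% ids) stop("unknown node: ", input_node)
  set.seed(replicate_seed)
  drive <- drive_signal(config$n_steps, config$drive_period_half)
  states <- stats::setNames(stats::runif(length(ids)) < 0.5, ids)
  states[input_node] <- TRUE  # the drive owns the input from the start
  trace <- matrix(NA, length(ids), config$n_steps,
                  dimnames = list(ids, NULL))
  for (t in seq_len(config$n_steps)) {
    states <- boolean_step(states, A, config$noise_prob,
                           driven = input_node, drive_value = drive[t])
    trace[, t] <- states
  }
  list(trace = trace, init = NULL, drive = drive, input_node = input_node,
       seed = replicate_seed)
}

#' Run an ensemble of replicate simulations for one driven input
#'
#' Replicate seeds are drawn from the master seed, so the whole ensemble is
#' reproducible while replicates are mutually independent.
#'
#' @inheritParams run_driven_simulation
#' @return a `trace_ensemble`: list with `traces` (list of nodes x steps
#'   logical matrices), `drive`, `input_node`, `node_ids`, `seeds`,
#'   `config`.
#' @export
run_ensemble <- function(network, input_node, config = sim_config()) {
  A <- signed_adjacency(network)
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, config$n_replicates)
  traces <- lapply(seeds, function(s) {
    run_driven_simulation(network, input_node, config, replicate_seed = s,
                          adjacency = A)$trace
  })
  structure(list(traces = traces,
                 drive = drive_signal(config$n_steps, config$drive_period_half),
                 input_node = input_node, node_ids = colnames(A),
                 seeds = seeds, config = config),
            class = "trace_ensemble")
}

#' @export
print.trace_ensemble <- function(x, ...) {
  cat("trace_ensemble:", length(x$traces), "replicates,",
      length(x$node_ids), "nodes x", x$config$n_steps, "steps; input =",
      x$input_node, "\n")
  invisible(x)
}
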
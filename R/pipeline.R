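#' Full pipeline configuration
#'
#' Collects every stage parameter with the study's printed defaults: 10 MI
#' bins, 1000 surrogates, alpha 0.05 for both MI and Pearson edges, 100
#' Boolean steps at 5% noise with a 10-step drive half-period, 100
#' replicates, top-10 paths, 10 swap attempts per edge, 100 permuted
#' networks and a 1% retention threshold.  The configuration is serialized
#' verbatim into each run's manifest.
#'
#' @param cohort_dir optional directory of an existing cohort (TSV layers +
#'   manifest); when `NULL` a synthetic cohort is generated.
#' @param scale layer cardinalities for synthesis (`"test"` or `"full"`).
#' @param n_subjects subjects to synthesize.
#' @param chains list of [chain_spec()] for synthesis.
#' @param missing_rate per subject-layer block missingness for synthesis.
#' @param n_bins,n_surrogates,alpha_mi MI edge-test settings.
#' @param alpha_pearson Pearson edge significance level.
#' @param n_steps,noise_prob,drive_period_half,n_replicates Boolean
#'   simulation settings.
#' @param k,max_lag,epsilon,ci_level path search settings.
#' @param swaps_per_edge,n_perm,threshold negative-control settings.
#' @param use_grn embed the genomics layer through a (synthetic) regulatory
#'   reference.
#' @param run_permutations run the permutation null screen (the most
#'   expensive stage).
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir output directory.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cohort_dir = NULL, scale = "test",
                            n_subjects = 300L, chains = list(),
                            missing_rate = 0,
                            n_bins = 10L, n_surrogates = 1000L,
                            alpha_mi = 0.05, alpha_pearson = 0.05,
                            n_steps = 100L, noise_prob = 0.05,
                            drive_period_half = 10L, n_replicates = 100L,
                            k = 10L, max_lag = 10L, epsilon = 0.01,
                            ci_level = 0.95,
                            swaps_per_edge = 10L, n_perm = 100L,
                            threshold = 0.01,
                            use_grn = FALSE, run_permutations = TRUE,
                            seed = 1L, out_dir = tempfile("mlnetpath_run_")) {
  structure(as.list(environment()), class = "pipeline_config")
}

derive_seed <- function(master, offset) {
  (as.integer(master) + as.integer(offset) * 7919L) %% 2147483646L + 1L
}

#' Run the full analysis pipeline
#'
#' Stages, in order: cohort synthesis or loading; per-layer and all-pairs
#' interlayer MI networks with density and degree summaries; the signed
#' Pearson five-layer network (optionally GRN-embedded); the combinatorial
#' Boolean screen over all input-output pairs; the permutation-null screen
#' and the <`threshold` occurrence filter; a summary report.  Every
#' artifact is written under `config$out_dir` and checksummed in
#' `manifest.json`; identical configuration and seed give identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @return the manifest list, invisibly; all artifacts on disk.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(...) {
    cat(sprintf("[%s] ", format(Sys.time(), "%H:%M:%S")), sprintf(...), "\n",
        sep = "", file = file.path(config$out_dir, "pipeline.log"),
        append = TRUE)
  }
  artifacts <- character()
  keep <- function(p) { artifacts <<- c(artifacts, p); p }

  # --- stage: cohort -------------------------------------------------
  if (is.null(config$cohort_dir)) {
    layers <- default_layers(config$scale)
    cohort <- generate_cohort(layers, config$n_subjects,
                              chains = config$chains,
                              missing_rate = config$missing_rate,
                              seed = derive_seed(config$seed, 1L))
    log_line("synthesized cohort: %d subjects", config$n_subjects)
  } else {
    cohort <- read_cohort(config$cohort_dir)
    missing <- setdiff(layer_hierarchy(), names(cohort$layers))
    if (length(missing)) {
      stop("cohort is missing layer(s): ", paste(missing, collapse = ", "))
    }
    log_line("loaded cohort from %s", config$cohort_dir)
  }
  keep(write_cohort(cohort, file.path(config$out_dir, "cohort")))

  # --- stage: topological networks -----------------------------------
  tcfg <- topo_config(config$n_bins, config$n_surrogates, config$alpha_mi)
  topo <- list()
  for (li in seq_along(names(cohort$layers))) {
    lay <- names(cohort$layers)[li]
    net <- build_layer_network(cohort, lay, tcfg,
                               seed = derive_seed(config$seed, 10L + li))
    topo[[lay]] <- net
    keep(write_network_tsv(net, file.path(config$out_dir,
                                          paste0("topo_", lay, ".tsv"))))
  }
  log_line("built %d layer networks", length(topo))

  # all-pairs interlayer edges on the complete-case subset (density view)
  hier <- layer_hierarchy()
  combo_edges <- do.call(rbind, lapply(topo, function(n) n$edges))
  pair_idx <- utils::combn(length(hier), 2L)
  for (pi in seq_len(ncol(pair_idx))) {
    a <- hier[pair_idx[1L, pi]]; b <- hier[pair_idx[2L, pi]]
    combo_edges <- rbind(combo_edges,
      build_interlayer_edges(cohort, a, b, tcfg,
                             seed = derive_seed(config$seed, 20L + pi)))
  }
  combo_nodes <- do.call(rbind, lapply(names(cohort$layers), function(lay) {
    data.frame(id = colnames(cohort$layers[[lay]]), layer = lay,
               stringsAsFactors = FALSE)
  }))
  combo <- ml_network(combo_nodes, combo_edges)
  keep(write_network_tsv(combo, file.path(config$out_dir, "topo_combined.tsv")))

  densities <- density_table(combo)
  utils::write.table(densities,
                     keep(file.path(config$out_dir, "densities.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dstats <- degree_stats(combo)
  utils::write.table(dstats$hubs, keep(file.path(config$out_dir, "hubs.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_line("combined topological network: %d edges", nrow(combo$edges))

  # --- stage: dynamic (signed) network -------------------------------
  dyn <- build_dynamic_network(cohort, alpha = config$alpha_pearson)
  if (config$use_grn) {
    snps <- dyn$nodes$id[dyn$nodes$layer == "genomics" &
                           !startsWith(dyn$nodes$id, "MSGB")]
    grn <- generate_grn(n_tfs = max(2L, length(snps) %/% 4L),
                        n_genes = max(2L, length(snps) %/% 2L),
                        seed = derive_seed(config$seed, 30L),
                        snp_names = snps)
    keep(write_grn(grn, file.path(config$out_dir, "grn")))
    dyn <- apply_grn(dyn, grn)
  }
  keep(write_network_tsv(dyn, file.path(config$out_dir, "dynamic_network.tsv")))
  keep(write_network_graphml(dyn,
                             file.path(config$out_dir, "dynamic_network.graphml")))
  log_line("dynamic network: %d edges", nrow(dyn$edges))

  # --- stage: combinatorial screen -----------------------------------
  inputs <- intersect(cohort$roles$input, dyn$nodes$id)
  outputs <- intersect(cohort$roles$output, dyn$nodes$id)
  scfg <- screen_config(
    sim = sim_config(config$n_steps, config$noise_prob,
                     config$drive_period_half, config$n_replicates,
                     seed = derive_seed(config$seed, 40L)),
    k = config$k, max_lag = config$max_lag, epsilon = config$epsilon,
    ci_level = config$ci_level)
  screen <- combinatorial_screen(dyn, inputs, outputs, scfg)
  keep(write_paths(screen, file.path(config$out_dir, "paths.tsv"), "tsv"))
  keep(write_paths(screen, file.path(config$out_dir, "paths.json"), "json"))
  log_line("screen: %d pairs, %d ranked paths", screen$n_pairs,
           nrow(screen$paths))

  # --- stage: negative controls --------------------------------------
  if (config$run_permutations && nrow(screen$paths)) {
    report <- permutation_path_counts(dyn, screen, scfg,
                                      n_perm = config$n_perm,
                                      swaps_per_edge = config$swaps_per_edge,
                                      seed = derive_seed(config$seed, 50L))
    keep(write_permutation_report(report,
                                  file.path(config$out_dir,
                                            "permutation_report.tsv"),
                                  config$threshold))
    retained <- filter_paths(screen, report, config$threshold)
    log_line("negative controls: %d/%d paths retained",
             nrow(retained$paths), nrow(screen$paths))
  } else {
    retained <- screen
  }
  keep(write_paths(retained, file.path(config$out_dir, "retained_paths.tsv"),
                   "tsv"))

  cfg_out <- config
  cfg_out$chains <- lapply(config$chains, unclass)
  yaml::write_yaml(unclass(cfg_out), keep(file.path(config$out_dir,
                                                    "config.yaml")))
  files <- unique(unlist(lapply(artifacts, function(p) {
    if (dir.exists(p)) list.files(p, full.names = TRUE, recursive = TRUE)
    else p
  })))
  manifest <- list(
    seed = config$seed,
    artifacts = lapply(files, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# within- and between-layer weighted densities of a combined network
density_table <- function(network) {
  layers <- unique(network$nodes$layer)
  rows <- list()
  for (i in seq_along(layers)) {
    a <- network$nodes$id[network$nodes$layer == layers[i]]
    if (length(a) >= 2L) {
      rows[[length(rows) + 1L]] <- data.frame(
        layer_a = layers[i], layer_b = layers[i],
        density = network_density(network, a), stringsAsFactors = FALSE)
    }
    for (j in seq_along(layers)) {
      if (j <= i) next
      b <- network$nodes$id[network$nodes$layer == layers[j]]
      rows[[length(rows) + 1L]] <- data.frame(
        layer_a = layers[i], layer_b = layers[j],
        density = network_density(network, a, b), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Summarize a completed pipeline run
#'
#' Reads the artifacts of a [run_pipeline()] output directory and returns
#' the report tables: within/between-layer densities, per-layer hubs,
#' retained paths with scores and confidence intervals, and per-node
#' path-degree percentages (the share of retained paths a node appears in,
#' overall and split by the input's layer).
#'
#' @param run_dir the pipeline output directory.
#' @return list with `densities`, `hubs`, `retained_paths`, `path_degree`.
#' @export
summarize_run <- function(run_dir) {
  need <- c("densities.tsv", "hubs.tsv", "retained_paths.tsv",
            "dynamic_network.tsv")
  absent <- need[!file.exists(file.path(run_dir, need))]
  if (length(absent)) {
    stop("incomplete run; missing: ", paste(absent, collapse = ", "))
  }
  densities <- utils::read.delim(file.path(run_dir, "densities.tsv"))
  hubs <- utils::read.delim(file.path(run_dir, "hubs.tsv"))
  retained <- utils::read.delim(file.path(run_dir, "retained_paths.tsv"),
                                stringsAsFactors = FALSE)
  dyn <- read_network_tsv(file.path(run_dir, "dynamic_network.tsv"))
  list(densities = densities, hubs = hubs, retained_paths = retained,
       path_degree = path_degree_table(retained, dyn))
}

#' Node path-degree percentages
#'
#' For each node, the number of retained paths it appears in as a
#' percentage of the total number of retained paths — overall and per input
#' layer.  An empty path table yields an empty result (no division by
#' zero).
#'
#' @param paths data.frame with at least `input` and `path` columns
#'   (`" > "`-joined node sequences), e.g. a `path_ensemble$paths`.
#' @param network `ml_network` supplying the input nodes' layer labels.
#' @return data.frame with `input_layer` (`"all"` row included), `node`,
#'   `n_paths`, `percent`.
#' @export
path_degree_table <- function(paths, network) {
  empty <- data.frame(input_layer = character(), node = character(),
                      n_paths = integer(), percent = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(paths)) return(empty)
  groups <- c(list(all = paths),
              split(paths, node_layer(network, paths$input)))
  out <- do.call(rbind, lapply(names(groups), function(g) {
    df <- groups[[g]]
    nodes <- lapply(strsplit(df$path, " > ", fixed = TRUE), unique)
    tab <- table(unlist(nodes))
    data.frame(input_layer = g, node = names(tab),
               n_paths = as.integer(tab),
               percent = 100 * as.integer(tab) / nrow(df),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
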
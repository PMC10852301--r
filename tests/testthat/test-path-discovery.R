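square_wave <- function(n = 100, half = 10) {
  rep(rep(c(1, -1), each = half), length.out = n)
}

test_that("max cross-correlation handles alignment, delay and degeneracy", {
  s <- square_wave()
  expect_equal(max_cross_correlation(s, s), list(cn = 1, lag = 0L,
                                                 degenerate = FALSE))
  delayed <- c(rep(s[1], 3), s[1:97])
  res <- max_cross_correlation(s, delayed)
  expect_equal(res$cn, 1, tolerance = 1e-3)
  expect_equal(res$lag, 3L)

  expect_equal(max_cross_correlation(rep(1, 50), square_wave(50))$cn, 0)
  expect_true(max_cross_correlation(rep(1, 50), square_wave(50))$degenerate)
  expect_error(max_cross_correlation(s, s[1:99]), "equal length")
  expect_error(max_cross_correlation(s[1:20], s[1:20], max_lag = 10),
               "max_lag")
})

test_that("self cross-correlation is exactly (1, 0) for non-constant signals", {
  set.seed(6)
  for (i in 1:20) {
    s <- sign(rnorm(100))
    res <- max_cross_correlation(s, s)
    expect_equal(res$cn, 1)
    expect_equal(res$lag, 0L)
  }
})

test_that("max cross-correlation of independent signals matches a Monte-Carlo oracle", {
  set.seed(7)
  impl <- replicate(300, {
    max_cross_correlation(sample(c(-1, 1), 100, TRUE),
                          sample(c(-1, 1), 100, TRUE))$cn
  })
  set.seed(123)
  orac <- replicate(300, {
    oracle_max_cn(sample(c(-1, 1), 100, TRUE),
                  sample(c(-1, 1), 100, TRUE))
  })
  expect_lt(abs(mean(impl) - mean(orac)), 0.02)
})

test_that("edge weights are inverse mean correlations with threshold pruning", {
  net <- ml_network(
    data.frame(id = c("a", "b", "c", "d"), layer = "x"),
    data.frame(from = c("a", "b", "c"), to = c("b", "c", "d"), weight = 0.9,
               method = "Pearson"))
  # identical signals on every node: mean Cn = 1, 3-edge path scores 3
  tr <- matrix(rep(square_wave() > 0, 4), 4, byrow = TRUE,
               dimnames = list(c("a", "b", "c", "d"), NULL))
  ens <- structure(list(traces = list(tr, tr), drive = square_wave() > 0,
                        input_node = "a", node_ids = rownames(tr),
                        seeds = c(1, 2), config = sim_config()),
                   class = "trace_ensemble")
  w <- edge_correlation_weights(ens, net)
  expect_equal(unname(w$edges$mean_cn), rep(1, 3))
  expect_equal(unname(w$edges$weight), rep(1, 3))
  paths <- k_shortest_paths(w, "a", "d")
  expect_equal(paths[[1]]$score, 3)

  # reciprocal rule and epsilon pruning
  expect_equal(w$graph$edges$weight, 1 / w$edges$mean_cn)
  pruned <- edge_correlation_weights(ens, net, epsilon = 1)  # meanCn <= 1
  expect_equal(nrow(pruned$graph$edges), 0)
  expect_error(edge_correlation_weights(
    structure(list(traces = list()), class = "trace_ensemble"), net),
    "empty ensemble")
})

test_that("k shortest paths order the diamond graph by total score", {
  g <- ml_network(
    data.frame(id = c("s", "m", "t"), layer = "x"),
    data.frame(from = c("s", "m", "s"), to = c("m", "t", "t"),
               weight = c(1, 1, 3), method = "w"))
  res <- k_shortest_paths(g, "s", "t", k = 10)
  expect_length(res, 2)
  expect_equal(res[[1]]$nodes, c("s", "m", "t"))
  expect_equal(res[[1]]$score, 2)
  expect_equal(res[[2]]$nodes, c("s", "t"))
  expect_equal(res[[2]]$score, 3)

  # no-path and error cases
  iso <- ml_network(data.frame(id = c("s", "t"), layer = "x"))
  expect_length(k_shortest_paths(iso, "s", "t"), 0)
  expect_error(k_shortest_paths(g, "s", "s"), "must differ")
  expect_error(k_shortest_paths(g, "s", "zz"), "not in graph")
})

test_that("Yen's algorithm equals exhaustive enumeration on random graphs", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(4:7, 1)
    g <- random_test_graph(n)
    src <- "A"; dst <- LETTERS[n]
    oracle <- oracle_all_paths(g$edges, src, dst)
    for (k in c(3, 10, 100)) {
      got <- k_shortest_paths(g, src, dst, k)
      want <- oracle[seq_len(min(k, length(oracle)))]
      expect_equal(length(got), length(want))
      for (j in seq_along(got)) {
        expect_equal(got[[j]]$nodes, want[[j]]$nodes)
        expect_equal(got[[j]]$score, want[[j]]$score, tolerance = 1e-9)
      }
    }
  }
})

test_that("extending a path strictly increases its score", {
  set.seed(18)
  g <- random_test_graph(6)
  res <- k_shortest_paths(g, "A", "F", 50)
  for (p in res) {
    if (length(p$nodes) <= 2) next
    sub <- k_shortest_paths(g, "A", p$nodes[length(p$nodes) - 1], 200)
    sub_score <- NULL
    for (q in sub) {
      if (identical(q$nodes, p$nodes[-length(p$nodes)])) sub_score <- q$score
    }
    if (!is.null(sub_score)) expect_lt(sub_score, p$score)
  }
})

test_that("path confidence intervals are percentile bands of replicate scores", {
  fake_w <- function(cn_row) {
    structure(list(
      graph = NULL,
      edges = data.frame(from = "a", to = "b", mean_cn = mean(cn_row),
                         weight = 1 / mean(cn_row)),
      cn_matrix = matrix(cn_row, 1,
                         dimnames = list(mlnetpath:::edge_key("a", "b"),
                                         NULL)),
      epsilon = 0.01), class = "path_weights")
  }
  # identical replicate scores collapse to a zero-width interval
  ci <- path_confidence_interval(fake_w(rep(0.5, 10)), c("a", "b"))
  expect_equal(ci$low, 2)
  expect_equal(ci$high, 2)

  # known distribution matches the percentile oracle
  set.seed(20)
  cn <- runif(200, 0.2, 0.9)
  ci2 <- path_confidence_interval(fake_w(cn), c("a", "b"))
  expect_equal(c(ci2$low, ci2$high),
               unname(quantile(1 / cn, c(0.025, 0.975))))

  # non-positive replicates excluded and counted; too few usable errors
  cn3 <- c(-0.1, 0.5, 0.5, 0.4)
  ci3 <- path_confidence_interval(fake_w(cn3), c("a", "b"))
  expect_equal(ci3$n_excluded, 1)
  expect_equal(ci3$n_used, 3)
  expect_error(path_confidence_interval(fake_w(c(-1, 0.5)), c("a", "b")),
               "usable replicates")
  expect_error(path_confidence_interval(fake_w(rep(0.5, 5)), c("a", "z")),
               "not present")
})

test_that("jackknife overlap is maximal for identical replicates", {
  net <- build_dynamic_network(planted_chain_cohort(44, n = 200))
  ens <- constant_ensemble(net, "MSGB_nonHLA", n_replicates = 30)
  w <- edge_correlation_weights(ens, net)
  full <- k_shortest_paths(w, "MSGB_nonHLA", "EDSS", 10)
  js <- jackknife_stability(w, "MSGB_nonHLA", "EDSS",
                            subsample_sizes = c(20, 10), seed = 2)
  expect_equal(unname(js), rep(length(full), 2))
  # subsample equal to the full ensemble is trivially stable too
  js_full <- jackknife_stability(w, "MSGB_nonHLA", "EDSS",
                                 subsample_sizes = 30, seed = 2)
  expect_equal(unname(js_full), length(full))
  expect_error(jackknife_stability(w, "MSGB_nonHLA", "EDSS",
                                   subsample_sizes = 31), "must not exceed")
})

test_that("the combinatorial screen enumerates pairs and caps ranks", {
  pairs <- enumerate_screen_pairs(c("i1", "i2"), c("o1", "o2", "o3"))
  expect_equal(nrow(pairs), 6)
  expect_error(enumerate_screen_pairs(character(), "o"), "empty role set")

  net <- build_dynamic_network(planted_chain_cohort(45, n = 250))
  cfg <- screen_config(sim = sim_config(n_replicates = 10, seed = 4), k = 5)
  scr <- combinatorial_screen(net, c("MSGB_nonHLA", "MK03"),
                              c("EDSS", "mRNFL"), cfg)
  expect_equal(scr$n_pairs, 4)
  expect_true(all(tapply(scr$paths$rank, paste(scr$paths$input,
                                               scr$paths$output), max) <= 5))
  # scores are non-decreasing within every ranked list
  for (grp in split(scr$paths, paste(scr$paths$input, scr$paths$output))) {
    expect_true(all(diff(grp$score) >= -1e-12))
  }
})

test_that("validation network applies the four regression-table rules", {
  nodes <- data.frame(
    id = c("GSK3AB", "xprot", "B_Memory", "Total_Treg", "INL_change",
           "NBV", "EDSS"),
    layer = c("proteomics", "proteomics", "cytomics", "cytomics", "imaging",
              "imaging", "clinical"))
  triples <- data.frame(
    protein = c("GSK3AB", "xprot", "GSK3AB"),
    cell = c("B_Memory", "Total_Treg", "Total_Treg"),
    phenotype = c("INL_change", "NBV", "EDSS"))

  pre <- build_validation_network(triples, character(), nodes,
                                  intersect = FALSE)
  keys <- mlnetpath:::edge_key(pre$edges$from, pre$edges$to)
  # direct protein-cell and cell-phenotype edges
  expect_true(mlnetpath:::edge_key("GSK3AB", "B_Memory") %in% keys)
  expect_true(mlnetpath:::edge_key("B_Memory", "INL_change") %in% keys)
  # indirect imaging-clinical edge through the shared cell Total_Treg
  expect_true(mlnetpath:::edge_key("NBV", "EDSS") %in% keys)
  # the cell-clinical edge Total_Treg-EDSS is pruned
  expect_false(mlnetpath:::edge_key("Total_Treg", "EDSS") %in% keys)

  # final rule: intersect with the edges occurring in top paths
  top <- c("GSK3AB > B_Memory > INL_change")
  post <- build_validation_network(triples, top, nodes)
  pk <- mlnetpath:::edge_key(post$edges$from, post$edges$to)
  expect_setequal(pk, c(mlnetpath:::edge_key("GSK3AB", "B_Memory"),
                        mlnetpath:::edge_key("B_Memory", "INL_change")))

  expect_error(build_validation_network(
    data.frame(protein = "GSK3AB", cell = "nope", phenotype = "NBV"),
    character(), nodes), "unknown node")
  expect_error(build_validation_network(
    data.frame(protein = "GSK3AB", cell = "B_Memory", phenotype = "xprot"),
    character(), nodes), "imaging or clinical")
})
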
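test_that("layer network detects a planted within-layer dependency", {
  ch <- chain_spec(c("MK03", "GSK3AB", "HSPB1"), 0.9)
  co <- generate_cohort(default_layers("test"), 400, chains = list(ch),
                        seed = 21)
  net <- build_layer_network(co, "proteomics",
                             topo_config(n_surrogates = 300), seed = 1)
  keys <- mlnetpath:::edge_key(net$edges$from, net$edges$to)
  expect_true(mlnetpath:::edge_key("MK03", "GSK3AB") %in% keys)
  expect_true(mlnetpath:::edge_key("GSK3AB", "HSPB1") %in% keys)
  expect_true(all(net$edges$weight >= 0 & net$edges$weight <= 1))
  expect_true(all(net$edges$method == "MI"))
})

test_that("single-feature layers and unknown layers are handled", {
  layers <- list(layer_spec("imaging", "mRNFL"),
                 layer_spec("clinical", c("EDSS", "ARMSS")))
  co <- generate_cohort(layers, 30, seed = 1)
  net <- build_layer_network(co, "imaging")
  expect_equal(nrow(net$edges), 0)
  expect_equal(nrow(net$nodes), 1)
  expect_error(build_layer_network(co, "cytomics"), "unknown layer")
})

test_that("interlayer edges find planted cross-layer links and reject disjoint subjects", {
  ch <- chain_spec(c("Total_T", "mRNFL"), 0.9)
  co <- generate_cohort(default_layers("test"), 400, chains = list(ch),
                        seed = 22)
  edges <- build_interlayer_edges(co, "cytomics", "imaging",
                                  topo_config(n_surrogates = 300), seed = 2)
  keys <- mlnetpath:::edge_key(edges$from, edges$to)
  expect_true(mlnetpath:::edge_key("Total_T", "mRNFL") %in% keys)

  # complementary missingness leaves no shared subjects
  co$layers$cytomics[1:200, ] <- NA
  co$layers$imaging[201:400, ] <- NA
  expect_error(build_interlayer_edges(co, "cytomics", "imaging"),
               "complete data")
})

test_that("network density follows the weighted-ratio definition", {
  ids <- c("a", "b", "c", "d")
  nodes <- data.frame(id = ids, layer = "x")
  cmb <- combn(ids, 2)
  full <- ml_network(nodes, data.frame(from = cmb[1, ], to = cmb[2, ],
                                       weight = 1, method = "MI"))
  expect_equal(network_density(full, ids), 1)

  three <- ml_network(data.frame(id = ids[1:3], layer = "x"),
                      data.frame(from = c("a", "b"), to = c("b", "c"),
                                 weight = 0.5, method = "MI"))
  expect_equal(network_density(three, ids[1:3]), 1 / 3)

  empty <- ml_network(nodes)
  expect_equal(network_density(empty, ids), 0)
  expect_error(network_density(full, "a"), "at least 2 nodes")

  # between-set mode normalizes by |a| * |b| and requires disjoint sets
  two_layer <- ml_network(
    data.frame(id = c("a", "b", "u", "v"), layer = c("x", "x", "y", "y")),
    data.frame(from = "a", to = "u", weight = 0.8, method = "MI"))
  expect_equal(network_density(two_layer, c("a", "b"), c("u", "v")), 0.2)
  expect_error(network_density(two_layer, c("a", "b"), c("b", "u")),
               "disjoint")
})

test_that("degree statistics report hubs with deterministic tie-breaks", {
  star <- ml_network(
    data.frame(id = c("hub", "a", "b", "c", "d"), layer = "x"),
    data.frame(from = "hub", to = c("a", "b", "c", "d"), weight = 1,
               method = "MI"))
  ds <- degree_stats(star)
  expect_equal(ds$hubs$id[1], "hub")
  expect_equal(ds$hubs$degree[1], 4)
  expect_equal(unname(ds$layer_means["x"]), 8 / 5)

  edgeless <- ml_network(data.frame(id = letters[1:4], layer = "x"))
  expect_true(all(degree_stats(edgeless)$degrees$degree == 0))

  # two equal-degree candidates: lexicographically smaller id first
  tie <- ml_network(
    data.frame(id = c("zed", "amy", "mid"), layer = "x"),
    data.frame(from = c("zed", "amy"), to = c("mid", "mid"), weight = 1,
               method = "MI"))
  expect_equal(degree_stats(tie, n_hubs = 3)$hubs$id, c("mid", "amy", "zed"))
})

test_that("degree-distribution comparison behaves across regimes", {
  ident <- compare_degree_distributions(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(ident$p_value, 0.9)

  sep <- compare_degree_distributions(rep(0, 4), rep(5, 4))
  expect_lt(sep$p_value, 0.05)
  expect_equal(sep$direction, "b_greater")

  tied <- compare_degree_distributions(rep(2, 5), rep(2, 5))
  expect_true(tied$degenerate)
  expect_equal(tied$p_value, 1)

  # type-I calibration: two samples from one distribution
  set.seed(12)
  rej <- replicate(400, {
    compare_degree_distributions(rpois(15, 4), rpois(15, 4))$p_value < 0.05
  })
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.10)
})
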
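test_that("cohort generation is deterministic under a fixed seed", {
  layers <- default_layers("test")
  ch <- chain_spec(c("MK03", "Total_T"), 0.8)
  a <- generate_cohort(layers, 30, chains = list(ch), missing_rate = 0.1,
                       seed = 7)
  b <- generate_cohort(layers, 30, chains = list(ch), missing_rate = 0.1,
                       seed = 7)
  expect_identical(a$layers, b$layers)
  expect_identical(a$weights, b$weights)
  c2 <- generate_cohort(layers, 30, chains = list(ch), missing_rate = 0.1,
                        seed = 8)
  expect_false(identical(a$layers, c2$layers))
})

test_that("features off any chain are mutually independent", {
  co <- generate_cohort(default_layers("test"), 2000, seed = 3)
  feats <- names(co$feature_layer)
  feats <- feats[!startsWith(feats, "MSGB")]  # scores derive from dosages
  vals <- do.call(cbind, lapply(feats, function(f) {
    co$layers[[co$feature_layer[[f]]]][, f]
  }))
  r <- cor(vals)
  off <- abs(r[upper.tri(r)])
  expect_gte(mean(off < 0.1), 0.99)
})

test_that("planted chain links attain their target correlation", {
  feats <- planted_chain_features()
  link_r <- function(seed) {
    co <- planted_chain_cohort(seed, n = 500)
    sapply(seq_len(length(feats) - 1), function(i) {
      a <- co$layers[[co$feature_layer[[feats[i]]]]][, feats[i]]
      b <- co$layers[[co$feature_layer[[feats[i + 1]]]]][, feats[i + 1]]
      cor(a, b)
    })
  }
  # single realization stays near the target
  expect_true(all(abs(link_r(1) - 0.9) < 0.1))
  # and so does the average over many seeds (generator contract)
  mean_r <- rowMeans(sapply(1:20, link_r))
  expect_true(all(abs(mean_r - 0.9) < 0.1))
})

test_that("chain validation rejects malformed specifications", {
  layers <- default_layers("test")
  expect_error(generate_cohort(layers, 20,
                               chains = list(chain_spec(c("MK03", "nope")))),
               "unknown feature")
  expect_error(generate_cohort(layers, 20,
                               chains = list(chain_spec(c("MK03", "EDSS")))),
               "adjacent")
  expect_error(generate_cohort(layers, 20,
                               chains = list(chain_spec(c("MK03", "MSGB_total")))),
               "burden score")
  expect_error(chain_spec(c("a", "b"), 1.2), "strengths")
  expect_error(generate_cohort(layers, 5), "n_subjects")
  expect_error(generate_cohort(layers, 20, missing_rate = 1), "missing_rate")
})

test_that("missingness removes whole subject-layer blocks", {
  co <- generate_cohort(default_layers("test"), 200, missing_rate = 0.3,
                        seed = 5)
  for (lay in names(co$layers)) {
    m <- co$layers[[lay]]
    na_frac <- rowMeans(is.na(m))
    expect_true(all(na_frac %in% c(0, 1)))  # all-or-nothing per row
  }
  cc <- complete_subjects(co)
  full <- Reduce(`&`, lapply(co$layers, complete.cases))
  expect_identical(cc, co$subjects[full])
  expect_gt(length(cc), 0)
})

test_that("burden score is the weighted dosage sum with exact partitioning", {
  w <- data.frame(locus = c("a", "b"), beta = c(0.2, 0.5),
                  hla = c(FALSE, TRUE))
  g <- matrix(c(2, 1), 1, dimnames = list("s1", c("a", "b")))
  expect_equal(unname(compute_msgb(g, w)), 0.9)
  g0 <- matrix(0, 3, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(compute_msgb(g0, w)), c(0, 0, 0))

  # linearity in the betas and exact subset additivity on a larger fixture
  weights <- msgb_weights(seed = 2)
  geno <- matrix(sample(0:2, 40 * nrow(weights), replace = TRUE), 40,
                 dimnames = list(NULL, weights$locus))
  total <- compute_msgb(geno, weights, "all")
  w3 <- weights; w3$beta <- 3 * w3$beta
  expect_equal(compute_msgb(geno, w3, "all"), 3 * total)
  expect_identical(total, compute_msgb(geno, weights, "hla") +
                     compute_msgb(geno, weights, "non_hla"))

  expect_error(compute_msgb(geno[, -1], weights), "absent")
  g_bad <- geno; g_bad[1, 1] <- 0.5
  expect_error(compute_msgb(g_bad, weights), "integers")
})

test_that("regulatory reference generator honors its contract", {
  grn <- generate_grn(n_tfs = 4, n_genes = 6, snps_per_gene = 2, seed = 9)
  expect_identical(grn, generate_grn(4, 6, 2, seed = 9))
  counts <- table(grn$snp_to_gene$gene)
  expect_true(all(counts == 2))
  expect_equal(nrow(grn$snp_to_gene), 12)
  expect_false(any(grn$edges$tf == grn$edges$target))
  expect_false(anyDuplicated(grn$snp_to_gene$snp) > 0)

  empty <- generate_grn(n_tfs = 0, n_genes = 3, snps_per_gene = 1, seed = 1)
  expect_equal(nrow(empty$edges), 0)
  expect_equal(nrow(empty$snp_to_gene), 3)
})

test_that("cohort and GRN round-trip through their delimited formats", {
  co <- generate_cohort(default_layers("test"), 25, missing_rate = 0.2,
                        seed = 11)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$layers, co$layers)
  expect_equal(back$roles$input, co$roles$input)
  expect_equal(back$roles$output, co$roles$output)

  grn <- generate_grn(3, 4, 2, seed = 2)
  gdir <- withr::local_tempdir()
  write_grn(grn, gdir)
  back_g <- read_grn(gdir)
  expect_equal(back_g$edges, grn$edges)
  expect_equal(back_g$snp_to_gene, grn$snp_to_gene)
})
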
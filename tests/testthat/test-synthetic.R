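test_that("simulation is deterministic under the seed", {
  cfg <- synthetic_config(n_genes = 40, seed = 99)
  s1 <- simulate_expression_dataset(cfg)
  s2 <- simulate_expression_dataset(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_expression_dataset(synthetic_config(n_genes = 40, seed = 100))
  expect_false(identical(s1$tables[[1]]$data$rpkm, s3$tables[[1]]$data$rpkm))
})

test_that("zero Brownian rate without noise gives identical species columns", {
  cfg <- synthetic_config(n_genes = 30, bm_sigma = 0, count_noise = "none",
                          seed = 5)
  sim <- simulate_expression_dataset(cfg)
  j <- join_orthologs(sim$tables)
  expect_true(all(apply(j$values, 1, function(x) max(x) - min(x)) == 0))
  r <- suppressWarnings(stats::cor(j$values))   # columns identical -> r = 1
  expect_true(all(abs(r - 1) < 1e-12))
})

test_that("an injected 38-fold spike appears as a 38.00 fold difference", {
  cfg <- synthetic_config(
    n_genes = 20, bm_sigma = 0, count_noise = "none", seed = 6,
    spikes = data.frame(gene = "SPIKE1", target = "hooded_seal", fold = 38))
  sim <- simulate_expression_dataset(cfg)
  a <- gene_rpkm(sim$tables$hooded_seal, "SPIKE1")
  b <- gene_rpkm(sim$tables$ferret, "SPIKE1")
  expect_equal(round_half_up(signed_fold_change(a, b), 2), 38.00)
  # group spike hits every species of the group
  cfg2 <- synthetic_config(
    n_genes = 20, bm_sigma = 0, count_noise = "none", seed = 6,
    spikes = data.frame(gene = "SPIKE1", target = "diving", fold = 10))
  sim2 <- simulate_expression_dataset(cfg2)
  f <- signed_fold_change(gene_rpkm(sim2$tables$minke_whale, "SPIKE1"),
                          gene_rpkm(sim2$tables$pig, "SPIKE1"))
  expect_equal(round_half_up(f, 2), 10.00)
})

test_that("spike validation rejects duplicates and unknown targets", {
  expect_error(synthetic_config(
    spikes = data.frame(gene = c("X", "x"), target = "human", fold = 2)),
    "duplicate spike")
  expect_error(synthetic_config(
    spikes = data.frame(gene = "X", target = "narwhal", fold = 2)),
    "unknown spike target")
  expect_error(synthetic_config(
    spikes = data.frame(gene = "X", target = "human", fold = 0)),
    "positive")
  expect_error(synthetic_config(tree = "not a tree"), "Newick")
})

test_that("marker ratios encode the configured glia fractions exactly", {
  sp <- ape::read.tree(text = default_species_tree())$tip.label
  gf <- setNames(c(0.048, 0.2, 0.5, 0.6, 0.8, 0.91), sp)
  cfg <- synthetic_config(n_genes = 10, count_noise = "none",
                          glia_fraction = gf, seed = 7)
  sim <- simulate_expression_dataset(cfg)
  for (s in sp) {
    prof <- glia_neuron_ratio(sim$tables[[s]])
    expect_equal(prof$ratio, gf[[s]] / (1 - gf[[s]]), tolerance = 1e-12)
  }
  expect_error(synthetic_config(glia_fraction = setNames(rep(1.2, 6), sp)),
               "\\(0, 1\\)")
})

test_that("confounded genes scale with the marker ratio", {
  sp <- ape::read.tree(text = default_species_tree())$tip.label
  gf <- setNames(c(0.1, 0.2, 0.5, 0.6, 0.8, 0.9), sp)
  cfg <- synthetic_config(n_genes = 10, bm_sigma = 0, count_noise = "none",
                          glia_fraction = gf, confounded_genes = "CONF",
                          seed = 8)
  sim <- simulate_expression_dataset(cfg)
  corrected <- vapply(sim$tables, function(t) {
    composition_correct(gene_rpkm(t, "CONF"), glia_neuron_ratio(t))
  }, numeric(1))
  expect_true(max(corrected) - min(corrected) < 1e-9 * max(corrected))
})

test_that("emitted counts satisfy RPKM-count conservation", {
  cfg <- synthetic_config(n_genes = 200, seed = 9)
  sim <- simulate_expression_dataset(cfg)
  for (t in sim$tables) {
    back <- sum(t$data$rpkm * t$data$length_bp) * t$library_size / 1e9
    expect_equal(back, sum(t$data$count), tolerance = 1e-6)
  }
})

test_that("log2 expression covariance follows the tree's shared path lengths", {
  cfg <- synthetic_config(n_genes = 20000, count_noise = "none", seed = 10)
  sim <- simulate_expression_dataset(cfg)
  j <- join_orthologs(sim$tables)
  keep <- setdiff(j$genes, c("GFAP", "RBFOX3"))
  x <- log2(j$values[keep, ])
  emp <- stats::cov(x)
  vcv <- ape::vcv(cfg$phy)[colnames(x), colnames(x)]
  expected <- cfg$baseline_log2_sd^2 + cfg$bm_sigma^2 * vcv
  off <- upper.tri(emp)
  expect_equal(emp[off], expected[off], tolerance = 0.1)
})

test_that("annotation simulator enriches the designated term and validates sizes", {
  sim <- simulate_annotation(reference_size = 2000, n_terms = 20,
                             enriched_term_genes = 100, query_size = 80,
                             enrichment_odds = 25, seed = 13)
  res <- suppressMessages(overrepresentation_test(sim$query, sim$annotation))
  expect_equal(res$term_id[1], sim$truth$enriched_term)
  expect_lt(res$p_adj[1], 0.05)

  one <- simulate_annotation(reference_size = 100, n_terms = 1,
                             enriched_term_genes = 10, query_size = 10,
                             enrichment_odds = 1, seed = 14)
  r1 <- overrepresentation_test(one$query, one$annotation)
  expect_equal(attr(r1, "m"), 1)

  expect_error(simulate_annotation(reference_size = 10, enriched_term_genes = 20),
               "exceed")
  expect_error(simulate_annotation(reference_size = 10, query_size = 20),
               "exceed")
  expect_error(simulate_annotation(enrichment_odds = 0), "positive")
})

test_that("flat key-value configs parse into full configurations", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c(
    "# simulation config",
    "n_genes = 25",
    "bm_sigma = 0.4",
    "seed = 3",
    "spikes = S100B:diving:38, CLU:hooded_seal:4",
    "confounded_genes = S100B",
    "glia_fraction = hooded_seal:0.3, ferret:0.5, minke_whale:0.7, bowhead_whale:0.6, pig:0.4, human:0.5",
    "gene_length_range = 600:3000"
  ), path)
  cfg <- read_synthetic_config(path)
  expect_equal(cfg$n_genes, 25L)
  expect_equal(cfg$bm_sigma, 0.4)
  expect_equal(cfg$spikes$fold, c(38, 4))
  expect_equal(cfg$confounded_genes, "S100B")
  expect_equal(cfg$glia_fraction[["minke_whale"]], 0.7)
  expect_equal(cfg$gene_length_range, c(600L, 3000L))
  sim <- simulate_expression_dataset(cfg)
  expect_equal(length(sim$tables), 6)
  expect_true(all(sim$tables$hooded_seal$data$length_bp >= 600 &
                  sim$tables$hooded_seal$data$length_bp <= 3000))
})
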
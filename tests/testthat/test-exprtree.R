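joined_from_matrix <- function(values) {
  tabs <- lapply(colnames(values), function(s) {
    toy_table(s, rownames(values), values[, s])
  })
  join_orthologs(tabs)
}

test_that("pearson_matrix computes standard correlations with guards", {
  v <- matrix(c(1, 2, 3, 1, 2, 4, 1, 2, 3), nrow = 3,
              dimnames = list(c("GA", "GB", "GC"), c("s1", "s2", "s3")))
  r <- pearson_matrix(joined_from_matrix(v))
  expect_equal(r["s1", "s3"], 1)                 # duplicated columns
  expect_equal(r["s1", "s2"], 0.981981, tolerance = 1e-5)
  expect_equal(r, t(r))
  expect_equal(diag(r), c(s1 = 1, s2 = 1, s3 = 1))
  expect_equal(attr(r, "n_genes"), 3)

  # a column reflected about its mean correlates at -1
  v2 <- v; v2[, "s3"] <- 2 * mean(v[, "s1"]) - v[, "s1"]
  r2 <- pearson_matrix(joined_from_matrix(v2))
  expect_equal(r2["s1", "s3"], -1)

  v3 <- v; v3[, "s2"] <- 7
  expect_error(pearson_matrix(joined_from_matrix(v3)), "constant.*s2")
})

test_that("correlation_to_distance supports both transforms", {
  expect_equal(correlation_to_distance(1), 0)
  expect_equal(correlation_to_distance(0), 1)
  expect_equal(correlation_to_distance(-1), 2)
  expect_equal(correlation_to_distance(0.5, "sqrt"), 1)
  expect_equal(correlation_to_distance(1, "sqrt"), 0)
  expect_error(correlation_to_distance(1.01), "\\[-1, 1\\]")
  m <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  dm <- correlation_to_distance(m)
  expect_equal(diag(dm), c(a = 0, b = 0))
  expect_equal(dm["a", "b"], 0.5)
})

test_that("three-taxon NJ uses the closed-form star", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  lens <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(lens[c("A", "B", "C")], c(A = 1, B = 2, C = 3))
  expect_equal(to_newick(tr), "(A:1.000000,B:2.000000,C:3.000000);")
})

test_that("four-taxon additive matrix is reconstructed exactly", {
  # distances generated from the tree ((A:1,B:2):1,C:3,D:4) and verified
  # against the four-point condition
  labs <- c("A", "B", "C", "D")
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, dimnames = list(labs, labs))
  expect_equal(d["A", "B"] + d["C", "D"], 10)        # smallest sum: AB|CD split
  tr <- neighbor_joining(d)
  truth <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:4);")
  expect_same_topology(tr, truth)
  expect_equal(tree_path_lengths(tr, labs), d, tolerance = 1e-12)
})

test_that("NJ reproduces additive matrices from random trees", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    gen <- ape::rtree(n, rooted = FALSE)
    d <- ape::cophenetic.phylo(gen)
    tr <- neighbor_joining(d)
    expect_same_topology(tr, gen)
    expect_equal(tree_path_lengths(tr, rownames(d)), d, tolerance = 1e-9)
  }
})

test_that("NJ topology agrees with an independent implementation on noisy matrices", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    gen <- ape::rtree(n, rooted = FALSE)
    d <- ape::cophenetic.phylo(gen)
    noise <- matrix(runif(n * n, 0, 0.2 * mean(d)), n)
    noise <- (noise + t(noise)) / 2; diag(noise) <- 0
    dn <- d + noise
    dimnames(dn) <- dimnames(d)
    mine <- neighbor_joining(dn, clamp_negative = FALSE)
    ref <- ape::nj(dn)
    expect_same_topology(mine, ref)
  }
})

test_that("NJ is invariant under taxon relabeling/permutation", {
  set.seed(43)
  gen <- ape::rtree(7, rooted = FALSE)
  d <- ape::cophenetic.phylo(gen)
  t1 <- neighbor_joining(d)
  perm <- sample(nrow(d))
  t2 <- neighbor_joining(d[perm, perm])
  expect_same_topology(t1, t2)
})

test_that("NJ validates its input", {
  d <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(neighbor_joining(d), "at least 3")
  d3 <- matrix(c(0, 1, 2, 9, 0, 3, 2, 3, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(d3), "symmetric")
  d4 <- matrix(c(0, -1, 2, -1, 0, 3, 2, 3, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(d4), "non-negative")
})

test_that("negative branch lengths are clamped with path preserved at the join", {
  # a strongly non-additive matrix that yields a negative NJ branch
  labs <- c("A", "B", "C", "D")
  d <- matrix(c(0, 0.1, 1, 1,
                0.1, 0, 1, 1.9,
                1, 1, 0, 0.1,
                1, 1.9, 0.1, 0), 4, dimnames = list(labs, labs))
  raw <- neighbor_joining(d, clamp_negative = FALSE)
  clamped <- neighbor_joining(d)
  expect_true(any(raw$edge.length < 0) || all(clamped$edge.length >= 0))
  expect_true(all(clamped$edge.length >= 0))
  expect_same_topology(raw, clamped)
})

test_that("newick serialization round-trips and validates labels", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  back <- ape::read.tree(text = to_newick(tr))
  expect_same_topology(tr, back)
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-6)
  bad <- tr; bad$tip.label[2] <- ""
  expect_error(to_newick(bad), "labeled")
  nolen <- tr; nolen$edge.length <- NULL
  expect_error(to_newick(nolen), "branch lengths")
})

test_that("PHYLIP distance files have the square format", {
  labs <- c("hooded_seal", "ferret", "minke", "pig")
  d <- matrix(0.25, 4, 4, dimnames = list(labs, labs)); diag(d) <- 0
  path <- withr::local_tempfile()
  write_phylip_distances(d, path)
  lines <- readLines(path)
  expect_length(lines, 5)
  expect_equal(lines[1], "4")
  expect_equal(substr(lines[2], 1, 10), "hooded_sea")   # padded/truncated to 10
  expect_equal(substr(lines[3], 1, 10), "ferret    ")
  nums <- as.numeric(strsplit(trimws(substr(lines[2], 11, nchar(lines[2]))),
                              " +")[[1]])
  expect_equal(nums, c(0, 0.25, 0.25, 0.25))
})
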
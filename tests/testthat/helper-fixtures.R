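# small deterministic fixtures used across tests

toy_table <- function(species, genes, rpkm, lib = 1e6) {
  expression_table(species, genes, lib, rpkm = rpkm)
}

# a pair of three-gene tables sharing two symbols
toy_pair <- function() {
  list(
    toy_table("seal", c("A", "B", "C"), c(10, 20, 30)),
    toy_table("ferret", c("B", "C", "D"), c(5, 60, 7))
  )
}

# joined matrix directly from per-species rpkm vectors (shared gene set)
toy_joined <- function(...) {
  tabs <- list(...)
  join_orthologs(tabs)
}

# independent binomial-tail oracle: direct summation of the pmf via lchoose
binom_tail_oracle <- function(k, n, p0) {
  pmf <- function(x) exp(lchoose(n, x) + x * log(p0) + (n - x) * log1p(-p0))
  list(over = sum(vapply(k:n, pmf, numeric(1))),
       under = sum(vapply(0:k, pmf, numeric(1))))
}

# leaf-to-leaf path lengths of a phylo tree, ordered by label
tree_path_lengths <- function(tree, labels) {
  pl <- ape::cophenetic.phylo(tree)
  pl[labels, labels]
}

expect_same_topology <- function(t1, t2) {
  expect_equal(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)), 0)
}
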
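#' Pearson correlation matrix across species
#'
#' Pairwise Pearson correlation of expression values over the shared gene
#' set of a joined matrix. By default correlation is computed on the
#' untransformed values; `log2_transform = TRUE` uses log2(x + 1).
#'
#' @param joined A `joined_matrix` with at least 3 species and 3 genes.
#' @param log2_transform Apply log2(x + 1) before correlating (default FALSE).
#' @return Symmetric correlation matrix (species x species, unit diagonal)
#'   with attribute `n_genes`.
#' @export
pearson_matrix <- function(joined, log2_transform = FALSE) {
  stopifnot(inherits(joined, "joined_matrix"))
  v <- joined$values
  if (ncol(v) < 3) fail("need at least 3 species")
  if (nrow(v) < 3) fail("need at least 3 genes")
  if (log2_transform) v <- log2(v + 1)
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0)) {
    fail("constant expression column for species: ",
         paste(colnames(v)[sds == 0], collapse = ", "))
  }
  r <- stats::cor(v)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  attr(r, "n_genes") <- nrow(v)
  r
}

#' Convert correlation coefficients to distances
#'
#' Default transform is `d = 1 - r`; the `sqrt` mode `d = sqrt(2 (1 - r))`
#' is provided because it is a metric (it is the Euclidean distance between
#' standardized vectors).
#'
#' @param r Correlation value(s) or matrix, in `[-1, 1]`.
#' @param transform `"one_minus_r"` (default) or `"sqrt"`.
#' @return Distances of the same shape as `r`; matrix input gets an exact
#'   zero diagonal.
#' @export
correlation_to_distance <- function(r, transform = c("one_minus_r", "sqrt")) {
  transform <- match.arg(transform)
  check_finite_numeric(r, "r")
  if (any(abs(r) > 1 + 1e-12)) fail("correlations must lie in [-1, 1]")
  # tolerate float rounding just past +/-1
  r <- pmin(pmax(r, -1), 1)
  d <- if (transform == "one_minus_r") 1 - r else sqrt(2 * (1 - r))
  if (is.matrix(d)) diag(d) <- 0
  d
}

# internal: validate a distance matrix for tree building
check_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) fail("d must be a square matrix")
  if (nrow(d) < 3) fail("need at least 3 taxa")
  if (is.null(rownames(d))) fail("d must have taxon labels as dimnames")
  if (any(!is.finite(d))) fail("distances must be finite")
  if (any(d < 0)) fail("distances must be non-negative")
  if (max(abs(d - t(d))) > 1e-8 * max(1, max(abs(d)))) fail("d must be symmetric")
  if (any(diag(d) != 0)) fail("d must have a zero diagonal")
  invisible(d)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Studier-Keppler Q criterion
#' \deqn{Q_{ij} = (m - 2) d_{ij} - r_i - r_j, \qquad r_i = \sum_k d_{ik},}
#' joining the pair with minimal Q at each step; ties are broken by the
#' lowest (row, column) index pair so the result is deterministic. Branch
#' lengths to the new node are
#' \deqn{b_i = d_{ij}/2 + (r_i - r_j) / (2 (m - 2)), \quad b_j = d_{ij} - b_i.}
#' For three remaining taxa the unique unrooted star is returned with
#' \eqn{a = (d_{AB} + d_{AC} - d_{BC})/2} etc. Negative branch lengths are
#' clamped to zero with the deficit transferred to the sibling branch (so
#' path lengths through the pair are preserved); set
#' `clamp_negative = FALSE` for raw lengths. On an additive matrix the tree's
#' leaf-to-leaf path lengths reproduce the input distances exactly.
#'
#' @param d Symmetric non-negative distance matrix with zero diagonal and
#'   taxon labels as dimnames; at least 3 taxa.
#' @param clamp_negative Clamp negative branch lengths (default TRUE).
#' @return An unrooted `phylo` tree (class from the ape package) whose tip
#'   labels are the taxon labels.
#' @export
neighbor_joining <- function(d, clamp_negative = TRUE) {
  check_distance_matrix(d)
  d <- (d + t(d)) / 2
  labs <- rownames(d)
  if (anyDuplicated(labs)) fail("taxon labels must be unique")
  # each active cluster carries its subtree as a newick fragment
  nodes <- as.list(labs)
  D <- unname(d)

  fmt <- function(x) sprintf("%.17g", x)
  pair_lengths <- function(bi, bj) {
    if (clamp_negative) {
      if (bi < 0) { bj <- bj + bi; bi <- 0 }
      if (bj < 0) { bi <- bi + bj; bj <- 0 }
      bi <- max(bi, 0); bj <- max(bj, 0)
    }
    c(bi, bj)
  }

  while (length(nodes) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    best <- c(NA, NA); best_q <- Inf
    for (i in 1:(m - 1)) {
      for (j in (i + 1):m) {
        q <- (m - 2) * D[i, j] - r[i] - r[j]
        if (q < best_q) { best_q <- q; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    b <- pair_lengths(bi, D[i, j] - bi)
    merged <- sprintf("(%s:%s,%s:%s)", nodes[[i]], fmt(b[1]),
                      nodes[[j]], fmt(b[2]))
    keep <- setdiff(seq_len(m), c(i, j))
    dnew <- (D[i, keep] + D[j, keep] - D[i, j]) / 2
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew), c(dnew, 0))
    nodes <- c(nodes[keep], merged)
  }

  # terminal 3-taxon star
  a <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  c3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  if (clamp_negative) { a <- max(a, 0); b <- max(b, 0); c3 <- max(c3, 0) }
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 nodes[[1]], fmt(a), nodes[[2]], fmt(b), nodes[[3]], fmt(c3))
  ape::read.tree(text = nwk)
}

#' Serialize a tree to Newick text
#'
#' Branch lengths are printed with a fixed number of decimal places
#' (default 6) and the string is terminated by a semicolon.
#'
#' @param tree A `phylo` object with branch lengths and labeled tips.
#' @param digits Decimal places for branch lengths.
#' @return A single Newick string.
#' @export
to_newick <- function(tree, digits = 6) {
  if (!inherits(tree, "phylo")) fail("tree must be a phylo object")
  if (is.null(tree$edge.length)) fail("tree has no branch lengths")
  if (is.null(tree$tip.label) || any(is.na(tree$tip.label)) ||
      any(!nzchar(tree$tip.label))) {
    fail("every leaf must be labeled")
  }
  ntip <- length(tree$tip.label)
  fmt <- function(node) {
    rows <- which(tree$edge[, 1] == node)
    parts <- vapply(rows, function(e) {
      child <- tree$edge[e, 2]
      lab <- if (child <= ntip) tree$tip.label[child] else fmt(child)
      sprintf("%s:%.*f", lab, digits, tree$edge.length[e])
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(fmt(ntip + 1L), ";")
}

#' Write a PHYLIP square-format distance file
#'
#' First line is the taxon count; each following line is a taxon name padded
#' (or truncated) to 10 characters followed by the full row of distances.
#'
#' @param d Labeled square distance matrix.
#' @param path Output file.
#' @export
write_phylip_distances <- function(d, path) {
  check_distance_matrix(d)
  labs <- rownames(d)
  pad <- sprintf("%-10s", substr(labs, 1, 10))
  rows <- vapply(seq_len(nrow(d)), function(i) {
    paste0(pad[i], paste(sprintf("%.6f", d[i, ]), collapse = "  "))
  }, character(1))
  writeLines(c(as.character(nrow(d)), rows), path)
  invisible(path)
}

#' Correlation-based expression phylogeny
#'
#' Convenience pipeline: Pearson correlation over a joined (optionally
#' composition-corrected) expression matrix, conversion to distances, and
#' neighbor joining.
#'
#' @param joined A `joined_matrix` (>= 3 species).
#' @param transform Distance transform, see [correlation_to_distance()].
#' @param log2_transform See [pearson_matrix()].
#' @return List with `r` (correlation matrix), `d` (distance matrix) and
#'   `tree` (unrooted `phylo`).
#' @export
expression_tree <- function(joined, transform = "one_minus_r",
                            log2_transform = FALSE) {
  r <- pearson_matrix(joined, log2_transform = log2_transform)
  d <- correlation_to_distance(r, transform = transform)
  list(r = r, d = d, tree = neighbor_joining(d))
}
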
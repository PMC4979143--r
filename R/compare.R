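#' Join per-species expression tables on shared gene symbols
#'
#' Cross-species comparison is done on the intersection of (uppercased) gene
#' symbols: a gene absent from any table is dropped rather than treated as
#' zero, since absence may reflect annotation failure rather than silence.
#' Genes are ordered lexicographically (C locale) for determinism.
#'
#' @param tables List of at least two [expression_table()] objects with
#'   distinct species ids.
#' @return An object of class `joined_matrix`: list with `genes`, `species`,
#'   `values` (genes x species RPKM matrix), and filter provenance fields
#'   `filter_min_rpkm`, `filter_mode` (both `NA` until [filter_expressed()]
#'   is applied).
#' @export
join_orthologs <- function(tables) {
  if (!is.list(tables) || length(tables) < 2) {
    fail("need at least two expression tables")
  }
  ok <- vapply(tables, inherits, logical(1), what = "expression_table")
  if (!all(ok)) fail("all elements must be expression_table objects")
  species <- vapply(tables, function(t) t$species_id, character(1))
  if (anyDuplicated(species)) fail("species ids must be distinct")
  shared <- Reduce(intersect, lapply(tables, function(t) t$data$gene))
  if (length(shared) == 0) fail("no shared gene symbols across the tables")
  shared <- sort(shared, method = "radix")
  values <- vapply(tables, function(t) {
    t$data$rpkm[match(shared, t$data$gene)]
  }, numeric(length(shared)))
  values <- matrix(values, nrow = length(shared),
                   dimnames = list(shared, species))
  structure(
    list(genes = shared, species = species, values = values,
         filter_min_rpkm = NA_real_, filter_mode = NA_character_),
    class = "joined_matrix"
  )
}

#' @export
print.joined_matrix <- function(x, ...) {
  cat(sprintf("joined_matrix: %d genes x %d species (%s)\n",
              length(x$genes), length(x$species),
              paste(x$species, collapse = ", ")))
  if (!is.na(x$filter_min_rpkm)) {
    cat(sprintf("filtered: RPKM %s %g in %s\n",
                if (x$filter_mode == "strict_greater") ">" else ">=",
                x$filter_min_rpkm,
                if (isTRUE(attr(x, "require_all"))) "all species" else "any species"))
  }
  invisible(x)
}

#' Filter a joined matrix on minimum expression
#'
#' Retains genes whose RPKM passes the threshold in all species
#' (`require_all = TRUE`, the analysis-set convention: e.g. RPKM > 5 in both
#' species) or in any species. The threshold test is strict `>` by default,
#' with a `greater_equal` mode.
#'
#' @param joined A `joined_matrix`.
#' @param min_rpkm Threshold (default 5).
#' @param mode `"strict_greater"` (default) or `"greater_equal"`.
#' @param require_all Require the test to pass in every species (default) or
#'   in at least one.
#' @return A filtered `joined_matrix` with filter provenance recorded.
#' @export
filter_expressed <- function(joined, min_rpkm = 5,
                             mode = c("strict_greater", "greater_equal"),
                             require_all = TRUE) {
  stopifnot(inherits(joined, "joined_matrix"))
  mode <- match.arg(mode)
  pass <- if (mode == "strict_greater") joined$values > min_rpkm else joined$values >= min_rpkm
  keep <- if (require_all) rowSums(pass) == ncol(pass) else rowSums(pass) > 0
  out <- joined
  out$genes <- joined$genes[keep]
  out$values <- joined$values[keep, , drop = FALSE]
  out$filter_min_rpkm <- min_rpkm
  out$filter_mode <- mode
  attr(out, "require_all") <- require_all
  out
}

#' Signed fold difference between two expression values
#'
#' The ratio of the larger to the smaller value, negated when the second
#' (reference) value is the larger one; its magnitude is always >= 1 and
#' equal values give +1. E.g. RPKM 3104.57 vs 777.62 gives 3.99 (2 dp),
#' while 1413.17 vs 3728.00 gives -2.64.
#'
#' @param rpkm_a,rpkm_b Positive expression values (vectors recycle).
#' @return Signed fold difference, `rpkm_a / rpkm_b` if `rpkm_a >= rpkm_b`,
#'   else `-(rpkm_b / rpkm_a)`.
#' @export
signed_fold_change <- function(rpkm_a, rpkm_b) {
  check_finite_numeric(rpkm_a, "rpkm_a")
  check_finite_numeric(rpkm_b, "rpkm_b")
  if (any(rpkm_a <= 0) || any(rpkm_b <= 0)) {
    fail("fold change undefined for non-positive RPKM; filter genes first")
  }
  ifelse(rpkm_a >= rpkm_b, rpkm_a / rpkm_b, -(rpkm_b / rpkm_a))
}

# internal: two-species fold-change data.frame for a joined matrix
fold_change_frame <- function(joined) {
  if (length(joined$species) != 2) {
    fail("fold-change operations need a joined matrix with exactly 2 species")
  }
  a <- joined$values[, 1]
  b <- joined$values[, 2]
  data.frame(gene = joined$genes, rpkm_a = unname(a), rpkm_b = unname(b),
             signed_fold = signed_fold_change(a, b),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank the top genes of a two-species comparison
#'
#' Ranks by expression in one species (the "most highly expressed genes"
#' table) or by absolute signed fold difference (the "largest differences"
#' table). Descending order; ties are broken lexicographically by symbol.
#'
#' @param joined A two-species `joined_matrix` (positive values; apply
#'   [filter_expressed()] first).
#' @param by `"expression"` (requires `species`) or `"abs_fold"`.
#' @param n Number of genes to report (capped at the number available).
#' @param species For `by = "expression"`, which species column to rank on.
#' @return data.frame with columns `gene`, `rpkm_a`, `rpkm_b`, `signed_fold`
#'   (a/b orientation follows the joined matrix's species order).
#' @export
rank_top_genes <- function(joined, by = c("expression", "abs_fold"), n = 10,
                           species = NULL) {
  stopifnot(inherits(joined, "joined_matrix"))
  by <- match.arg(by)
  if (n < 1) fail("n must be a positive integer")
  fc <- fold_change_frame(joined)
  key <- if (by == "expression") {
    if (is.null(species)) fail("by = 'expression' needs a species id")
    col <- match(species, joined$species)
    if (is.na(col)) fail("unknown species id: ", species)
    joined$values[, col]
  } else {
    abs(fc$signed_fold)
  }
  ord <- order(-key, fc$gene, method = "radix")
  fc[ord[seq_len(min(n, nrow(fc)))], , drop = FALSE]
}

#' Select differentially expressed genes by fold threshold
#'
#' Genes with at least a `min_fold` expression difference in the requested
#' direction; the twofold boundary is inclusive (a fold of exactly 2 counts
#' as "at least twofold").
#'
#' @param joined A two-species `joined_matrix` with positive values.
#' @param min_fold Minimum fold magnitude, >= 1 (default 2).
#' @param direction `"a_over_b"` (first species higher) or `"b_over_a"`.
#' @return Character vector of gene symbols.
#' @export
select_differential <- function(joined, min_fold = 2,
                                direction = c("a_over_b", "b_over_a")) {
  stopifnot(inherits(joined, "joined_matrix"))
  direction <- match.arg(direction)
  if (!is.numeric(min_fold) || length(min_fold) != 1 || min_fold < 1) {
    fail("min_fold must be a single number >= 1")
  }
  fc <- fold_change_frame(joined)
  keep <- if (direction == "a_over_b") fc$signed_fold >= min_fold
          else fc$signed_fold <= -min_fold
  fc$gene[keep]
}

#' Write a fold-change table as TSV
#'
#' Mirrors the published table layout: gene, per-species RPKM, fold
#' difference; RPKM and folds rounded half-up to 2 decimals for display.
#'
#' @param fc data.frame from [rank_top_genes()].
#' @param path Output file.
#' @param species Character vector of length 2 used for column names.
#' @export
write_fold_change_table <- function(fc, path, species = c("species_a", "species_b")) {
  out <- data.frame(
    gene = fc$gene,
    a = round_half_up(fc$rpkm_a, 2),
    b = round_half_up(fc$rpkm_b, 2),
    fold_difference = round_half_up(fc$signed_fold, 2)
  )
  names(out)[2:3] <- paste0(species, "_rpkm")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
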
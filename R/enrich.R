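#' Gene-set annotation against a reference list
#'
#' A flat term -> gene-set map plus a reference gene list (e.g. all human
#' genes). Only the part of each term that intersects the reference enters
#' any test; ontology structure (term hierarchies, ancestor propagation) is
#' deliberately not modeled — the annotation is taken as supplied.
#'
#' @param terms Named list; each element is `list(name = <description>,
#'   genes = <character vector>)`. Names are the term ids.
#' @param reference Character vector of reference gene symbols.
#' @return Object of class `gene_set_annotation`.
#' @export
gene_set_annotation <- function(terms, reference) {
  if (!is.list(terms) || is.null(names(terms)) || any(!nzchar(names(terms)))) {
    fail("terms must be a named list keyed by term id")
  }
  reference <- unique(toupper(as.character(reference)))
  if (length(reference) == 0) fail("reference list is empty")
  terms <- lapply(terms, function(t) {
    if (is.character(t)) t <- list(name = "", genes = t)
    list(name = as.character(t$name %||% ""),
         genes = unique(toupper(as.character(t$genes))))
  })
  structure(list(terms = terms, reference = reference),
            class = "gene_set_annotation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read gene sets in GMT format
#'
#' One term per line: term id, description, then member genes, all
#' tab-separated.
#'
#' @param path GMT file.
#' @param reference Character vector (or path to a one-symbol-per-line file)
#'   giving the reference gene list.
#' @return A [gene_set_annotation()].
#' @export
read_gmt <- function(path, reference) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2)
  if (length(bad) > 0) fail("malformed GMT line(s): ", paste(bad, collapse = ", "))
  ids <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(ids)) fail("duplicate term ids in ", path)
  terms <- lapply(fields, function(f) list(name = f[2], genes = f[-(1:2)]))
  names(terms) <- ids
  if (is.character(reference) && length(reference) == 1 && file.exists(reference)) {
    reference <- read_gene_list(reference)
  }
  gene_set_annotation(terms, reference)
}

#' @rdname read_gmt
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, encoding = "UTF-8"))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Gene-set overrepresentation test
#'
#' For each annotation term, tests whether the query list contains more (or
#' fewer) of the term's genes than expected from the term's frequency in the
#' reference list. With reference size \eqn{N}, term size \eqn{K_t} (within
#' the reference), query size \eqn{n} and \eqn{k} query genes in the term,
#' the default binomial model uses \eqn{p_0 = K_t / N} and
#' \deqn{p_{over} = P(X \ge k), \quad p_{under} = P(X \le k), \quad
#'       X \sim \mathrm{Binomial}(n, p_0).}
#' Both tails are always computed (underrepresentation is reported too);
#' the tail matching the observed direction is Bonferroni-adjusted by the
#' number of terms actually tested (those with \eqn{K_t > 0}). A Fisher's
#' exact mode (hypergeometric) is available for sensitivity analysis.
#'
#' Query genes outside the reference are dropped with a message.
#'
#' @param query Character vector of gene symbols.
#' @param annotation A [gene_set_annotation()].
#' @param method `"binomial"` (default) or `"fisher"`.
#' @return data.frame with one row per tested term, ordered by `p_adj` then
#'   term id: `term_id`, `term_name`, `n_list`, `k_obs`, `K_ref`, `expected`,
#'   `fold_enrichment`, `p_over`, `p_under`, `direction`, `p_raw`, `p_adj`.
#'   The number of tested terms is attached as attribute `m`.
#' @examples
#' ann <- gene_set_annotation(
#'   list(T1 = list(name = "toy", genes = paste0("G", 1:10))),
#'   reference = paste0("G", 1:100))
#' overrepresentation_test(paste0("G", c(1:5, 50:54)), ann)
#' @export
overrepresentation_test <- function(query, annotation,
                                    method = c("binomial", "fisher")) {
  stopifnot(inherits(annotation, "gene_set_annotation"))
  method <- match.arg(method)
  query <- unique(toupper(as.character(query)))
  outside <- setdiff(query, annotation$reference)
  if (length(outside) > 0) {
    message(length(outside), " query gene(s) not in the reference list were dropped")
    query <- setdiff(query, outside)
  }
  if (length(query) == 0) fail("empty query after reference intersection")
  N <- length(annotation$reference)
  n <- length(query)

  rows <- lapply(names(annotation$terms), function(id) {
    term <- annotation$terms[[id]]
    genes_t <- intersect(term$genes, annotation$reference)
    K <- length(genes_t)
    if (K == 0) return(NULL)
    k <- length(intersect(query, genes_t))
    p0 <- K / N
    expected <- n * p0
    if (method == "binomial") {
      p_over <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
      p_under <- stats::pbinom(k, n, p0)
    } else {
      tab <- matrix(c(k, n - k, K - k, N - K - (n - k)), nrow = 2)
      p_over <- stats::fisher.test(tab, alternative = "greater")$p.value
      p_under <- stats::fisher.test(tab, alternative = "less")$p.value
    }
    direction <- if (k >= expected) "over" else "under"
    data.frame(term_id = id, term_name = term$name, n_list = n, k_obs = k,
               K_ref = K, expected = expected,
               fold_enrichment = k / expected,
               p_over = p_over, p_under = p_under, direction = direction,
               p_raw = if (direction == "over") p_over else p_under,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) fail("no term overlaps the reference list")
  res <- do.call(rbind, rows)
  m <- nrow(res)
  res$p_adj <- bonferroni_adjust(res$p_raw, m)
  res <- res[order(res$p_adj, res$term_id, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "m") <- m
  res
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the number of tests `m` and caps at 1. `m`
#' defaults to the number of p-values supplied; the family size is exposed
#' because conventions differ on whether it should count all terms in an
#' ontology slim or only the terms actually tested.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param m Positive integer family size.
#' @return Adjusted p-values, order preserved.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  check_finite_numeric(p_values, "p_values")
  if (any(p_values < 0 | p_values > 1)) fail("p-values must lie in [0, 1]")
  if (!is.numeric(m) || length(m) != 1 || m < 1) fail("m must be a positive integer")
  pmin(1, p_values * m)
}

#' Write an enrichment result table as TSV
#'
#' @param result data.frame from [overrepresentation_test()].
#' @param path Output file.
#' @export
write_enrichment_table <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
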
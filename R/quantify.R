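#' RPKM from read counts
#'
#' Reads Per Kilobase of transcript per Million mapped reads:
#' \deqn{RPKM_g = 10^9 \, c_g / (N \, L_g)}
#' where \eqn{c_g} is the number of reads uniquely mapped to gene \eqn{g},
#' \eqn{L_g} the gene length in bp and \eqn{N} the library size (total mapped
#' reads). All arguments recycle to a common length.
#'
#' @param count Non-negative integer vector of mapped reads per gene.
#' @param gene_length_bp Positive gene (or transcript) length in base pairs.
#' @param library_size Positive total number of mapped reads in the library.
#' @return Numeric vector of RPKM values.
#' @examples
#' compute_rpkm(10, 1000, 1e6)        # 10
#' compute_rpkm(250, 2500, 5e6)       # 20
#' @export
compute_rpkm <- function(count, gene_length_bp, library_size) {
  check_finite_numeric(count, "count")
  check_finite_numeric(gene_length_bp, "gene_length_bp")
  check_finite_numeric(library_size, "library_size")
  if (any(count < 0)) fail("count must be non-negative")
  if (any(gene_length_bp <= 0)) fail("gene_length_bp must be positive")
  if (any(library_size <= 0)) fail("library_size must be positive")
  1e9 * as.numeric(count) / (as.numeric(library_size) * as.numeric(gene_length_bp))
}

#' Per-species gene expression table
#'
#' Container for one species' gene-level expression: gene symbols (uppercased,
#' unique), optional read counts and gene lengths, RPKM values, and the
#' library size. When counts and lengths are supplied, RPKM is (re)computed
#' with [compute_rpkm()]; a user-supplied `rpkm` vector is then validated
#' against the recomputation at 1e-6 relative tolerance.
#'
#' @param species_id Character scalar naming the species/sample.
#' @param gene Character vector of gene symbols (case-insensitive; stored
#'   uppercased).
#' @param library_size Positive integer, total mapped reads.
#' @param count Optional non-negative integer vector of read counts.
#' @param length_bp Optional positive integer vector of gene lengths.
#' @param rpkm Optional non-negative RPKM vector; required if `count` or
#'   `length_bp` is absent.
#' @return An object of class `expression_table`: a list with elements
#'   `species_id`, `data` (data.frame with columns `gene`, `count`,
#'   `length_bp`, `rpkm`) and `library_size`.
#' @export
expression_table <- function(species_id, gene, library_size,
                             count = NULL, length_bp = NULL, rpkm = NULL) {
  if (!is.character(species_id) || length(species_id) != 1 || !nzchar(species_id)) {
    fail("species_id must be a non-empty character scalar")
  }
  check_finite_numeric(library_size, "library_size")
  if (length(library_size) != 1 || library_size <= 0) {
    fail("library_size must be a single positive number")
  }
  gene <- toupper(as.character(gene))
  dup <- unique(gene[duplicated(gene)])
  if (length(dup) > 0) {
    fail("duplicate gene symbol(s) after uppercasing: ", paste(dup, collapse = ", "))
  }
  n <- length(gene)
  has_counts <- !is.null(count) && !is.null(length_bp)
  if (!has_counts && is.null(rpkm)) {
    fail("need either count + length_bp + library_size, or rpkm")
  }
  if (has_counts) {
    if (length(count) != n || length(length_bp) != n) {
      fail("count and length_bp must match the number of genes")
    }
    computed <- compute_rpkm(count, length_bp, library_size)
    if (!is.null(rpkm)) {
      check_finite_numeric(rpkm, "rpkm")
      rel <- abs(rpkm - computed) / pmax(abs(computed), .Machine$double.xmin)
      bad <- which(rel > 1e-6 & !(rpkm == 0 & computed == 0))
      if (length(bad) > 0) {
        fail("supplied rpkm inconsistent with counts for gene(s): ",
             paste(gene[bad], collapse = ", "))
      }
    }
    rpkm <- computed
  } else {
    check_finite_numeric(rpkm, "rpkm")
    if (any(rpkm < 0)) fail("rpkm must be non-negative")
    if (length(rpkm) != n) fail("rpkm must match the number of genes")
    count <- rep(NA_real_, n)
    length_bp <- rep(NA_real_, n)
  }
  structure(
    list(
      species_id = species_id,
      data = data.frame(gene = gene, count = as.numeric(count),
                        length_bp = as.numeric(length_bp),
                        rpkm = as.numeric(rpkm), stringsAsFactors = FALSE),
      library_size = as.numeric(library_size)
    ),
    class = "expression_table"
  )
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table: %s (%d genes, library size %s)\n",
              x$species_id, nrow(x$data),
              format(x$library_size, big.mark = ",", scientific = FALSE)))
  print(utils::head(x$data))
  if (nrow(x$data) > 6) cat(sprintf("... %d more genes\n", nrow(x$data) - 6))
  invisible(x)
}

#' Look up RPKM of one gene in an expression table
#'
#' @param table An `expression_table`.
#' @param gene Gene symbol (case-insensitive).
#' @return RPKM value, or `NA` if the gene is absent.
#' @export
gene_rpkm <- function(table, gene) {
  stopifnot(inherits(table, "expression_table"))
  i <- match(toupper(gene), table$data$gene)
  if (is.na(i)) return(NA_real_)
  table$data$rpkm[i]
}

#' Read / write expression tables as TSV
#'
#' The on-disk format is UTF-8 tab-separated text with `.` decimals: metadata
#' lines `# species_id=<id>` and `# library_size=<int>`, then a header row
#' `gene  count  length_bp  rpkm` (columns other than `gene` optional, empty
#' values allowed) and one row per gene. The round trip is lossless; RPKM is
#' written with 17 significant digits.
#'
#' @param path File path.
#' @param species_id Optional species id overriding the file's metadata line.
#' @return `read_expression_table` returns an [expression_table()];
#'   `write_expression_table` returns `path` invisibly.
#' @export
read_expression_table <- function(path, species_id = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  meta_idx <- grep("^#", lines)
  meta <- lines[meta_idx]
  get_meta <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "\\s*="), meta, value = TRUE)
    if (length(hit) == 0) return(NULL)
    trimws(sub("^[^=]*=", "", hit[1]))
  }
  lib <- get_meta("library_size")
  if (is.null(lib)) fail("missing '# library_size=' metadata line in ", path)
  lib <- as.numeric(lib)
  if (is.null(species_id)) species_id <- get_meta("species_id")
  if (is.null(species_id)) fail("no species_id: supply one or add '# species_id=' to ", path)

  body <- lines[setdiff(seq_along(lines), meta_idx)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 1) fail("no table content in ", path)
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene" %in% names(df)) fail("missing 'gene' column in ", path)
  num_or_null <- function(col) {
    if (!col %in% names(df)) return(NULL)
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (all(is.na(v))) NULL else v
  }
  expression_table(species_id, df$gene, lib,
                   count = num_or_null("count"),
                   length_bp = num_or_null("length_bp"),
                   rpkm = num_or_null("rpkm"))
}

#' @rdname read_expression_table
#' @param table An `expression_table` to serialize.
#' @export
write_expression_table <- function(table, path) {
  stopifnot(inherits(table, "expression_table"))
  d <- table$data
  fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  rows <- paste(d$gene, fmt_num(d$count), fmt_num(d$length_bp),
                fmt_num(d$rpkm), sep = "\t")
  writeLines(c(
    sprintf("# species_id=%s", table$species_id),
    sprintf("# library_size=%s", sprintf("%.17g", table$library_size)),
    "gene\tcount\tlength_bp\trpkm",
    rows
  ), path, useBytes = FALSE)
  invisible(path)
}
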
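#' Glia/neuron marker ratio of a brain sample
#'
#' The RPKM ratio of a glial marker (GFAP by default) to a neuronal marker
#' (RBFOX3/NeuN by default) is used as a proxy for the cell-type composition
#' of a bulk brain sample. A per-species neuronal-marker override is
#' supported for genomes where RBFOX3 is unannotated (e.g. SNAP25 in pig).
#'
#' @param table An [expression_table()].
#' @param glia_marker Glial marker symbol (default `"GFAP"`).
#' @param neuron_marker Neuronal marker symbol (default `"RBFOX3"`).
#' @return Object of class `composition_profile`: list with `species_id`,
#'   marker names and RPKMs, and `ratio = glia_rpkm / neuron_rpkm`.
#' @export
glia_neuron_ratio <- function(table, glia_marker = "GFAP",
                              neuron_marker = "RBFOX3") {
  stopifnot(inherits(table, "expression_table"))
  vals <- vapply(c(glia_marker, neuron_marker), function(m) {
    v <- gene_rpkm(table, m)
    if (is.na(v)) {
      fail("marker ", toupper(m), " absent from species ", table$species_id)
    }
    if (v <= 0) {
      fail("marker ", toupper(m), " has non-positive RPKM in species ",
           table$species_id)
    }
    v
  }, numeric(1))
  structure(
    list(species_id = table$species_id,
         glia_marker = toupper(glia_marker),
         neuron_marker = toupper(neuron_marker),
         glia_rpkm = vals[[1]], neuron_rpkm = vals[[2]],
         ratio = vals[[1]] / vals[[2]]),
    class = "composition_profile"
  )
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("composition_profile: %s  %s/%s = %.4g/%.4g = %.4g\n",
              x$species_id, x$glia_marker, x$neuron_marker,
              x$glia_rpkm, x$neuron_rpkm, x$ratio))
  invisible(x)
}

#' Composition-correct a target gene's expression
#'
#' Divides the target RPKM by the sample's glia/neuron marker ratio, i.e.
#' expresses the gene per unit of glial signal — appropriate for genes that
#' are predominantly astrocytic (such as S100B), where bulk RPKM scales with
#' the glial content of the sample. A `multiply` mode is provided since the
#' direction of normalisation is a modelling choice; genes expressed in both
#' neurons and glia (e.g. CLU) should not be corrected at all.
#'
#' @param target_rpkm Positive expression value(s).
#' @param profile A [glia_neuron_ratio()] profile (or a positive ratio).
#' @param mode `"divide"` (default) or `"multiply"`.
#' @return Corrected expression value(s).
#' @export
composition_correct <- function(target_rpkm, profile,
                                mode = c("divide", "multiply")) {
  mode <- match.arg(mode)
  ratio <- if (inherits(profile, "composition_profile")) profile$ratio else profile
  check_finite_numeric(ratio, "ratio")
  if (any(ratio <= 0)) fail("marker ratio must be positive")
  check_finite_numeric(target_rpkm, "target_rpkm")
  if (any(target_rpkm <= 0)) fail("target RPKM must be positive")
  if (mode == "divide") target_rpkm / ratio else target_rpkm * ratio
}

#' Two-group comparison of expression values
#'
#' Classic two-sample t-test between species groups (e.g. diving vs
#' non-diving mammals), two-tailed. The default is Student's pooled-variance
#' test; Welch's unequal-variance test is available via `variant`. Values
#' enter untransformed. Degenerate inputs: if both groups have (numerically)
#' zero variance and equal means the result is t = 0, p = 1; zero variance
#' with unequal means is an error.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param variant `"student_pooled"` (default) or `"welch"`.
#' @return Object of class `group_comparison`: list with `t_statistic`, `df`,
#'   `p_two_tailed`, `mean_a`, `mean_b`, `n_a`, `n_b`, `variant`.
#' @examples
#' two_group_ttest(c(1, 2, 3), c(4, 5, 6))
#' @export
two_group_ttest <- function(values_a, values_b,
                            variant = c("student_pooled", "welch")) {
  variant <- match.arg(variant)
  check_finite_numeric(values_a, "values_a")
  check_finite_numeric(values_b, "values_b")
  if (length(values_a) < 2 || length(values_b) < 2) {
    fail("each group needs at least 2 values")
  }
  va <- stats::var(values_a); vb <- stats::var(values_b)
  scale2 <- mean(c(values_a, values_b))^2 + 1
  degenerate <- (va + vb) / scale2 < 1e-24
  if (degenerate) {
    if (isTRUE(all.equal(mean(values_a), mean(values_b)))) {
      res <- list(t_statistic = 0,
                  df = length(values_a) + length(values_b) - 2,
                  p_two_tailed = 1)
    } else {
      fail("zero within-group variance with unequal means: t undefined")
    }
  } else {
    tt <- stats::t.test(values_a, values_b,
                        var.equal = (variant == "student_pooled"))
    res <- list(t_statistic = unname(tt$statistic), df = unname(tt$parameter),
                p_two_tailed = tt$p.value)
  }
  structure(
    c(res, list(mean_a = mean(values_a), mean_b = mean(values_b),
                n_a = length(values_a), n_b = length(values_b),
                variant = variant)),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("two-group comparison (%s): t = %.4g, df = %.4g, two-tailed p = %.4g\n",
              x$variant, x$t_statistic, x$df, x$p_two_tailed))
  cat(sprintf("group means: %.4g (n = %d) vs %.4g (n = %d)\n",
              x$mean_a, x$n_a, x$mean_b, x$n_b))
  invisible(x)
}

#' Read a species-group table
#'
#' TSV with columns `species_id`, `group`, and optionally
#' `neuron_marker_override` (empty = use the default neuronal marker).
#'
#' @param path TSV file.
#' @return data.frame with those columns.
#' @export
read_species_groups <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species_id", "group")
  if (!all(need %in% names(df))) {
    fail("species-group table needs columns: ", paste(need, collapse = ", "))
  }
  if (!"neuron_marker_override" %in% names(df)) {
    df$neuron_marker_override <- NA_character_
  }
  df$neuron_marker_override[!nzchar(trimws(
    ifelse(is.na(df$neuron_marker_override), "", df$neuron_marker_override)))] <- NA_character_
  df
}

#' Composition-corrected cross-species comparison of one target gene
#'
#' Convenience driver: computes per-species marker ratios (honouring
#' neuronal-marker overrides), corrects the target gene's RPKM, and runs the
#' two-group test on corrected (and, for reference, uncorrected) values.
#'
#' @param tables List of [expression_table()] objects.
#' @param target Target gene symbol (e.g. `"S100B"`).
#' @param groups data.frame as from [read_species_groups()]; must cover all
#'   species and contain exactly two distinct groups.
#' @param glia_marker,neuron_marker Default markers.
#' @param variant t-test variant, see [two_group_ttest()].
#' @param mode Correction mode, see [composition_correct()].
#' @return List with `per_species` (data.frame: species, group, target RPKM,
#'   marker RPKMs, ratio, corrected), `test_corrected`, `test_uncorrected`.
#' @export
compare_target_across_groups <- function(tables, target, groups,
                                         glia_marker = "GFAP",
                                         neuron_marker = "RBFOX3",
                                         variant = "student_pooled",
                                         mode = "divide") {
  species <- vapply(tables, function(t) t$species_id, character(1))
  gi <- match(species, groups$species_id)
  if (anyNA(gi)) {
    fail("species missing from group table: ",
         paste(species[is.na(gi)], collapse = ", "))
  }
  grp <- groups$group[gi]
  if (length(unique(grp)) != 2) fail("need exactly two groups")
  per <- do.call(rbind, lapply(seq_along(tables), function(i) {
    nm <- groups$neuron_marker_override[gi[i]]
    if (is.na(nm)) nm <- neuron_marker
    prof <- glia_neuron_ratio(tables[[i]], glia_marker, nm)
    rpkm <- gene_rpkm(tables[[i]], target)
    if (is.na(rpkm)) fail("target ", toupper(target), " absent from ", species[i])
    data.frame(species_id = species[i], group = grp[i],
               target_rpkm = rpkm, glia_rpkm = prof$glia_rpkm,
               neuron_marker = prof$neuron_marker,
               neuron_rpkm = prof$neuron_rpkm, ratio = prof$ratio,
               corrected = composition_correct(rpkm, prof, mode),
               stringsAsFactors = FALSE)
  }))
  lv <- sort(unique(grp), method = "radix")
  split_vals <- function(col) split(per[[col]], factor(per$group, levels = lv))
  vc <- split_vals("corrected"); vu <- split_vals("target_rpkm")
  list(per_species = per,
       test_corrected = two_group_ttest(vc[[1]], vc[[2]], variant),
       test_uncorrected = two_group_ttest(vu[[1]], vu[[2]], variant),
       groups = lv)
}
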
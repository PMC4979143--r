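#' Default six-species brain-sample tree
#'
#' A rooted six-taxon tree (Newick, branch lengths in units of 100 Myr,
#' approximating accepted mammalian divergence times) used as the default
#' generating phylogeny for simulations: two carnivores (hooded seal,
#' ferret; split ~45 Mya), two cetaceans (minke whale, bowhead whale;
#' ~28 Mya) grouped with the pig (~65 Mya), carnivore/cetartiodactyl split
#' ~78 Mya, and human as the most distant lineage (~95 Mya). The diving taxa
#' (seal and the two whales) do NOT form a clade, mirroring the
#' convergent-adaptation setting the simulator is meant to emulate.
#'
#' @return Newick string.
#' @export
default_species_tree <- function() {
  paste0("(((hooded_seal:0.45,ferret:0.45):0.33,",
         "((minke_whale:0.28,bowhead_whale:0.28):0.37,pig:0.65):0.13):0.17,",
         "human:0.95);")
}

#' Default diving / non-diving grouping for the default tree
#'
#' @return Named character vector mapping species to `"diving"` /
#'   `"non_diving"`.
#' @export
default_species_groups <- function() {
  c(hooded_seal = "diving", minke_whale = "diving", bowhead_whale = "diving",
    ferret = "non_diving", pig = "non_diving", human = "non_diving")
}

#' Configuration for the multi-species expression simulator
#'
#' Describes a synthetic dataset: per gene, a baseline log2 expression is
#' drawn at the root of `tree` and evolved along the branches by Brownian
#' motion with rate `bm_sigma` (log2 units per square-root branch-length
#' unit), so the between-species covariance of log2 expression equals
#' `bm_sigma^2` times the shared root-to-tip path length. Tip values are
#' exponentiated to true RPKM, then fold-change spikes, marker genes and
#' composition confounds are applied, and finally read counts are drawn
#' (Poisson by default) and converted back to RPKM.
#'
#' @param tree Newick string or `phylo`: the generating species tree.
#' @param n_genes Number of background genes (markers come on top).
#' @param bm_sigma Brownian-motion rate on log2 expression (default 0.5).
#' @param baseline_log2_mean,baseline_log2_sd Root log2-expression
#'   distribution (defaults 4 and 2: median ~16 RPKM with a realistic
#'   right-skewed spread on the linear scale).
#' @param spikes Optional data.frame with columns `gene`, `target`, `fold`:
#'   multiply `gene`'s true RPKM by `fold` in the species `target`, or in
#'   every species of group `target` (see `groups`). Duplicate spike genes
#'   are an error.
#' @param groups Named character vector, species -> group label.
#' @param glia_marker,neuron_marker Marker gene symbols.
#' @param glia_fraction Named vector of per-species glial cell fractions in
#'   (0, 1); the marker RPKM ratio is set to `f / (1 - f)`. Default 0.5
#'   everywhere (ratio 1).
#' @param confounded_genes Symbols whose RPKM scales with the glia/neuron
#'   ratio (composition-confounded genes).
#' @param marker_neuron_rpkm Neuronal-marker RPKM level (default 100).
#' @param gene_length_range Integer range gene lengths are drawn from.
#' @param library_size Total mapped reads per species (default 2e7).
#' @param count_noise `"poisson"` (default) or `"none"` (tables then carry
#'   exact RPKM and no counts).
#' @param nb_dispersion Optional negative-binomial size parameter; `NULL`
#'   (default) keeps pure Poisson noise.
#' @param seed Integer RNG seed; same seed + config reproduces the dataset
#'   exactly.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(tree = default_species_tree(),
                             n_genes = 5000,
                             bm_sigma = 0.5,
                             baseline_log2_mean = 4,
                             baseline_log2_sd = 2,
                             spikes = NULL,
                             groups = default_species_groups(),
                             glia_marker = "GFAP",
                             neuron_marker = "RBFOX3",
                             glia_fraction = NULL,
                             confounded_genes = character(),
                             marker_neuron_rpkm = 100,
                             gene_length_range = c(500L, 5000L),
                             library_size = 2e7,
                             count_noise = c("poisson", "none"),
                             nb_dispersion = NULL,
                             seed = 1L) {
  count_noise <- match.arg(count_noise)
  if (inherits(tree, "phylo")) tree <- ape::write.tree(tree)
  phy <- tryCatch(ape::read.tree(text = tree),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy) || is.null(phy$edge.length)) {
    fail("tree must be valid Newick with branch lengths")
  }
  if (anyDuplicated(phy$tip.label)) fail("tree tip labels must be unique")
  if (bm_sigma < 0) fail("bm_sigma must be non-negative")
  if (n_genes < 1) fail("n_genes must be positive")
  if (library_size <= 0) fail("library_size must be positive")
  if (is.null(glia_fraction)) {
    glia_fraction <- stats::setNames(rep(0.5, length(phy$tip.label)),
                                     phy$tip.label)
  }
  if (any(glia_fraction <= 0 | glia_fraction >= 1)) {
    fail("glia_fraction values must lie strictly in (0, 1)")
  }
  missing_f <- setdiff(phy$tip.label, names(glia_fraction))
  if (length(missing_f) > 0) {
    fail("glia_fraction missing for: ", paste(missing_f, collapse = ", "))
  }
  if (!is.null(spikes)) {
    spikes <- as.data.frame(spikes, stringsAsFactors = FALSE)
    need <- c("gene", "target", "fold")
    if (!all(need %in% names(spikes))) {
      fail("spikes needs columns: ", paste(need, collapse = ", "))
    }
    spikes$gene <- toupper(spikes$gene)
    if (anyDuplicated(spikes$gene)) fail("duplicate spike genes")
    if (any(spikes$fold <= 0)) fail("spike folds must be positive")
    known <- c(phy$tip.label, unique(unname(groups)))
    bad <- setdiff(spikes$target, known)
    if (length(bad) > 0) {
      fail("unknown spike target(s): ", paste(bad, collapse = ", "))
    }
  }
  structure(
    list(tree = tree, phy = phy, n_genes = as.integer(n_genes),
         bm_sigma = bm_sigma, baseline_log2_mean = baseline_log2_mean,
         baseline_log2_sd = baseline_log2_sd, spikes = spikes,
         groups = groups, glia_marker = toupper(glia_marker),
         neuron_marker = toupper(neuron_marker),
         glia_fraction = glia_fraction[phy$tip.label],
         confounded_genes = toupper(confounded_genes),
         marker_neuron_rpkm = marker_neuron_rpkm,
         gene_length_range = as.integer(gene_length_range),
         library_size = library_size, count_noise = count_noise,
         nb_dispersion = nb_dispersion, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# internal: Brownian motion of n_genes traits along a rooted phylo tree.
# Returns tips x genes matrix of trait values.
simulate_bm_tips <- function(phy, n_genes, sigma, root_mean, root_sd) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  vals <- matrix(NA_real_, nrow = nnode, ncol = n_genes)
  root <- ntip + 1L
  vals[root, ] <- stats::rnorm(n_genes, root_mean, root_sd)
  # preorder: parents before children
  edges <- ape::reorder.phylo(phy, "cladewise")$edge
  lens <- ape::reorder.phylo(phy, "cladewise")$edge.length
  for (e in seq_len(nrow(edges))) {
    parent <- edges[e, 1]; child <- edges[e, 2]
    step <- if (sigma > 0) stats::rnorm(n_genes, 0, sigma * sqrt(lens[e])) else 0
    vals[child, ] <- vals[parent, ] + step
  }
  v <- vals[seq_len(ntip), , drop = FALSE]
  rownames(v) <- phy$tip.label
  v
}

#' Simulate a multi-species expression dataset with known truth
#'
#' See [synthetic_config()] for the generative model. Marker genes are held
#' out of Brownian variation and spikes so the composition signal is clean.
#'
#' @param config A [synthetic_config()].
#' @return List with `tables` (list of [expression_table()], in tree tip
#'   order) and `truth` (list: `tree`, `true_rpkm` genes x species matrix
#'   before count noise, `spikes`, `glia_fraction`, `marker_ratio`,
#'   `gene_length`).
#' @export
simulate_expression_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  phy <- config$phy
  species <- phy$tip.label

  n_named <- unique(c(toupper(config$spikes$gene), config$confounded_genes))
  n_named <- setdiff(n_named, c(config$glia_marker, config$neuron_marker))
  n_anon <- max(0L, config$n_genes - length(n_named))
  genes <- c(n_named, sprintf("G%05d", seq_len(n_anon)))

  tips_log2 <- simulate_bm_tips(phy, length(genes), config$bm_sigma,
                                config$baseline_log2_mean,
                                config$baseline_log2_sd)
  true_rpkm <- t(2^tips_log2)            # genes x species
  dimnames(true_rpkm) <- list(genes, species)

  ratio <- config$glia_fraction / (1 - config$glia_fraction)

  if (length(config$confounded_genes) > 0) {
    true_rpkm[config$confounded_genes, ] <-
      sweep(true_rpkm[config$confounded_genes, , drop = FALSE], 2, ratio, `*`)
  }
  if (!is.null(config$spikes)) {
    for (i in seq_len(nrow(config$spikes))) {
      sp <- config$spikes[i, ]
      targets <- if (sp$target %in% species) sp$target
                 else names(config$groups)[config$groups == sp$target]
      targets <- intersect(targets, species)
      true_rpkm[sp$gene, targets] <- true_rpkm[sp$gene, targets] * sp$fold
    }
  }

  marker_rpkm <- rbind(config$marker_neuron_rpkm * ratio,
                       rep(config$marker_neuron_rpkm, length(species)))
  dimnames(marker_rpkm) <- list(c(config$glia_marker, config$neuron_marker),
                                species)
  true_rpkm <- rbind(true_rpkm, marker_rpkm)
  all_genes <- rownames(true_rpkm)

  lens <- sample(seq(config$gene_length_range[1], config$gene_length_range[2]),
                 length(all_genes), replace = TRUE)

  tables <- lapply(species, function(s) {
    if (config$count_noise == "none") {
      expression_table(s, all_genes, config$library_size,
                       rpkm = true_rpkm[, s])
    } else {
      mu <- true_rpkm[, s] * lens * config$library_size / 1e9
      counts <- if (is.null(config$nb_dispersion)) {
        stats::rpois(length(mu), mu)
      } else {
        stats::rnbinom(length(mu), size = config$nb_dispersion, mu = mu)
      }
      expression_table(s, all_genes, config$library_size,
                       count = counts, length_bp = lens)
    }
  })
  names(tables) <- species

  list(tables = tables,
       truth = list(tree = phy, true_rpkm = true_rpkm,
                    spikes = config$spikes,
                    glia_fraction = config$glia_fraction,
                    marker_ratio = ratio,
                    gene_length = stats::setNames(lens, all_genes)))
}

#' Simulate a gene-set annotation with one enriched term
#'
#' Builds a reference list of `reference_size` synthetic gene symbols and
#' `n_terms` terms whose members are drawn uniformly from the reference; one
#' designated term (the first) has `enriched_term_genes` members. The query
#' is sampled without replacement with weight `enrichment_odds` for genes of
#' the designated term and 1 otherwise, so `enrichment_odds = 1` is the
#' null.
#'
#' @param reference_size Reference list size (default 5000).
#' @param n_terms Number of terms (default 50).
#' @param enriched_term_genes Size of the designated term (default 100).
#' @param query_size Query list size (default 100).
#' @param enrichment_odds Sampling odds for designated-term genes
#'   (default 1).
#' @param term_size_range Size range for the other terms (default 10..100).
#' @param seed Integer RNG seed.
#' @return List with `annotation` ([gene_set_annotation()]), `query`
#'   (character vector) and `truth` (list: `enriched_term`, `odds`).
#' @export
simulate_annotation <- function(reference_size = 5000, n_terms = 50,
                                enriched_term_genes = 100, query_size = 100,
                                enrichment_odds = 1,
                                term_size_range = c(10, 100), seed = 1L) {
  if (enriched_term_genes > reference_size) {
    fail("enriched_term_genes cannot exceed reference_size")
  }
  if (query_size > reference_size) {
    fail("query_size cannot exceed reference_size")
  }
  if (enrichment_odds <= 0) fail("enrichment_odds must be positive")
  if (n_terms < 1) fail("n_terms must be positive")
  set.seed(as.integer(seed))
  reference <- sprintf("R%05d", seq_len(reference_size))
  enriched <- sample(reference, enriched_term_genes)
  sizes <- if (n_terms > 1) {
    sample(seq(term_size_range[1], min(term_size_range[2], reference_size)),
           n_terms - 1, replace = TRUE)
  } else integer(0)
  terms <- c(
    list(T0001 = list(name = "designated enriched term", genes = enriched)),
    stats::setNames(
      lapply(sizes, function(k) list(name = "background term",
                                     genes = sample(reference, k))),
      sprintf("T%04d", seq_len(n_terms)[-1]))
  )
  w <- ifelse(reference %in% enriched, enrichment_odds, 1)
  query <- sample(reference, query_size, prob = w)
  list(annotation = gene_set_annotation(terms, reference),
       query = query,
       truth = list(enriched_term = "T0001", odds = enrichment_odds))
}

#' Read a simulator configuration from a flat key-value file
#'
#' Lines of the form `key = value` (`#` comments allowed). Scalar keys match
#' the arguments of [synthetic_config()]. Compound values:
#' `spikes = GENE:target:fold, GENE2:target:fold`,
#' `glia_fraction = species:f, species:f, ...`,
#' `groups = species:group, ...`,
#' `gene_length_range = lo:hi`, `confounded_genes = A, B, C`.
#'
#' @param path Config file.
#' @return A [synthetic_config()].
#' @export
read_synthetic_config <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  kv <- stats::setNames(as.list(vals), keys)

  split_pairs <- function(x) {
    parts <- strsplit(trimws(strsplit(x, ",")[[1]]), ":")
    parts[lengths(parts) > 0]
  }
  args <- list()
  num_keys <- c("n_genes", "bm_sigma", "baseline_log2_mean", "baseline_log2_sd",
                "marker_neuron_rpkm", "library_size", "nb_dispersion", "seed")
  for (k in intersect(names(kv), num_keys)) args[[k]] <- as.numeric(kv[[k]])
  for (k in intersect(names(kv), c("tree", "glia_marker", "neuron_marker",
                                   "count_noise"))) {
    args[[k]] <- kv[[k]]
  }
  if (!is.null(kv$gene_length_range)) {
    args$gene_length_range <- as.integer(strsplit(kv$gene_length_range, ":")[[1]])
  }
  if (!is.null(kv$confounded_genes)) {
    args$confounded_genes <- trimws(strsplit(kv$confounded_genes, ",")[[1]])
  }
  if (!is.null(kv$spikes)) {
    p <- split_pairs(kv$spikes)
    args$spikes <- data.frame(
      gene = vapply(p, `[[`, character(1), 1),
      target = vapply(p, `[[`, character(1), 2),
      fold = as.numeric(vapply(p, `[[`, character(1), 3)),
      stringsAsFactors = FALSE)
  }
  if (!is.null(kv$glia_fraction)) {
    p <- split_pairs(kv$glia_fraction)
    args$glia_fraction <- stats::setNames(
      as.numeric(vapply(p, `[[`, character(1), 2)),
      vapply(p, `[[`, character(1), 1))
  }
  if (!is.null(kv$groups)) {
    p <- split_pairs(kv$groups)
    args$groups <- stats::setNames(vapply(p, `[[`, character(1), 2),
                                   vapply(p, `[[`, character(1), 1))
  }
  do.call(synthetic_config, args)
}
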
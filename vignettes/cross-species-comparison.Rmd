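---
title: "Methods: cross-species brain transcriptome comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species brain transcriptome comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corticompare)
```

## Scope

`corticompare` implements the computational stages of a cross-species
comparison of bulk brain transcriptomes, of the kind used to contrast the
visual cortex of a deep-diving pinniped (the hooded seal) with terrestrial
relatives and with cetaceans. Read mapping, assembly and annotation are out
of scope: the package starts from gene-level tables of counts or RPKM per
species and takes ortholog assignment as given by shared gene symbols.

## Quantification and comparison

Expression is measured in RPKM,

$$\mathrm{RPKM}_g = \frac{10^9 \, c_g}{N \, L_g},$$

with $c_g$ the reads mapped to gene $g$, $L_g$ its length in bp and $N$ the
library size. Species are joined on the intersection of uppercased gene
symbols; a gene missing from one annotation is dropped rather than imputed
as zero, because absence is more often an annotation failure than true
silence. The analysis set is then restricted to genes passing an expression
filter in **all** species. The default test is strict (`RPKM > 5`), with a
`greater_equal` mode, since both conventions occur in practice; the strict
variant defines the differential-expression analysis set here.

Differences are summarized as a *signed fold difference*: the ratio of the
larger to the smaller RPKM, negated when the reference species is higher.
Its magnitude is always at least 1, and equal values give +1. Display
rounding is half-up to two decimals, matching how such tables are usually
printed; all internal arithmetic is at full double precision. The "at least
twofold" selection boundary is inclusive ($|f| \ge 2$).

With one library per species there is no replication, so no
statistical test accompanies the two-species fold ranking; this is a
deliberate limitation, not an omission.

## Overrepresentation testing

Gene-set enrichment of a query list (e.g. all genes at least twofold higher
in one species) is evaluated against a user-supplied annotation (GMT) and
reference list. For a term with $K_t$ of the $N$ reference genes, query size
$n$ and $k$ query genes in the term, the binomial model uses
$p_0 = K_t/N$ and reports both exact tails
$P(X \ge k)$ and $P(X \le k)$ for $X \sim \mathrm{Binomial}(n, p_0)$ —
underrepresentation is biologically meaningful too. The binomial tail was
chosen as the default because it is the historical default of the popular
web-based overrepresentation services; a Fisher's exact
(hypergeometric) mode is provided for sensitivity analysis, and the two
agree closely whenever $n \ll N$. The Bonferroni family size $m$ is the
number of terms actually tested (non-empty after intersection with the
reference); $m$ is exposed because conventions differ. Term hierarchies and
ancestor propagation are not modeled: the ontology graph is the annotation
provider's data, not this package's method.

## Composition correction

Bulk brain samples differ in cell-type makeup, so a gene expressed mainly in
astrocytes can differ in RPKM between samples purely through glial content.
The package uses the two-marker proxy
$\rho = \mathrm{RPKM}_{\mathrm{GFAP}} / \mathrm{RPKM}_{\mathrm{RBFOX3}}$,
with a per-species neuronal-marker override (SNAP25 where RBFOX3 is not
annotated, as in the pig genome). The corrected value is

$$\tilde{x} = x / \rho,$$

i.e. expression per unit of glial signal. The direction of this
normalisation is a genuine modelling choice — published figure captions
describing it are ambiguous between dividing by the glia/neuron ratio and
multiplying by its inverse-sounding "neuron/glia ratio" — and division by
$\rho$ is adopted here because it is the choice that makes a purely
glial gene invariant to glial content; a `multiply` mode is provided.
Correction should only be applied to genes the analyst designates as
predominantly single-compartment (e.g. S100B); genes expressed in both
neurons and glia (e.g. clusterin) should be left uncorrected.

The diving vs non-diving group comparison uses a two-tailed two-sample
t-test on untransformed values, Student's pooled-variance variant by
default (the default of common GraphPad-style workflows), with Welch
available. Groups are always user-supplied, never inferred. If both groups
are numerically constant with equal means the test returns $t=0$, $p=1$;
constant groups with unequal means are an error rather than a spurious
infinity.

## Expression phylogeny

Pairwise Pearson correlations over the shared gene set are converted to
distances ($d = 1 - r$ by default; $d = \sqrt{2(1-r)}$, which is a metric,
behind a flag) and fed to an in-package neighbor-joining implementation
(Saitou–Nei with the Studier–Keppler $Q$ criterion). Determinism choices:
ties in $Q$ are broken by the lowest (row, column) index pair, and negative
branch lengths are clamped to zero with the deficit moved to the sibling
edge so the path length through the joined pair is preserved (a common
NEIGHBOR-compatible convention); a raw mode keeps negative lengths. On
additive matrices the reconstruction is exact: leaf-to-leaf path lengths
reproduce the input to $10^{-9}$ in the validation suite.

`pearson_matrix()` correlates **untransformed** values by default, matching
the spreadsheet-style analyses this pipeline descends from. For validating
topology recovery, however, the package uses its `log2_transform = TRUE`
mode: on the linear scale the gene-expression distribution is so
heavy-tailed (approximately lognormal with $\mathrm{sd} \approx 2$ on the
log2 scale) that a correlation over 5,000 genes is effectively determined
by a handful of extreme genes, and the resulting distance estimates are too
noisy to resolve short internal branches regardless of the Brownian rate.
Log-scale correlation restores the nominal effective sample size. Both
modes are exposed; the linear default is kept for fidelity, the log mode is
recommended for tree inference.

## The synthetic-data generator

The generator emulates the statistical structure the pipeline assumes in
real data:

* **Phylogenetic covariance.** Each gene's log2 baseline is drawn at the
  root ($\mathcal{N}(4, 2^2)$: median ~16 RPKM with a realistic
  right-skewed linear-scale spread) and evolved along the species tree by
  Brownian motion with rate `bm_sigma` (default 0.5 log2 units per square
  root of branch length), so the between-species covariance of log2
  expression is $\sigma^2 \times$ the shared root-to-tip path length — an
  invariant checked empirically at 20,000 genes in the test suite.
* **The default tree** has six taxa (hooded seal, ferret, minke whale,
  bowhead whale, pig, human) with branch lengths in units of 100 Myr
  approximating accepted mammalian divergence times (seal–ferret split
  ~45 Mya, the whales ~28 Mya, whale–pig ~65 Mya,
  carnivore–cetartiodactyl ~78 Mya, human ~95 Mya). The diving species do
  **not** form a clade, so a diving-group expression spike is convergent
  with respect to the tree, as in the motivating biology.
* **Spikes.** Chosen genes are multiplied by a fold (e.g. 38, the magnitude
  of the S100B enrichment that motivates the design) in one species or one
  group.
* **Composition.** Marker genes (GFAP-like and RBFOX3-like) are set so the
  marker ratio equals $f/(1-f)$ for the configured glial fraction $f$, and
  flagged "confounded" genes scale with that ratio. Marker genes are held
  out of Brownian variation and spikes so the composition signal is clean
  unless the user opts otherwise. Ratios spanning a 200-fold range emulate
  the extreme composition differences seen between real brain samples.
* **Count noise.** Expected counts are RPKM-inverted through the same
  formula as quantification and sampled as Poisson by default (single
  libraries carry no replicate-level overdispersion information; a
  negative-binomial dispersion knob exists but is off by default); library
  size defaults to $2 \times 10^7$ mapped reads, gene lengths are uniform
  on 500–5,000 bp and shared across species.

What the generator does **not** emulate: mapping bias between genomes of
unequal quality, annotation-driven ortholog loss, isoform-level length
differences, lane/batch effects, and brain-region heterogeneity beyond the
two-marker composition proxy. Passing the simulation-based checks therefore
validates the pipeline's statistical logic, not robustness to those
real-data artifacts.

## Validation problem sizes

The test-suite and acceptance checks run at sizes chosen to make the
relevant sampling error small while keeping the suite quick: topology
recovery uses 100 datasets of 5,000 genes on the 6-taxon default tree
(expecting $\ge 95\%$ exact recovery); NJ correctness uses 50 random
additive matrices from trees of up to 8 leaves; composition recovery uses
200 replicates of 500-gene datasets with the 200-fold marker-ratio span,
`bm_sigma = 0` (the confounded-recovery condition fixes the target's
per-glial-unit expression across species) and Poisson noise, expecting the
38-fold group spike back within 15% and at least a 5-fold CV reduction;
type-I control uses 200 null annotation simulations (reference 5,000,
50 terms, query 100), expecting Bonferroni-significant hits in at most 6%
of runs. The binomial implementation is compared with direct
log-space pmf summation to $10^{-12}$ over all $n \le 12$.

## Known limitations

* Gene identity is the uppercased symbol; paralog confusion and
  symbol drift between annotations are the user's responsibility.
* RPKM inherits its known length/depth biases; no TPM or
  between-sample normalisation is offered because the downstream methods
  (ratios, ranks, correlations) are scale-tolerant by construction.
* The composition proxy is two markers, not a deconvolution; it cannot
  separate more than one axis of cell-type variation.
* With $n = 1$ library per species, all cross-species contrasts are
  descriptive; only the multi-species group comparison carries a test.
* The expression tree is a similarity summary, not a phylogenetic estimate;
  no bootstrap or rooting is provided.
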
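---
title: "Methods: from a two-group count matrix to ranked biomarker candidates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from a two-group count matrix to ranked biomarker candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(superpath)
```

`superpath` implements a complete biomarker-prioritization chain for a
malignant versus nonmalignant bulk RNA-seq comparison, of the kind used to
profile canine prostate cancer: roughly ten tumor and fourteen control
specimens (tissue and fine-needle aspirates), a poorly annotated source
genome that is analyzed through its human orthologs, and a final short list
of genes supported simultaneously by statistics, pathway context and
external evidence. This vignette explains each model, the tunable
parameters, the numerical choices, and what the synthetic-data tests do and
do not demonstrate.

## Differential expression

Counts $K_{gs}$ are modelled as negative binomial with mean $f_s \mu_{gj}$
and dispersion $\alpha_g$, where $f_s$ is a per-sample size factor,
$\mu_{gj}$ the expression level of gene $g$ in group $j$, and the variance
is $\mu + \alpha\mu^2$ (we state the parameterization because "negative
binomial" is ambiguous across ecosystems).

**Size factors** are median-of-ratios: the per-gene reference is the
geometric mean across samples over genes with all-positive counts, and
$f_s$ is the median ratio to that reference. Genes containing any zero are
excluded from every sample's median; if no gene is all-positive the
function asks the caller to filter first rather than guessing.

**Dispersions** are method-of-moments on normalized counts with variance
pooled within the two groups: $\hat\alpha_g = \max(\epsilon_\alpha,
(s^2_g - \bar m_g)/\bar m_g^2)$ with a floor $\epsilon_\alpha = 10^{-8}$.
The floor engages whenever the sample variance does not exceed the mean
(including constant genes) and keeps every estimate finite and
non-negative. Method-of-moments is deliberately simple: it has no shrinkage
across genes, so the Wald test below is slightly anticonservative at small
sample sizes, which the null-calibration test quantifies rather than hides.

**The Wald test** compares group means of normalized counts:
$\widehat{\mathrm{lfc}} = \log_2\frac{\bar m_{\text{mal}} + \epsilon}
{\bar m_{\text{non}} + \epsilon}$ with $\epsilon = 0.5$ normalized counts,
so genes expressed in only one group stay finite. The standard error comes
from the observed Fisher information of the two-group NB log-mean model,
$I_j = \sum_{s \in j} f_s\mu/(1 + \alpha f_s \mu)$ evaluated at the
pseudo-counted group means, and the statistic
$\widehat{\mathrm{lfc}}/\mathrm{se}$ is referred to a standard normal,
two-sided. All-zero genes are reported with $\mathrm{lfc} = 0$, $p = 1$.
There is no fold-change shrinkage, no independent filtering and no outlier
replacement: the decision rule the package reproduces is a plain NB Wald
test with Benjamini–Hochberg adjustment and the inclusive cutoff
FDR $\le 10^{-5}$.

The fold-change direction convention is malignant over nonmalignant, fixed
by the package (upregulated means higher in tumors).

**Ordination.** The visual group-separation check runs principal components
on $\log_2(\text{normalized count} + 1)$ over DEG rows. A
regularized-log transform would equalize variance more carefully; since
only the separation property matters here (not a variance percentage), the
simple offset transform is used and only qualitative separation is
asserted.

## Ortholog mapping and enrichment

Gene identifiers pass through a `source_gene → target_gene` table;
one-to-many relations contribute every target, and unmapped genes are
dropped with a logged count. The enrichment background defaults to all
mapped targets of the count matrix's genes — the analysis-universe analogue
of a fixed ortholog background list — and is configurable.

Over-representation uses the hypergeometric upper tail
$P[X \ge k]$, BH-adjusted across the collection, enriched at
FDR $\le 0.05$ inclusive. Because the original analyses of this design were
run in DAVID, whose EASE score discounts one hit ($P[X \ge k-1]$), that
variant is available behind a flag; the plain tail is the default and the
two are never mixed. Whether a published 49-pathway list came from one
score or the other cannot be decided from text alone, which is exactly why
both are shipped and documented.

## Cross-talk and superpathways

Pathway cross-talk is the overlap coefficient
$\mathrm{OC}(A,B) = |A \cap B| / \min(|A|,|B|)$ computed on memberships
restricted to the enrichment background, so the clustered objects are the
same sets the enrichment stage tested. Pathways are clustered by
complete linkage on $d = 1 - \mathrm{OC}$ and the dendrogram is cut into a
fixed number of clusters, $k = 5$ by default. A fixed-$k$ cut is the only
cut parameterizable from a five-superpathway design; a height-threshold cut
is available as an alternative for exploratory use. Clustering delegates to
`stats::hclust`, whose deterministic merge order makes results reproducible
across platforms; tied merge distances are resolved by its internal rule
(the package's oracle tests use continuous random distances, where ties
have probability zero).

Per-superpathway summaries report the gene union, the number and fraction
of DEGs in it, and the "mean of median overlap": for each member pathway
take the median OC to the other members, then average. A singleton cluster
has no within-cluster overlap and reports `NA` rather than a fabricated
number.

## The three-tier screen

* **DEG^S** (strongly deregulated superpathway genes): DEG, with
  $|\mathrm{lfc}| \ge 2$, group-median normalized expression strictly above
  the 40th percentile in at least one group, and membership in a
  superpathway's gene union (translated back through the ortholog map).
* **DEG^D** (database-associated): DEG with at least one of six boolean
  evidence flags. Evidence provenance (database versions, query dates) is
  frozen into the catalog file; the package never queries the internet.
* **DEG^SD**: the intersection, the top tier.

Two boundary conventions deserve comment. The fold-change boundary is
*inclusive* by default ($\ge 2$ / $\le -2$), matching the phrasing used for
the published DEG counts, with a strict-mode switch since the methods
wording ("smaller than −2 or larger than 2") reads strict. The expression
percentile is the linear-interpolation empirical quantile (type 7) of
group-median normalized counts over *all* tested genes, zeros included, and
"above" is strict — with the side effect that a degenerate table where all
genes tie passes nothing, which the tests pin down. The percentile universe
is configurable because the original description does not fix it.

The UpSet accounting assigns every gene in DEG^S ∪ DEG^D to exactly one
combination of seven criteria (six channels + S-tier membership); cells are
disjoint by construction and sum to the union size. Headline percentages
are rounded to the nearest integer and reported as `NA` when a denominator
is zero.

## PPI network and hubs

The network is the subgraph induced on the screened genes (DEG^S ∪ DEG^D by
default, any universe by argument), keeping edges with confidence strictly
greater than 0.4. Isolated genes remain as degree-0 nodes so the mean
degree refers to the full analyzed gene set. A hub is a node whose degree
strictly exceeds the *unrounded* mean degree; a published "more than 17
interactions" rule is the rounded form of such a mean, and a fixed-integer
threshold mode exists for replication against printed hub lists.
Neighborhood queries return the union of the queried genes' partners
intersected with a universe; a queried gene re-enters the result only as a
partner of another queried gene.

## The synthetic-study generator

`simulate_study()` produces every pipeline input with known ground truth.
Its defaults are the emulated study conditions, chosen once:

| parameter | default | rationale |
|---|---|---|
| `group_sizes` | 10 / 14 | the emulated design (9 tissues + 1 FNA vs 9 + 5) |
| `n_genes` | 5000 | enough genes for stable FDR behavior at desk scale |
| `de_fraction` | 0.1 | ~500 planted DEGs, a realistic DE share |
| `effect_log2fc` | 3 | strong planted effects (8-fold), random sign |
| `baseline_mean_log_mu`, `_sigma` | 4, 1.5 | log-normal mean spectrum typical of bulk RNA-seq |
| `dispersion` | 0.1 | common NB dispersion for tissue cohorts |
| `libsize_log_sigma` | 0.3 | 1.3–2-fold depth differences, so normalization matters |
| blocks × pathways | 5 × 10 | five superpathways over ~50 pathways |
| `pathway_size` | 40 | mid-sized curated pathways |
| `within/between_block_overlap` | 0.8 / 0.05 | clearly recoverable cross-talk structure |
| `de_member_fraction` | 0.4 | ~34–43% DE members per pathway, as in the emulated study |
| channel probabilities | 0.008–0.08 | scaled to the per-channel evidence counts of such catalogs |
| `ppi_within/between_density` | 0.25 / 0.002 | dense co-pathway wiring over a sparse background |
| `n_hubs`, `hub_degree_factor` | 5, 3 | hubs wired to 3× the expected mean degree |

All randomness flows from one master seed: each generator seeds its own
stream at a fixed offset (0 counts, 101 pathways, 211 evidence, 307 PPI,
401 orthologs), so stages are individually reproducible and the whole
study is a pure function of its configuration.

Blocks are built constructively: each pathway is a block core
(`within` fraction) plus a global shared set (`between` fraction) plus
unique members, so within-block overlap coefficients are at least the
within level and cross-block coefficients equal the between level. DE
genes are placed into pathway pools at `de_member_fraction`, which is what
makes all planted blocks enriched and the end-to-end block recovery
meaningful. Evidence channels are independent Bernoulli by default; a
Gaussian-copula correlation knob concentrates flags on "well-studied"
genes, raising the multi-channel share among flagged genes while
preserving marginals — mirroring catalogs where only a minority of
database-supported genes appear in two or more sources.

**What the generator does not emulate:** specimen-type (tissue vs FNA)
batch effects, gene-length and GC biases, correlated gene-gene expression,
read-level artifacts, and ortholog maps with many-to-one collapses beyond
the planted one-to-many pairs. Passing recovery tests therefore show the
pipeline's logic is correct under its stated model, not that any
particular biological dataset would yield the same lists.

## Test problem sizes and numerical choices

The recovery suites run at the generator defaults (5000 genes, 10/14
samples) for DE recovery and null calibration, 50 seeded replicates of a
400-gene PPI universe for hub recovery, exhaustive enumeration up to
background size 12 for the hypergeometric oracle, and up to 7 pathways for
the agglomeration oracle — sizes chosen so each property is checked in
seconds while remaining faithful to the study conditions. Degenerate
inputs are specified, not accidental: empty DEG sets give unit p-values,
empty tiers flow through the pipeline as empty results, two empty sets
have no overlap coefficient (error), and zero-DEG summaries report `NA`
shares instead of dividing by zero.
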
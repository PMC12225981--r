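---
title: "Methods: TE expression across sex-chromosome karyotypes"
author: "tekaryo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TE expression across sex-chromosome karyotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tekaryo)
```

# Scope and data model

`tekaryo` analyses bulk RNA-seq count tables of genes and transposable
elements (TEs) in cohorts structured by sex-chromosome karyotype
(46,XX; 46,XY; 47,XXY; 47,XYY). It deliberately starts *after*
alignment: per-copy or per-subfamily TE counts and gene counts are
inputs, because TE quantification from reads (multi-mapping assignment,
pseudo-alignment) is a solved upstream problem with dedicated tools.
What the package owns is everything from counts to inference.

All genomic intervals are 0-based half-open (BED convention) everywhere
inside the package; the RepeatMasker `.out` and GTF readers convert at
the boundary. A single convention avoids off-by-one drift between the
overlap modules, and abutting intervals (`[100,200)` vs `[200,300)`) do
not overlap. Chromosome names are taken verbatim; two files that share
no chromosome name raise an error rather than silently producing empty
overlaps, because a `chr` prefix mismatch is the most common way to get
a plausible-looking zero.

# Subfamily quantification

Individual TE insertion copies are not reliably assignable in donors
whose genomes are not sequenced, so counting happens at the subfamily
level: a rosetta map sends every copy id to its subfamily, and
`aggregate_copy_counts()` sums member copies per sample. The operation
conserves per-sample totals exactly (a tested invariant) and commutes
with subfamily-level exclusion. The embedded exclusion list holds the
24 repeat subfamilies that are not TEs (7SLRNA, 7SK, ..., HY5, 5S:
snRNA, scRNA, satellite and rRNA repeats); applied to a 1,270-subfamily
repeat library it leaves the 1,246 TE subfamilies. The trailing "5S" is
treated as one name. Names are opaque byte strings — "ALR/Alpha"
contains a slash and is matched literally. Features with zero counts in
every sample are dropped before inference.

# Gene-anchored normalization

Size factors are median-of-ratios estimators computed **from gene rows
only**: genes with positive counts in all samples form the reference
(geometric mean per gene), and a sample's factor is the median of its
count-to-reference ratios (arithmetic midpoint for even counts).
TE subfamily counts are then divided by these gene-derived factors.

The anchoring is the scientific point, not a convenience: if factors
were estimated from the joint matrix, a genuine genome-wide increase in
TE expression — exactly the effect under study — would be partially
absorbed into the factors and normalized away. Factors are invariant to
TE rows by construction (tested), and scaling a sample's raw column by
*c* scales its factor ratio by *c*, leaving ratio-normalized values
unchanged. Factors are defined only up to a global constant; all
downstream statistics use ratios or within-sample proportions and are
unaffected.

Gene-length offsets (relevant when gene-level counts are derived from
transcript-level estimates) are out of scope; inputs are gene-level
counts.

For display-level statistics, `remove_batch_effect()` fits per feature
a least-squares model of `log2(count + 0.5)` on the biological group
plus batch and subtracts the batch offsets. The biological group
(karyotype by default) is retained as a covariate so that unbalanced
batches do not leak group signal into the offsets. This adjustment is
only for descriptive statistics and plots; inferential models include
batch as a covariate instead. Inputs with a single batch pass through
unchanged, and a batch that is confounded 1:1 with the group is an
error.

# The global TE proportion

The headline statistic is, per sample, the sum of normalized TE
subfamily counts divided by the total normalized counts over genes plus
all TE subfamilies. Subset versions (LTR, SINE, LINE, SVA, DNA classes;
HERVK/AluS/L1/AluY named groups resolved by editable name-prefix rules)
keep the *full* denominator so that subset proportions over a partition
sum to the overall proportion (tested invariant).

Group comparisons use two-sided Wilcoxon rank-sum tests for every
karyotype pair: exact when both groups have at most eight samples and
no ties (at the study's 6/6/8/4 cohort sizes the exact branch is the
default), otherwise the normal approximation with tie and continuity
correction. The exact branch is verified against complete labeling
enumeration for all group sizes with n+m ≤ 10. Pairwise p-values are
reported raw; multiplicity correction across the pairs is available but
off by default, and directional claims should be made from group
medians, not one-sided tests. Kruskal–Wallis (with tie correction)
serves as the omnibus test, and a linear model `value ~ sex + age_group`
with a two-sided *t*-test on the sex coefficient handles sex effects
adjusted on age. Age groups are the five decades [20–30], ]30–40], ...,
]60–70].

A curation helper flags males suspected of undiagnosed sex-chromosome
aneuploidy: a male whose X-inactivation marker (XIST) exceeds half the
female median while a Y marker (USP9Y) is also expressed. Both the
fraction and the Y floor are configurable; females are never flagged.

# Differential expression

Each feature is modelled as NB(μ, α) with log link:
`log μ = X β + log s`, where `s` is the gene-derived size factor. The
primary factor is karyotype (reference XX by convention) with batch as
covariate; any sample-sheet columns can serve as covariates, including
interaction terms. Wald tests on pairwise level contrasts give log2
fold-changes of predicted normalized means; a likelihood-ratio
chi-square test (full vs. design without the primary factor, df =
levels − 1) tests the factor as a whole. BH adjustment is applied per
test family. Features with total count below 10 are not tested, and a
feature whose fit fails is reported with `NA` rather than aborting.

**Dispersion.** Plain per-feature ML dispersion is biased low when the
sample size barely exceeds the number of coefficients, which makes
Wald tests anti-conservative: at n = 6 vs 6 with batch, true dispersion
0.1, the measured type-I error at α = 0.05 was ≈ 0.12. The package
therefore maximizes the Cox–Reid adjusted profile likelihood
(the NB log-likelihood at the fitted means minus
`0.5 log det(XᵀWX)`), the same adjustment the established NB-GLM
packages use, and refers the Wald statistic to a *t* distribution with
the residual degrees of freedom. Under the same null this combination
measures ≈ 0.04–0.05 (a tested acceptance bound of [0.03, 0.07] at
2,000 features). The dispersion is floored at 1e-8, so constant or
Poisson-like features degrade gracefully; a feature with identical
counts in all samples yields log2FC 0 and p ≈ 1. No information is
shared across features — no shrinkage, no outlier refitting, no
independent filtering — which is the main fidelity gap relative to
full-featured DE engines and is intentional: operating characteristics
are established by simulation (calibration and recovery), not by
numeric parity with any particular tool.

The median-log2FC test summarizes a contrast across all TE subfamilies:
a two-sided Wilcoxon signed-rank test of the log2FC vector against
zero (zeros dropped), requiring at least five finite values. It detects
a coherent genome-wide shift in TE expression even when few individual
subfamilies pass FDR at small n. Feature ranking (e.g., the top 15 by
the LR test) orders by adjusted p, then raw p, then feature id —
fully deterministic.

# Y-chromosome enrichment

For each subfamily with at least one annotated copy, the number of
copies on the Y is tested against Binomial(n, 1.85%), where 1.85% =
57,200 kb / 3,088,200 kb is the Y's share of total chromosome length
(the published kb-rounded lengths are used as printed; X = 156,040 kb
for the X-based variant). Two-sidedness uses the minimum-likelihood
rule — the sum of the probabilities of all outcomes no more likely than
the observed count — matching the default exact binomial test of the R
environment the original analysis ran in; the doubled-one-sided
alternative is available behind a flag. The implementation is verified
against full-outcome enumeration for every n ≤ 500.

BH correction runs across all tested subfamilies; `enriched` means
padj < 0.05 with observed > expected, `depleted` the mirror image, and
the three predicate groups (no Y copies, no X copies, neither) are
membership facts independent of the test. A one-sided binomial test
(`enriched_share_test()`) asks whether a selected set — e.g., the most
karyotype-dependent subfamilies — contains more Y-enriched members than
the genome-wide share.

Chromosome-length calibration was chosen over copy-weighted genome
share deliberately: the null is "copies land proportionally to
sequence length", which is the published definition.

# Region enrichment

Upstream regions span 3 kb from the TSS (interval start for + genes,
end for − genes), clipped at zero and optionally at chromosome ends;
regions of adjacent genes are not merged, each gene contributes one
region. The overlap statistic is count-once: a region counts at most
once however many TE copies it intersects, with strand ignored (the
intragenic test, mirroring an intersection run with strand matching, is
strand-aware; both behaviours are flags).

The permutation null resamples, 5,000 times by default, `|selected|`
regions from the universe of all upstream regions without replacement
and recomputes the statistic. The side is chosen automatically (greater
when the observed count is at least the null mean) and the empirical p
is `(1 + #extreme) / (n_perm + 1)`, never below `1/(n_perm+1)`.
Auto-sidedness biases p slightly downward under the null; the
calibration bound is widened accordingly ([0.02, 0.09] at α = 0.05
over 400 replicate tests). Because the count-once statistic of a subset
is a sum of per-region indicators, the region/copy overlap is computed
once and each permutation reduces to an indicator sum, making 5,000
permutations cheap. The universe includes the selected regions during
resampling (standard resampling semantics). Identical inputs and seed
give bit-identical results.

The intragenic test compares the share of DE genes containing at least
one copy (≥1 bp, strands matching) from the DE subfamilies with the
same share over all genes, by a two-sided exact binomial test; when no
gene at all contains a copy the test is skipped with a status flag.

# The synthetic cohort generator

The generator emulates the study conditions end to end: cohort sizes
default to 6 XX / 6 XY / 8 XXY / 4 XYY, matching the gonosome
aneuploidy cohort scale so that statistical behaviour at that n is
visible. A toy genome (two autosomes, chrX, chrY; the Y ≈ 2% of the
sequence, mirroring the human length share) receives TE copies: a
configurable fraction of subfamilies (default 10%) places each copy on
the Y with probability 0.5 — far above the length share — while all
other placement is length-proportional. Expression follows
`baseline × dosage × library factor × batch factor` with NB noise
(shared dispersion 0.05 by default): Y-located features are silent
without a Y and double per extra Y (`y_dosage_effect = 2`, a fully
active extra Y), X-located features scale by 1.1 per extra X
(`x_dosage_effect = 1.1`, an extra X that is largely inactivated).
These two knobs encode the interpretive model of sex-chromosome dosage
as tunable parameters, not claims. Library factors are log-normal
(sd 0.3); half the samples get per-feature log-normal batch multipliers
(sd 0.1). Marker genes `XIST_sim` / `USP9Y_sim` express only with ≥2 X
or ≥1 Y, exercising the aneuploidy flag. The whole bundle is a pure
function of the design (seed mandatory), and ground truth ships with
it: enrichment status per subfamily, exact expected log2FC per
karyotype contrast from the noise-free means, and the true library
factors.

What the generator does **not** emulate: mappability and GC artifacts,
multi-mapping ambiguity, per-copy expression heterogeneity within a
sample beyond the fixed baseline, gene-length bias, single-cell
structure, or age effects. Passing recovery tests therefore shows the
*inference machinery* is correct under the stated generative model, not
that real RNA-seq satisfies that model.

# Problem sizes and numerical choices

The validation suite runs at sizes chosen to make Monte-Carlo bounds
meaningful while staying desk-scale: NB null calibration at 2,000
features (n = 12, unbalanced batches), permutation calibration over 400
replicate tests at 500 permutations, binomial-oracle equivalence for
every n ≤ 500, recovery designs with 40–60 subfamilies × 60 copies, and
the karyotype-ordering check over 100 replicate cohorts at 6/6/8/4
(measured: ordering XYY > XY > XX holds in 98–99% of replicates; Wald
null size 0.046–0.055; permutation null 0.03–0.08; Y-enrichment and
FC-2 DE recovery 100%).

Other numerical conventions: even-length medians are arithmetic
midpoints; the BH family for Y enrichment is all subfamilies with ≥1
copy; Wald contrasts are antisymmetric by construction
(`log2FC(A vs B) = −log2FC(B vs A)`); ties in feature ranking break by
raw p then lexicographic id; the binomial minlike rule guards
floating-point ties with a 1e-7 relative tolerance; permutation and
simulation code save and restore the global RNG state.

# Known limitations

* Subfamily-level counts cannot separate autonomous TE transcription
  from co-transcription with genes; the intragenic overlap test bounds,
  but does not resolve, that ambiguity.
* No dispersion shrinkage means reduced DE power at very small n
  compared with empirical-Bayes engines, traded for a self-contained,
  simulation-calibrated estimator.
* The display-level batch adjustment assumes an additive log-scale
  batch effect shared across features' scale; inferential conclusions
  never rely on it.
* Chromosome-length enrichment calibration ignores assembly gaps and
  mappability; a subfamily whose copies are systematically unmappable
  on the Y will appear depleted.
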
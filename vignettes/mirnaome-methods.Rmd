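---
title: "Models and methods behind mirnaome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mirnaome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirnaome)
```

This vignette documents the statistical models, algorithms and design
choices in `mirnaome`, in the spirit of the methods sections of the
established expression-analysis packages: what is computed, under which
assumptions, which knobs matter, and what the synthetic validation does
and does not demonstrate.

## The reference model

A miRBase-style reference consists of hairpin precursors (~70 nt), mature
miRNAs embedded in them, and a GFF3 carrying genomic coordinates
(`miRNA_primary_transcript` and `miRNA` records linked by
`Derives_from`). `load_reference()` joins the three sources and verifies
that every mature occurs verbatim inside its hairpin; for minus-strand
hairpins whose FASTA carries the genomic-plus sequence, the reverse
complement is tried before declaring failure. All coordinates are held
1-based inclusive, the R/Bioconductor convention, so GFF3 I/O is
conversion-free.

Two derived groupings drive the downstream analyses:

* **Seed families.** The seed is the 7-mer at mature positions 2–8 — the
  canonical seed definition — and a family is the set of matures with an
  identical seed. Curated family labels (which occasionally merge
  different seeds) can be supplied through `annotated` mode; matures
  missing from the annotation fall back to seed grouping and are flagged.
* **Genomic clusters.** Following the miRBase convention, matures within
  10,000 bases on a chromosome form a cluster. The gap is the number of
  intervening bases (`next start − previous end − 1`, overlap counting as
  zero), and membership is the single-linkage closure of the pairwise
  relation: coordinate-sorted matures are chained with a running maximum
  end, which equals the transitive closure for interval data. Clusters
  are strand-agnostic, because the convention is purely coordinate-based.
  Singletons are not clusters; they are reported in a side attribute.
  Names are `Chr{chrom}.{k}` with `k` the start-order ordinal of the
  cluster on its chromosome.

## IsomiR classification

Reads arrive collapsed (unique sequences with per-sample multiplicities).
For a read of length `n` and a mature of length `L` at offset `o` in its
hairpin, every end-shift pair `(s5, s3)` with `|s5|, |s3| ≤ 3` and
`L + s5 + s3 = n` defines a candidate alignment; negative shifts trim
bases relative to the canonical end, positive shifts add bases, matching
the sign convention in which "position −3" at the 5′ end means a 3-base
deletion. The default ±3/±3 window with at most one internal mismatch is
the tolerance of the miraligner family of tools; both bounds are exposed
as parameters (`max_shift`, `max_sub`), so the asymmetric windows used by
other aligners can be emulated.

Within a candidate:

* mismatches in the canonical body are **substitutions**, reported in
  1-based canonical-mature coordinates regardless of the shift;
* added 5′/3′ bases are compared against the flanking hairpin sequence:
  a perfect match is a **templated** addition (imprecise processing),
  any mismatch or extension beyond the hairpin marks the addition
  **non-templated** (enzymatic tailing). Tail mismatches do not consume
  the substitution budget, because non-templated tailing is a distinct
  biological process from internal editing.

A candidate is valid when its substitution count is within budget; the
call is the valid candidate minimizing
`|s5| + |s3| + substitutions`, with ties broken by fewer substitutions,
then smaller `|s5|` (5′ variation is biologically rarer, as it changes
the seed), then mature name in C-locale order, then the signed
`(s5, s3)` pair. The last two steps are arbitrary but deterministic: a
read compatible with several members of a seed family is always assigned
to the same one. Each read goes to exactly one mature — no fractional
multi-mapping — so per-sample counts are conserved exactly between input,
calls and the unassigned list. Unassigned reads carry a reason; a read
that becomes assignable when the window is doubled failed on the shift
tolerance, the rest on the mismatch budget.

The end-class labels follow the shifts alone: `exact` (both zero),
`iso5`, `iso3`, `iso5_iso3`. A read with exact ends and one substitution
is therefore an `exact`-class call carrying a substitution record —
end variation and internal variation are orthogonal axes.

### ADAR candidate sites

A-to-I editing is sequenced as A→G on the sense read. A call whose single
substitution is A→G at an *internal* mature position (2 to L−1; the
extremes are excluded because end positions are dominated by
trimming/tailing artifacts and editing is known to be depleted there)
contributes to the site's edited counts. The per-site edited fraction is
edited counts over the mature's total assigned counts in that sample. The
per-sample editing burden — the number of distinct matures with at least
one edited read — is compared between populations with an unpaired
two-sided Welch t-test on the replicate values; with zero variance and
equal means the statistic is defined as 0 (p = 1). Whether such a burden
should count matures or distinct sequences is not settled usage; counting
matures was chosen because sequence counts scale with isomiR diversity
rather than editing.

## Filtering, normalization, differential expression

The expression filter keeps a feature when some population supports it,
in one of two readings: every replicate at least `min_reads` (strict,
default), or the population mean at least `min_reads` (`mean_only`).
Both are provided because the two clauses answer different questions
(robust presence vs average abundance); the strict rule implies the mean
rule, so strict feature sets are always nested inside mean-only sets.

CPM normalization scales each sample to one million; it is used for
reporting, ranking and profile building. Inference uses raw counts with
**median-of-ratios size factors**: factor_j is the median over
all-nonzero features of `count_ij / geomean_i`, rescaled to geometric
mean 1.

Differential expression is a deliberately transparent negative-binomial
Wald pipeline, not a re-implementation of a full shrinkage estimator:

1. normalize by size factors computed on the two compared groups;
2. per feature, estimate the dispersion by method of moments on the
   normalized counts pooled within the groups:
   `α = max((s² − μ)/μ², 1e-8)` with `s²` the df-weighted pooled
   within-group variance and `μ` the overall mean; the floor keeps the
   model at least Poisson;
3. `log2FC = log2((μ_B + 0.5)/(μ_A + 0.5))`; the 0.5 pseudocount keeps
   fold changes finite for group-absent features without materially
   biasing expressed ones;
4. the Wald statistic divides the fold change by its delta-method
   standard error under the NB variance `μ + αμ²`;
5. two-sided p-values use a **t reference with `nA + nB − 2` degrees of
   freedom**, then BH adjustment.

The t reference is the one place where transparency required a
calibration choice. With three replicates per group the pooled variance
has ~4 degrees of freedom, and referring the statistic to a normal
distribution is several-fold anticonservative at p = 0.01 (a nominal 1%
test rejects ~6% of null features in simulation). The t reference
restores calibration: in the package's null simulations (NB counts,
shared per-feature mean and dispersion, 3 vs 3, 2,000 features) the
fraction of p ≤ 0.01 lands near 0.01 (the validation band is
0.005–0.02), while planted log2FC = 6 features are still recovered with
essentially full sensitivity at the volcano thresholds. `df = Inf`
restores the normal reference if desired. No dispersion shrinkage toward
a mean trend is performed — a documented simplification relative to the
heavyweight DE engines; the cost is power on borderline features, not
calibration.

Volcano labels are `up`/`down` when `|log2FC| ≥ 3` and the raw p ≤ 0.01
by default, the customary cutoffs for staged small-RNA designs of this
size; adjusted-p labelling is a flag. Sample distances are Euclidean on
`log2(CPM + 1)`, and PCA is performed on centered (optionally scaled)
features with samples as observations; the log transform is the
package's choice, made once, as variance stabilization for heavily
right-skewed CPM values.

## Fuzzy trajectory clustering

Clustering operates on per-population replicate means of
`log2(CPM + 1)` — three-point profiles for a three-stage design —
standardized row-wise to mean 0, sd 1 (sample sd; constant rows cannot
be standardized and are dropped with a record). Standardization makes
the clustering about *shape*, not expression level.

`fuzzy_cmeans()` is the standard algorithm: memberships
`u_ik = 1/Σ_j (d_ik/d_ij)^(2/(m−1))` with Euclidean distances,
centroids the `u^m`-weighted means, iterated until the largest
membership change drops below `tol = 1e-6` or 500 iterations. A point
coinciding with a centroid receives membership 1 there. The fuzzifier
defaults to m = 2, the conventional choice; data-driven estimation of m
is out of scope. Initial centroids are `c` distinct rows drawn by a
seeded sample over the *canonical* (value-sorted) row order, so the fit
is invariant to the order in which features arrive; 10 restarts are run
and the lowest-objective fit kept. The objective trace is returned and
is non-increasing — a property the tests assert on every fit.

The number of clusters is chosen by a separation criterion:
for each candidate `c`, the best-of-restarts model's minimum pairwise
centroid distance is computed, and the chosen `c` is the largest whose
separation exceeds 0.5 standardized units. The rationale: when `c`
exceeds the number of real patterns, some pattern is split and two
centroids nearly coincide, collapsing the diagnostic. On the package's
planted three-pattern data this selects 3; the default `c = 5` mirrors
the five dynamic patterns characteristic of staged cardiac
differentiation (monotone up, late up, late down, early down, transient
up). Hard assignments take the maximum membership when it reaches
`min_membership` (default 0.5, ties to the lowest cluster index),
otherwise the feature stays unassigned.

## Group-level analyses and the cell-type miRNAome

Family and cluster expression are member-wise sums of CPM per sample;
matures outside every group are carried separately so the aggregation
conserves column totals exactly. Cluster–family links classify each
cluster by the number of distinct families among its members
(`single_family` vs `multi_family`). Word-cloud rankings weight groups
by population-mean CPM normalized to the maximum, with alphabetical
tie-breaks.

The three-tier cell-type report for a target population:

* **top expressed** — the `top_n` features by target-mean CPM among
  features passing the expression filter;
* **up vs all** — features labelled `up` against *each* other population
  separately (an intersection of pairwise volcano calls, not a pooled
  one-vs-rest test, which would let one very different population mask
  another);
* **unique** — features with *strictly zero* raw counts in every sample
  of every other population, floored at 5 CPM target mean so that
  single-read artifacts are not called "unique".

The report's `mean` columns are CPM means and are labelled as such.

## Target-set statistics

Externally produced target-prediction tables (gene, predictor, score in
[0, 1]) are consumed as-is; the prediction algorithms are out of scope.
Filtering keeps scores strictly above 0.8 by default ("above" read
strictly; a flag switches to ≥ for boundary sensitivity). Venn overlaps
for two or three sets report all disjoint regions. Score correlations
between predictors are computed over genes scored by *both* (Pearson by
default, Spearman by flag); zero-filling absent predictions would
fabricate agreement, so pairs with fewer than three common genes are
flagged undefined rather than guessed. Over-representation of gene sets
uses the upper-tail hypergeometric probability `P(X ≥ k)` with BH
adjustment across sets; the machinery is annotation-agnostic and works
with any user-supplied gene sets.

## The synthetic-data generators

`simulation_config()` fixes the planted study conditions; the defaults
emulate the structure of a three-stage differentiation experiment with
three replicates per stage:

* **Reference**: ~30 hairpins over 7 chromosomes; planned clusters with
  sub-10-kb gaps, including two single-mature-per-hairpin clusters whose
  members share one seed (the family-equals-cluster situation typified
  by the mir-302 cluster); singletons spaced 20,001 bases apart; two
  minus-strand hairpins to exercise orientation handling.
* **Reads**: per mature, distinct sequences drawn with end-class
  probabilities (exact 0.35, iso5 0.10, iso3 0.35, both 0.20 — exact
  sequences a minority, 3′ variation dominant, 5′ variation rarest),
  5′-shift distribution with mode −3 and 3′ mode −1, a 10% substitution
  rate with spectrum weights favouring C>G, G>A and T>C, and five
  planted A→G editing sites (internal reference-A positions, per-read
  editing probability 0.2, binomially split between the edited and
  unedited sequence so the planted rate is exact in expectation).
  Counts are NB per sample; truth records the generating call and an
  ambiguity flag (whether any other candidate ties or beats the
  generating one under enumeration).
* **Counts**: NB with log-uniform means (20–2,000) and uniform
  dispersions (0.01–0.2). Planted DE features shift one population's
  mean by `2^log2FC` and are drawn from the well-expressed,
  low-dispersion range (means 200–2,000, dispersion ≤ 0.1), and planted
  trajectory features likewise (means ≥ 500, dispersion ≤ 0.05) — both
  mirror the fact that the corresponding real analyses run after
  expression filtering, on well-measured miRNAs. Trajectory features
  follow the five standardized shapes with amplitude 2 log2 units and
  Gaussian stage noise of sd 0.2; `simulate_trajectory_profiles()`
  generates the same shapes directly in standardized space for
  clustering validation isolated from count noise.
* **Score tables**: per-predictor target sets of configured sizes and
  pairwise overlaps, targets scored Uniform(0.8, 1) and non-targets
  Uniform(0, 0.8).

All generators are deterministic given the seed, to the byte for file
outputs.

What the generators do **not** emulate — and hence what passing
validation does not demonstrate about real libraries: sequencing error
and base qualities (collapsed input has none), adapter contamination,
multi-mapping against near-identical paralogs beyond what random
sequences produce, mean-dispersion trends, library-composition biases,
and correlated replicates. Results on real data depend on upstream
trimming and on the completeness of the reference in ways the synthetic
route cannot probe.

## Validation problem sizes and numerical choices

The shipped validation (test suite and `scripts/acceptance.R`) uses:
a 4-mature hand fixture with full candidate enumeration (~700 reads)
for exact agreement with a brute-force oracle; ~11,000 distinct
simulated sequences against a 392-mature reference for recovery and
count conservation; 2,000-feature null and spike-in matrices (3 vs 3)
for calibration and power; 150 planted profiles for shape recovery;
100 random coordinate sets against a transitive-closure oracle; and
universes of at most 12 genes for exact hypergeometric enumeration.
These sizes were chosen so each property is measured with low Monte
Carlo error while the whole suite stays interactive.

Numerical details worth knowing: the membership update treats a
squared distance below 1e-300 as coincidence (membership 1); the
objective is reported including the initial configuration; BH
adjustment is `stats::p.adjust`; sample sd (ddof 1) is used both in
standardization and in `(1,2,3) → (−1,0,1)`-style expectations;
fold-change pseudocount and dispersion floor are as above; all
random draws go through a single seeded stream per generator call, so
adding features to a config changes downstream draws (configs are
compared by identity, not by patch distance).

## Known limitations

* The DE engine is per-feature; very low counts (means below ~10) give
  the t reference limited power, and no independent filtering is
  applied.
* Reads are assigned to exactly one mature; abundance of identical-seed
  paralogs sharing a sequence is attributed deterministically, not
  split.
* The cluster-number criterion is a heuristic; for strongly overlapping
  patterns the separation threshold of 0.5 may select fewer clusters
  than a likelihood-based criterion would.
* `annotated` family mode trusts the supplied table; no reconciliation
  with seed identity is attempted beyond the fallback for missing
  entries.
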
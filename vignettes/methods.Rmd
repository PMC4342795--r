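---
title: "Tag-based DGE profiling of a senescence time course: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tag-based DGE profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cottonDGE)
```

## The problem

NlaIII digital gene expression (DGE) represents each transcript by a
21-nt tag — the CATG restriction site nearest the poly(A) tail plus the
17 nucleotides downstream — and measures expression by counting tag
copies in a sequencing library. For an allotetraploid (AD genome)
species profiled against its two diploid progenitor genomes, the
reference must merge the A and D gene sets while removing cross-genome
tag redundancy, or homeologous genes poison each other's counts.
`cottonDGE` implements this pipeline end to end for a six-time-point
leaf senescence design: virtual tag-library construction, one-mismatch
tag mapping with ambiguity filtering, tags-per-million (TPM)
normalization, pairwise exact-count differential expression, time-course
clustering, annotation-set over-representation, and qPCR
cross-validation — plus a ground-truthed synthetic-data generator so
that every stage is testable at desk scale.

## Reference tag library

Every CATG occurrence with at least 17 nt downstream in a coding
sequence yields a reference tag; `site_rank` 1 marks the 3'-most site,
the one the protocol actually captures. Only the sense strand is
scanned, because NlaIII tags derive from the mRNA.

Merging is asymmetric by design: canonical (rank-1) tags of the two
genomes are compared, and a D-genome gene whose canonical tag lies
within Hamming distance 1 of any A-genome canonical tag is removed
entirely (all of its sites), the A copy being kept with priority.
Hamming distance is computed over all 21 positions; since the CATG
anchor is constant in valid tags this equals suffix-only distance, and a
test asserts the equivalence. Within-genome duplicate tags are *not*
removed at build time — they surface as ambiguity at mapping, which
matches the filtering rule that tags hitting multiple genes are
discarded from counting.

The source protocol is ambiguous about whether mapping used all CATG
sites or only 3'-most sites; the default here indexes all sites while
redundancy removal always uses canonical tags, and a `canonical_only`
switch restricts the mapping database for users who prefer the stricter
reading.

The Hamming-1 index stores, for each reference tag, its exact key and
its 21 single-position wildcard keys. Two equal-length strings are
within distance 1 iff they share a masked key, so the index is exact by
construction, not a heuristic; an `O(n^2)` Hamming-scan oracle confirms
this on randomized libraries.

## Tag assignment and TPM

Assignment is exact-first: an exact hit resolving to one gene is
unambiguous even when 1-mismatch neighbours exist in other genes (the
protocol literature is silent; exact-first is standard practice and is
flagged in the run report). Failing an exact hit, all Hamming-1
neighbours are pooled; one gene is unambiguous, two or more are
ambiguous, none is unmapped. Ambiguity is evaluated at the gene level,
so multiple tag sites within one gene never cause a discard. Malformed
tags (wrong length, non-ACGT, broken CATG anchor — e.g. a sequencing
error in the anchor) are counted in a `rejected` bin rather than
silently dropped, and copy-number conservation
(unambiguous + ambiguous + unmapped + rejected = clean total) is
asserted by tests.

TPM here is the tag-count sense: `raw x 1e6 / clean_total`, not the
length-normalized RNA-seq quantity. Raw counts are always carried
alongside.

## Differential expression

With one pooled library per time point there are no replicates, so
counts are compared with the Audic–Claverie exact statistic. Given `x`
tags in a library of `N1` clean tags, the probability of `y` tags in a
library of `N2` is

$$p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{\!y}
\frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}},$$

equivalently `y | x ~ NegBinom(x + 1, N1/(N1+N2))` — the package
computes the log-gamma form and the test suite uses the negative
binomial identity and a term recurrence as independent oracles. The
two-sided p-value is `min(1, 2*min(lower, upper))` with the lower tail
summing `y' <= y` and the upper tail computed as one minus the strict
lower tail, clamped at zero.

One subtlety is worth recording: with these discrete tails the two-sided
p is *not* exactly symmetric under swapping `(x, y)` — conditioning on
`x = 5, y = 0` gives 1/32 while `x = 0, y = 5` gives 1/16, the
difference being the boundary point mass. The worked tail examples pin
the definition; tests assert near-symmetry (within a factor of two)
rather than an identity the definition cannot deliver.

A gene is differentially expressed in a pairwise comparison when all
three filters pass: Benjamini–Hochberg FDR ≤ 0.001 (step-up, applied
per comparison across the tested genes; a Benjamini–Yekutieli switch is
provided), |log2 TPM ratio| ≥ 2 (four-fold), and raw count ≥ 10 in at
least one library. Genes at 0/0 are untestable and excluded from the
multiple-testing family so they do not inflate the FDR denominator.
When one TPM is zero the TPM equivalent of a single raw tag is
substituted to keep the ratio finite; the raw ≥ 10 filter makes this
floor rarely decisive. All 15 unordered pairs of the six libraries are
tested by default (a baseline design is available), and the union DEG
set records which comparisons fired and a per-gene direction summary.

## Clustering and trajectory types

DEG profiles are `log2(TPM + 1)`, z-scored per gene by default. K-means
is authored in-package rather than delegated to `stats::kmeans` because
the contract demands behaviours the stock implementation does not
promise: deterministic k-means++ initialization under a seed,
re-seeding of emptied clusters from the farthest point, and relabelling
of final clusters by descending early-time-point mean so downregulated
clusters lead the presentation. The within-cluster sum of squares is
recorded per iteration and is non-increasing. K defaults to 42 to
mirror the source study's choice, but that number is not derivable from
anything in the data and is a plain parameter. Hierarchical clustering
(average linkage, Euclidean) is delegated to `stats::hclust`, with a
naive agglomeration oracle checking cophenetic distances on small
inputs.

A cluster is `type_I` (down) when its mean log2 profile falls from the
early phase (first two time points) to the late phase (last two) by at
least one fold-threshold unit (default two-fold) *and* trends
monotonically (Spearman correlation with time ≤ −0.5); `type_II` is
symmetric upward; everything else — notably peak-shaped trajectories —
is `complex`. The Spearman cutoff of 0.5 was chosen because the
generator's peak shape has rank correlation ≈ −0.44 with time: a
stricter cutoff would misfile peaks as monotone, a looser one would
never label anything.

## Over-representation analysis

Any term→gene table (KEGG pathway, GO, TF family, hormone category) is
consumed as a GMT-style file; no live database access is performed, and
GO DAG propagation is deliberately not implemented — tables must be
pre-propagated if true-path semantics are wanted. The statistic is the
one-sided hypergeometric upper tail (`stats::phyper`, verified against
exhaustive enumeration with binomial coefficients for all backgrounds up
to 30 genes), corrected by BH within each namespace, significant at
corrected p < 0.05. The background defaults to the detected-gene
universe of the expression matrix, not the annotation file, because
enrichment claims are about what was measurable.

## qPCR validation

Relative expression follows the comparative 2^−ΔΔCt method: technical
replicate Cts are averaged arithmetically (the standard practice;
geometric aggregation of expression would differ only by replicate
ordering), ΔCt is taken against the reference gene per sample, ΔΔCt
against the calibrator sample (default the first time point), so the
calibrator's relative expression is exactly 1 by construction. Platform
agreement is the per-gene Pearson correlation between the 2^−ΔΔCt
profile and the TPM profile, on the untransformed scale by default (a
log-scale flag exists; the choice is not determinable from the source
methods). Genes with fewer than three shared points or zero variance on
either platform are reported as undefined and excluded from the mean
with a warning. A per-gene exclusion list supports dropping failed
amplifications rather than hard-coding any particular gene set.

## The synthetic world

The generator states one fixed world and the tests live in it:

* **Genomes.** Each gene is an i.i.d.-uniform random CDS (default
  500 nt) with a guaranteed CATG placed so its suffix is flush with the
  3' end; any chance CATG inside the suffix has fewer than 17 nt
  downstream, so the injected site is always the canonical one. This
  guarantees taggability without a biological sequence model.
* **Homeologs.** 30% of A genes have a D partner; divergence is applied
  only inside the 17-nt tag suffix, with substitution counts 0/1/2 at
  probabilities 0.25/0.50/0.25. The A/D progenitor genomes diverged a
  few million years ago (a few percent nucleotide divergence), which for
  a 21-nt window means mostly 0–2 substitutions; putting mass on 0 and 1
  exercises both redundancy removal and the 1-mismatch mapping radius.
* **Trajectories.** Patterns flat/down/up/peak at 0.70/0.15/0.12/0.03.
  This is deliberately DE-enriched relative to the real study (~15% of
  detected genes were DEGs) so that desk-scale runs retain enough signal
  for clustering and enrichment to be testable; non-flat folds are drawn
  log-uniformly from [4, 16], so every non-flat gene is DE truth under
  the four-fold rule.
* **Libraries.** Multinomial sampling of canonical tags at fixed library
  size (default 1e5; the real libraries were 4.3–4.7 million and a flag
  scales up), matching the Poisson-like sampling assumption of the
  exact test so type-I-error checks are meaningful; an optional
  Dirichlet noise flag adds overdispersion. Per-base error rate defaults
  to 0.01 (HiSeq-era), applied i.i.d. per base; a fraction
  `1 - 0.99^21 ≈ 0.19` of copies carry at least one error, which the
  tests verify against the closed form.
* **Not simulated.** Read-level quality strings, adaptor artifacts,
  isoforms, poly(A) tails (clean tags are already trimmed 21-mers), and
  the real protocol's unspecified low-quality-tag filter. A green test
  therefore establishes algorithmic correctness under the stated
  sampling model, not robustness to library-prep pathologies.

One compositional subtlety matters for power analyses: because each
library is renormalized to its own total, a one-sided block of
upregulated genes shrinks every realized fold change. The power
acceptance test therefore states a balanced world (50 genes up, 50 down,
8-fold each among 900 nulls), in which the observable fold equals the
generating fold exactly.

## Determinism and numerical choices

Every stochastic stage takes a seed; stage seeds are derived from the
master seed by a fixed affine map (kept below 2^31) and RNG state is
restored afterwards, so whole-pipeline runs are byte-identical under
identical config + seed (the run manifest records wall-clock and is the
one file excluded from byte comparisons; its config hash also excludes
filesystem paths so the same science hashes identically anywhere).
Probability computations run in log space; tails are clamped to [0, 1];
BH enforces monotonicity by a reverse cumulative minimum. K-means ties
in nearest-centre assignment break toward the lower cluster index;
cluster relabelling orders by early-phase mean, descending.

## Known limitations

No replicate-aware dispersion modelling (the design has one pooled
library per time point); no genome-scale intergenic or antisense tags;
no figure-faithful heat-map rendering; enrichment p-values for the real
study's tables are not recomputable because the original background
universe is unstated. The study-scale headline numbers (tens of
thousands of detected genes, mapping fractions, the 0.86 mean qPCR
correlation) depend on the real libraries and genome assemblies and are
out of scope by design; the acceptance suite instead pins closed forms,
brute-force oracles, and generator ground truth.
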
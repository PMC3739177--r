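---
title: "Methods and design notes for spirotax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for spirotax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spirotax)
```

## What the package computes

spirotax re-implements, as a tested pipeline, the comparative-genomic
evidence that modern spirochete taxonomy leans on when 16S rRNA trees alone
cannot settle a genus assignment:

1. **Genome-to-genome distance components.** Two genomes are compared by
   ungapped local alignment; the resulting high-scoring segment pairs
   (HSPs) are summarized into three ratios: *f1*, the fraction of the
   average genome length covered by HSPs; *f2*, the per-site identity
   within HSPs; and *f3*, identities over the average genome length. By
   construction `f3 = f1 * f2`.
2. **COG functional-category composition.** Per-genome gene tables with
   COG category letters become a genomes x 25 count matrix, converted to
   proportions, variance-stabilized, and clustered on both axes for a
   heatmap in which lifestyle groups (free-living, host-associated,
   intracellular) separate.
3. **Trait vs gene-content correlation with phylogenetic correction.**
   A continuous phenotype (the motivating case: mean periplasmic flagella
   per cell) is correlated with a genomic proportion (genes in COG category
   N, cell motility), both on the raw species values and on Felsenstein's
   phylogenetically independent contrasts, which remove the
   pseudocorrelation induced by shared ancestry.
4. **16S rRNA hit-table profiling.** BLAST tabular hits against an rRNA
   database are summarized into score-weighted genus frequencies,
   score-weighted stemmed-keyword frequencies, and per-hit mean HSP
   identity and coverage; aligned rRNA copies can be compared by mismatch
   counts.
5. **Genome summary statistics.** G+C content, coding density, and the
   gene-class breakdown of a standard genome report table.

Every stage can be driven by the synthetic-data module, so the whole
pipeline is testable offline.

## The HSP aligner and the distance formulas

The comparison underlying *f1*-*f3* only needs an aligner that reports
segment coverage and within-segment identity. spirotax uses a blastn-like
ungapped seed-and-extend scheme: exact seeds of `word_size = 11`, +1/-1
match/mismatch scoring, x-drop 20, minimum HSP score 28, both strands of
the second genome. These defaults were fixed once from standard blastn
practice; the original distance-calculator service does not publish its
aligner parameters, so numerical agreement with published pairwise tables
is expected to be approximate, never exact (see Limitations).

Two choices matter for the formulas' semantics:

* **Overlap resolution.** HSPs are kept greedily by descending score and
  discarded if they overlap an already-kept HSP on genome A. Coverage
  therefore never counts a genome-A base twice, which keeps `f1 <= 1` and
  makes `f3 = f1 * f2` an identity rather than an approximation.
* **Normalizing length.** The arithmetic mean of the two genome lengths,
  following the "average of both genome lengths" convention of the
  published tables.

Ambiguity characters never seed and always score as mismatches. An empty
HSP set reports `f2 = 0` with an explicit flag rather than NaN.

## Independent contrasts and their correlation

`independent_contrasts()` is the classical pruning recursion: at each
internal node the standardized contrast is `(x_i - x_j)/sqrt(v_i + v_j)`,
the node inherits the precision-weighted average of its children, and its
parent branch is extended by `v_i v_j/(v_i + v_j)`. A tree with n leaves
yields n - 1 contrasts. Polytomies are resolved arbitrarily into
bifurcations whose zero-length branches are lifted to `1e-8 x` tree height
— small enough not to perturb well-formed trees, large enough to keep the
recursion finite.

Because each contrast's sign depends on the arbitrary order of the two
children, the correlation between two contrast sets is computed **through
the origin** (`r = sum(xy)/sqrt(sum(x^2) sum(y^2))`, no centering), with
significance from `t = r sqrt((n-1)/(1-r^2))` on n - 1 degrees of freedom.
The uncorrected species-level correlation uses standard centered Pearson r
on n - 2 degrees of freedom. The tests verify the recursion against two
independent oracles: a closed-form GLS computation that inverts the
Brownian covariance (shared path length) matrices, and the reference
implementation in ape.

## The synthetic world

The generators state a fixed world; their defaults are not tuned to test
outcomes.

* **Trees** are pure-birth (Yule): while k lineages exist the waiting time
  is Exponential(k x birth rate), and one further waiting period elapses
  after the n-th lineage, so expected root-to-tip depth is
  `sum(1/(k*birth_rate))`, k = 2..n. This is the simplest model producing
  rooted ultrametric trees with strictly positive branch lengths; any real
  rooted tree with branch lengths is accepted downstream.
* **Traits** follow bivariate Brownian motion with per-branch increment
  covariance `rho * sigma_x * sigma_y * branch_length`. `rho` is exactly
  the quantity the contrast correlation estimates, which is what makes
  parameter-recovery simulation a meaningful check (bias below 0.05 at 128
  taxa over 200 replicates, and type-I error of the test near 0.05).
* **Genome pairs** descend from a common ancestor of 50 kb by default:
  a controlled fraction (default 0.30) survives as non-overlapping
  conserved segments (default minimum 100 bp, long enough that a segment
  at moderate identity still clears the score threshold), copied with
  independent per-site substitution so that the identity parameter
  (default 0.85) is the expected fraction of unchanged sites
  (Jukes-Cantor-style replacement to one of the other three bases).
  Everything else is i.i.d. uniform sequence, which keeps background HSPs
  score-limited. The emitted TruthMap is the oracle the aligner must
  recover. The defaults mirror the coverage/identity scale of a
  genus-boundary genome pair (single-digit to tens of percent coverage,
  ~80-90 % within-HSP identity).
* **COG tables** draw each gene's primary category from a per-group
  profile; extra assignments are Poisson(0.1) per gene, reproducing the
  real-table property that summed category counts exceed the number of
  genes assigned to COGs; 22.5 % of genes stay unassigned, a typical
  spirochete value. Planted-group studies draw profiles from Dirichlet(1),
  the uniform distribution on the simplex.

What the generators deliberately do **not** emulate: indels,
rearrangements and repeats in genomes (so the aligner is never tested
against paralogy or shuffling), non-Brownian trait evolution, and any
correlation between COG categories within a genome. A green test
establishes that the algorithms recover the stated statistical structure,
not that they are robust to every artifact of real data.

## COG profiling conventions

The category proportion denominator is the **sum of per-category
assignment counts**, not the number of genes assigned to COGs and not the
total gene count — with multi-category genes these differ, and only this
convention reproduces the published percentage table this package's tests
pin (23 of its 25 one-decimal entries exactly; the remaining two differ by
0.1 from every integer-count denominator and are rounding slips in the
source). The separate "not in COGs" share uses total genes as denominator.

Proportions are variance-stabilized with `asin(sqrt(p))` before
clustering; absolute counts use `log(count + 1)`. Both axes are clustered
with Euclidean distance and average linkage (UPGMA) — a common default for
profile heatmaps; the original figure's package defaults are not
recoverable, so only planted-structure recovery (not topology-level
agreement with the published figure) is asserted.

## 16S profiling conventions

Hits are (query, subject) pairs aggregating possibly many HSP rows: the
hit's score is its best HSP bit score, its identity pools identities over
aligned columns, and its coverage is the merged-interval fraction of the
query. Weights are bit scores, making frequencies invariant to uniform
score rescaling. Keywords are lower-cased, tokenized on non-alphabetic
runs, filtered of tokens shorter than 3 characters and a fixed
function-word stopword list, and Porter-stemmed; each distinct stem counts
**once per hit**. Per-occurrence counting is defensible too (published
keyword percentages may use it); per-hit was chosen because repeated words
within one database description line carry no extra evidence. The Porter
stemmer is implemented in full and tested against the algorithm's
published example vectors. In pairwise rRNA comparisons, sites with gaps
or ambiguity codes are excluded entirely rather than counted as
differences.

## Numerical and degenerate-input choices

* Percentages print at two decimals in distance and genome-statistics
  reports and one decimal in COG tables, matching the published tables'
  precision.
* `|rho| = 1` bypasses the Cholesky factorization (the covariance is
  singular) and drives both traits with one shared normal deviate.
* G+C counting: S counts as G+C, W as A+T (i.e. not G+C); all other
  ambiguity codes are excluded from the numerator only, the denominator
  being full genome length — the percent-of-genome-size convention.
* Pseudo genes are a disjoint class: reported against total genes but not
  added to them, consistent with published tables where CDS + RNA equals
  the stated total while pseudo genes are listed separately.
* The contrast at the root uses the root's two children; the root value
  itself yields no contrast.

## Reproducibility

Every generator takes a seed; the pipeline derives per-stage seeds from
one global seed and records it in the output manifest together with an MD5
digest of every file, so a rerun with the same configuration is verifiably
byte-identical. The run configuration is a single declarative JSON file
(`inst/extdata/demo_config.json` is a working example) whose defaults
mirror the documented per-function defaults.

## Known limitations

* The aligner is ungapped; diverged homologous segments interrupted by
  indels fragment into several HSPs, which slightly underestimates *f2*
  relative to a gapped aligner at identical coverage.
* Published pairwise distance tables cannot be reproduced exactly because
  the original aligner and its parameters are unpublished; the package's
  criterion is internal consistency (`f3 = f1 f2`) plus recovery of
  synthetic ground truth.
* The GenBank reader is minimal (simple, `complement`, and flattened
  `join`/`order` locations); remote or fuzzy locations are skipped.
* Fetching INSDC accessions is deliberately out of scope; comparing real
  genome pairs is a documented manual step (download FASTA, then
  `spirotax ggd`).
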
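---
title: "Stage-resolved expression profiling from barcoded pyrosequencing reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-resolved expression profiling from barcoded pyrosequencing reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyroprofile)
```

## The analysis problem

Early development of benthic mollusks — spiral cleavage, the hatching
trochophore, the swimming veliger, settlement and metamorphosis into a
postlarva — is driven by stage-specific transcriptional programs.
`pyroprofile` implements a complete digital expression-profiling pipeline
for the experimental design used to study this in abalone: seven
synchronized embryonic/larval samples (two-cell, morula, trochophore,
19 h/58 h/74 h veligers, 144 h postlarva) plus one adult tissue library,
each cDNA library tagged with its own multiplex identifier (MID) barcode and
pooled on a single pyrosequencing run of a few hundred thousand reads.

At such depths — orders of magnitude below modern RNA-seq — the central
statistical question is which temporal profiles are *reliable*. The package
therefore couples the profiling steps (demultiplexing, read cleaning,
best-hit counting, per-million normalization) to an explicit per-gene
reliability framework based on Poisson counting error and small-sample
outlier statistics, and validates the surviving profiles against qPCR.

## Reliability model

### Poisson counting error and the count cutoff

A read count $N$ is a Poisson-distributed event count, so its relative
statistical error at a $k\sigma$ confidence level is

$$E\,[\%] = \frac{100\,k}{\sqrt{N}},$$

with $k = 1, 2, 3$ corresponding to 68.3%, 95.5% and 99.7% intervals.
Inverting at a target error gives the smallest acceptable count,
$N = \lceil (100k/E)^2 \rceil$. At the default working point — one sigma,
25% relative error — the cutoff is `cutoff_count(25, 1)` = 16: a gene whose
seven early-stage counts sum to at least 16 is retained, and its true count
lies within $(1 \pm 25\%)N$ at its widest with 68.3% confidence. This is a
deliberately loose gate that preserves most informative genes
(`filter_by_total()`; the comparison operator is configurable because ">="
and ">" are both defensible readings of the protocol).

### Count-depth stars ($\tau_\sigma$)

A seven-stage profile is only as trustworthy as its weakest stage. The
count-depth confidence is scored as

$$\tau_\sigma = \left\lfloor \frac{\sqrt{\min_i N_i}}{4} \right\rfloor,$$

so a gene counted 16 times in *every* stage (each stage exactly at the 25%
one-sigma level) earns one star, 64 per stage earns two, and any
zero-count stage earns none. This "weakest link" aggregation is one
consistent rendering of the anchor condition (all seven counts at 16 give
one star); because it is the principal place where a different reading
could change the candidate list, it is isolated in `tau_sigma_stars()` and
a mean-count aggregator can be selected instead. Whether more than one
$\tau_\sigma$ star is achievable is not constrained by the anchor; the
chosen formula allows it, which rewards deeply covered genes.

### Dixon Q-test stars

Profiles with one dramatic stage are reliable even at modest depth. For the
seven expression values $x_{(1)} \le \dots \le x_{(7)}$ the Dixon $r_{10}$
statistics

$$Q_{low} = \frac{x_{(2)} - x_{(1)}}{x_{(7)} - x_{(1)}}, \qquad
  Q_{high} = \frac{x_{(7)} - x_{(6)}}{x_{(7)} - x_{(1)}}$$

test the low and high extremes; the larger of the two is compared against
the standard two-sided Dean–Dixon critical values for $n = 7$ — 0.507,
0.568 and 0.680 at 90%, 95% and 99% confidence — to award 1, 2 or 3
outlier stars (`dixon_q()`). The critical values are config-overridable
since different editions of the tables differ in the third decimal. The
test is applied to the normalized expression values (the "expression data
points"), not the raw counts, because unequal library depths would
otherwise manufacture outliers; a flag allows raw-count testing. A zero
range (all seven values equal) makes the statistic undefined and is
reported as no confidence. Both statistics are invariant under permutation
and positive affine transforms of the profile, which the test suite checks
property-style.

### Candidate selection

A gene's total stars are $\tau_\sigma + Q$ stars; genes with **2 or more
stars in total** are candidates for cluster analysis (`assign_stars()`,
`star_table()`). The threshold follows the figure-caption convention
("2 or more"); the adjacent protocol text can be read as strictly more
than 2, so the operator is configurable.

## Clustering protocol

Candidates are clustered with the classic Cluster 3.0 recipe
(`cluster_expression()`):

1. exact zeros (undetected, not absent) are replaced by 0.0002, the small
   positive floor used for this data scale (`replace_zeros()`);
2. each row is median-centered three times and scaled to unit sum of
   squares five times (`center_and_normalize()`); because scaling
   preserves a zero median the combination is a projection, and the
   processed matrix satisfies row median 0 and $\sum x^2 = 1$ to 1e-9 —
   asserted on every emitted file. A constant row becomes identically zero
   and is dropped with a warning;
3. genes and stages are clustered by **centroid linkage**: at each step the
   two clusters whose centroids (arithmetic means of member profiles,
   recomputed after every merge) are most similar are joined
   (`centroid_hclust()`). The similarity metric is not dictated by the
   protocol; the default is centered Pearson correlation distance
   ($1 - r$), the conventional choice for expression profiles, with
   uncentered correlation and Euclidean distance selectable. Exact distance
   ties are broken by the smallest pair of original item indices, making
   trees deterministic and order-independent; the test suite verifies the
   implementation against a brute-force $O(n^3)$ oracle on a thousand
   random instances. Centroid linkage can produce height inversions; they
   are emitted as-is rather than repaired.

Results are written as the CDT/GTR/ATR triplet readable by Java TreeView
(`write_treeview()`), with merge similarities recorded as $1 - d$.

## qPCR concordance

Sequencing-derived dynamics are validated against qPCR series
(`concordance_table()`). The gene's per-million series is divided
stage-wise by the geometric mean of the internal control genes (ICGs; the
geometric mean is the standard combination rule for reference-gene panels,
and reduces to the single-gene case), then rescaled so the lowest stage is
1, matching the qPCR fold-change convention. Pearson's $r$ classifies each
gene as strong ($r > 0.75$), acceptable ($r > 0.6$) or weak; since $r$ is
invariant under positive affine transforms, the rescaling affects only
plotting, never classification (asserted in the tests). Correlations are
computed on the linear fold-change scale as plotted; a log-scale option
exists. Zero stages in a sequencing series keep value 0 and the smallest
*detected* stage maps to 1.

## The synthetic-data generator

Every stage of the pipeline is exercised against simulated data with full
ground truth (`sim_config()`, `build_program()`, `sample_counts()`,
`emit_reads()`, `simulate_qpcr()`). The generator emulates the study
design, not sequencing chemistry:

* **Libraries and depths.** Eight libraries (seven early stages plus adult
  intestine) at the study's non-redundant depths (38,923 / 33,423 / 41,160
  / 30,296 / 22,441 / 14,853 / 67,916 / 58,026 reads), the default
  multinomial sizes.
* **Archetypes.** Genes draw from five expression programs: *maternal
  decay* (peak at two-cell, 40–80-fold drop to morula, continued decay),
  *trochophore spike* (30–120-fold over every other stage), *postlarval
  rise* (25–100-fold over every earlier stage), *housekeeping* (flat
  within 1.5-fold) and low *background* (lognormal stage noise, sd 0.5).
  Fold ranges bracket the depletion/induction magnitudes this kind of
  profile exhibits; within-stage biological variance is not documented for
  this design, so the residual stage noise (lognormal sd 0.15) is a free
  parameter chosen to be small relative to the archetype folds.
* **Exact fold contracts under closure.** Relative abundances are closed
  (each library column sums to 1), and naive column normalization would let
  spiking genes compress everyone else's fold ratios. The generator
  therefore scales every non-background profile to peak 1 with a lognormal
  baseline mass (sd 1.2, a realistic expression spread), and lets the
  background genes share each library's mass remainder (about 25% of each
  library): library totals are equal by construction, normalization is one
  global constant, and every archetype contract holds exactly on the
  normalized fractions. Without background genes the columns are normalized
  directly and contracts hold only to $O(1/\sqrt{n_{genes}})$.
* **Benthic shift.** With `benthic_shift = TRUE` (default) the late
  competent veliger and postlarva share programs, emulating anticipatory
  development: postlarval-rise genes are already 2–6-fold elevated at
  74VEL, and 30% of background genes carry one shared 3–6-fold elevation
  at both stages. On typical runs the stage tree joins 74VEL and 144PL
  before either joins an earlier stage; because the signal rides on the
  shallowest library (14,853 reads), individual seeds can miss the
  pairing — the acceptance report includes the observed indicator.
* **Reads.** Each counted read becomes a uniform random 50–600 nt
  subsequence of its transcript (the size-selection window plus a short
  tail), decorated 5' with the library MID (standard Roche 10-mers) and a
  shared adaptor, with substitution errors at a configurable per-base rate
  (default 0.005). Indels, homopolymer/flowgram artifacts and chimeras are
  deliberately not modeled: they would complicate the internal mapper
  without changing what the tests can demonstrate. Duplicates are exact
  full-length copies — matching the duplicate-removal rule's definition of
  redundancy — with extra copies per read drawn Geometric(1 − d), so the
  expected duplicate fraction of the pool is exactly d (default 0.10, the
  clean-to-non-redundant regime of the emulated run) and the expected
  surviving fraction after deduplication is 1 − d.
* **qPCR panels.** True per-stage abundances perturbed by multiplicative
  lognormal noise (sd 0.1 by default) and min-rescaled, with flat
  housekeeping genes serving as synthetic ICGs.

What passing synthetic tests do *not* show about real data: reference bias
and assembly artifacts (references here are exact), mapping ambiguity
between paralogs/isoforms (transcripts are random and dissimilar),
PCR-induced composition bias beyond exact duplication, and 454-specific
error modes. The read-level checks demonstrate the bookkeeping is exact
when the mapper is; they do not benchmark the aligner.

## Numerical and interface choices

* **Internal mapper.** `map_reads_internal()` is a seeded (k = 15),
  ungapped extender with identity ≥ 0.95 and overlap ≥ 50 nt thresholds,
  compiled code for speed. Only best-hit resolution and the
  $E < 10^{-30}$ threshold are scientific rules; real-data users supply
  BLAST tabular hits (`read_blast_tab()`), and the mapper attaches a
  surrogate expectation value $4^{-score}$ — monotone in the score, so
  `resolve_best_hits()` applies unchanged, and calibrated so a perfect
  50 nt match falls just inside the default threshold.
* **Tie-breaks.** Best-hit E-value ties break by score, then
  lexicographically smaller contig id; demultiplexing assigns a read only
  if exactly one MID matches within the mismatch budget (default 0 —
  whether the original matching tolerated mismatches is unrecorded, and
  anchored exact matching avoids cross-library contamination);
  deduplication keeps the first-encountered representative.
* **Denominators.** Per-million normalization divides by the library's
  total non-redundant reads, following the stated formula literally, not
  by its mapped-read count.
* **Problem sizes.** The test suite runs the counts-level pipeline at the
  full library depths with 300–600 genes (a transcriptome-scale count per
  gene well above the real run's, which spread similar depth over ~35,000
  references — candidate fractions are therefore higher here), the
  read-level round trip at 1/100 of the depths with 80 genes, Q-test
  specificity on 2,500 flat genes, and the clustering oracle on up to
  8-item instances; these sizes give stable statistics while keeping the
  suite fast.

## Known limitations

* The count-depth star formula is one consistent reading of an anchor
  condition, not a transcribed equation; reproducing an exact published
  candidate count depends on that reading (and is the flagged risk when
  applying the pipeline to the original expression table).
* Dixon's test addresses a single outlier in seven points; profiles with
  two elevated stages (for example a shared benthic program) earn no
  outlier stars and must qualify through count depth alone.
* No multiple-testing correction is applied across genes, by design
  fidelity to the original protocol.
* Centroid linkage is not inversion-free, and cutting an inverted tree at
  a fixed cluster count should be interpreted with care.
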
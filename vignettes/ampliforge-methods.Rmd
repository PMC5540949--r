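---
title: "ampliforge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ampliforge: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ampliforge is a self-contained 16S rRNA gene amplicon pipeline of the
classic OTU-based design: paired-end merging, primer trimming,
expected-error filtering, pooled dereplication, greedy centroid clustering
at a fixed identity cutoff, naive-Bayes taxonomy, and the standard
diversity, ordination, hypothesis-testing and co-occurrence layers. This
vignette explains each model, the tunable parameters, the numerical
choices, and what the built-in mock-community validation does and does not
demonstrate.

## Read preparation

**Merging.** A pair is merged by aligning the forward read against the
reverse complement of its mate over every ungapped offset whose overlap is
at least `min_overlap_len` (default 100 nt). The scan is exhaustive and
scored as matches − mismatches with ties broken toward the longer overlap,
so it is exact at any realistic read length; `N` never matches anything.
A pair is rejected as `short_overlap` when the best candidate scores no
better than chance (score ≤ 0 — with no admissible overlap the comparison
is essentially random sequence, which scores negatively in expectation),
and as `too_many_diffs` when the best overlap carries more than
`max_diffs` (default 8) mismatches.

**Posterior qualities.** In the overlap a single base and quality are
derived per column: agreeing bases get `Q = min(Q1 + Q2, 45)` (independent
observations of the same base multiply error probabilities, capped at the
container's Phred ceiling of 45), and disagreeing columns keep the
higher-quality base with `Q = max(2, |Q1 − Q2|)`. This mirrors published
posterior-error mergers: a disagreement between two similar qualities
leaves almost no information, and such columns correctly inflate the
expected-error statistic downstream.

**Primer trimming** is anchored: the best-matching forward primer is
compared at position 1 and the reverse complement of the best-matching
reverse primer flush with the 3' end, IUPAC-aware, allowing `pdiffs`
(default 2) mismatches each. There is no floating search window — after
merging, a well-formed amplicon read starts and ends in its primers.

**Quality filtering** truncates each read to `trunclen` bases (default
250) and discards it when the expected errors over the truncated read,
`EE = Σ 10^(−Q/10)`, exceed `maxee` (default 1.0). Reads shorter than
`trunclen` are discarded, so every surviving read has identical length —
which also lets the clustering stage use exact Hamming comparisons.
Filtering uses the posterior qualities (they are what exists after
merging). The boundary is inclusive: `EE == maxee` passes, with a 1e-9
absolute tolerance so that the closed-form boundary case (100 bases at
Q20 against `maxee = 1.0`) is not lost to floating-point accumulation.
Defaults for `maxee`, `trunclen`, `pdiffs` and the 0.97 similarity cutoff
are package choices, logged at run time.

## OTU inference

Dereplication collapses identical reads with per-sample counts and sorts
by abundance (descending), ties broken lexicographically by sequence —
every downstream step is therefore deterministic. Singletons (abundance
1) are removed before centroid formation; error-derived sequences are
overwhelmingly singletons, and seeding centroids from them inflates
richness.

Clustering is a single greedy pass: each unique joins the
highest-identity existing centroid at or above `similarity_cutoff`
(default 0.97, the conventional species-level proxy); otherwise it is
tested as a chimera and, failing that, founds a new OTU. Identity between
equal-length sequences is the ungapped fraction of matching positions;
for unequal lengths a global alignment with free terminal gaps
(match +1, mismatch −1, gap −2; identity over non-terminal columns) is
used via Biostrings.

The chimera test is a deliberately simple two-parent, single-crossover
model: a query is flagged when some crossover column splits it into a
prefix ≥ 99% identical to one centroid and a suffix ≥ 99% identical to a
different centroid, while no single centroid reaches the cutoff and all
candidate parents are at least `chimera_skew` (default 2.0) times as
abundant as the query. The segment threshold and skew are configuration,
not biology; the model trades sensitivity for transparency and is not a
re-implementation of any published detector.

After clustering, *all* reads — including members of discarded singleton
uniques — are mapped back to the highest-identity centroid at or above
the cutoff; unassignable reads are dropped and counted. Rarefaction
subsamples each sample without replacement to a common depth (default:
the smallest sample total, the largest depth every sample can support),
deterministically given the seed. Diversity is computed on both the raw
and the rarefied table; classification uses the unrarefied centroids.

## Taxonomy

The classifier is the word-presence naive-Bayes scheme standard for
amplicon reads: 8-mer profiles per genus, word prior
`(n_w + 0.5)/(N + 1)`, genus conditional `(m_w + prior)/(M + 1)`, genus
score as the sum of log conditionals over the query's word set. Bootstrap
confidence at each rank is the fraction of 100 resamples of `⌊W/8⌋` words
whose winner falls under that rank's taxon; ranks below 0.80 report
"unclassified", and everything beneath the first unclassified rank is
unclassified too. `k = 8`, the 1/8 subsample, 100 bootstraps and the 0.80
cutoff are the conventional values for this family of classifiers; all
are arguments. The reference database is pluggable (FASTA plus a
tab-separated lineage file); the test suite ships only synthetic
references generated in code.

## Diversity, ordination, tests

Alpha indices use the Mothur-compatible definitions: `sobs`; Chao1
`S + n1(n1−1)/(2(n2+1))`; ACE with rare cutoff 10; first-order jackknife
`S + n1(N−1)/N`; Shannon with natural logs; the Chao–Shen
coverage-adjusted Shannon (`npshannon`); and the unbiased Simpson
`Σ n_i(n_i−1)/(N(N−1))`. Beta measures: Jaccard on membership (`jclass`),
Jaccard with Chao1-estimated per-sample richnesses and the observed
shared-OTU count (`jest` — the estimator pair is a package choice, since
several variants circulate), Yue–Clayton θ on relative abundances
(`thetayc`), and Bray–Curtis on counts.

UPGMA trees come from average-linkage `hclust`; leaf-to-root height is
half the final merge distance, so ultrametric inputs are reconstructed
exactly. PCoA is classical scaling (`cmdscale`). NMDS minimises Kruskal
stress-1 through `MASS::isoMDS`, started from the metric-scaling
configuration plus `n_starts − 1` random restarts (default 20), keeping
the lowest-stress fit; `isoMDS` is the canonical Kruskal implementation,
so the package wraps it rather than re-deriving the isotonic-regression
loop, and reports stress as a fraction. Exact zeros in the input are
nudged to `max(d)·1e-9` because tied-at-zero dissimilarities break the
monotone regression.

AMOVA partitions squared distances:
`F = (SS_among/(k−1)) / (SS_within/(N−k))` with
`SS_within = Σ_g Σ_{i<j∈g} d²_{ij}/n_g` and `SS_among = SS_total −
SS_within`; HOMOVA is the Bartlett-style statistic on within-group mean
squared distances, zero when dispersions are equal. Both use label
permutation with `p = (1 + #{perm ≥ obs})/(1 + n_perm)`, which can never
report zero. Note an arithmetic consequence of this estimator: with two
groups of four, a random permutation reproduces the observed partition
with probability 1/35, so the smallest attainable p is ≈ 0.03 regardless
of effect size; power statements in the validation therefore use groups
of five at the 0.05 level, where separation drives p to ≈ 0.009.

## Co-occurrence networks

OTUs below 0.1% overall relative abundance or present in fewer than two
samples are removed; correlations (Spearman on midranks, or Pearson) are
computed on the absolute counts of the survivors, with two-sided p-values
from the t transform on n − 2 degrees of freedom. Edges require
`|r| ≥ 0.6` and `p ≤ 0.01` (or 0.05), applied inclusively at the
boundary. No multiple-testing correction is applied by default, matching
common practice for these descriptive networks; negative correlations
are kept by magnitude with the sign stored (`positive_only` restores the
signed reading). Constant OTU vectors are skipped with a warning. The
graph serialises to GEXF 1.2 with taxonomy/abundance node attributes and
r/p/method edge attributes.

## The mock-community simulator

The simulator is the package's study condition, not a tuning knob. Its
default design: 25 bacterial members forming 21 distinct 16S classes —
three multi-strain species (2 + 2 + 3 members) are identical at the 16S
level, and four single-strain classes occur only in the uneven community
at ~0.01%. Members evolve from a random ancestor on a star topology at a
0.04 per-lineage substitution rate and are rejection-sampled until every
inter-class identity (full 427-nt insert and its first 250 nt, the
post-truncation window) sits below 96%. Each gene carries an exact
forward-primer site and a concretised reverse-primer site so in-silico
PCR yields the 427-nt insert exactly.

Profiles: ECC weights equal cells by a per-class 16S copy number (drawn
once from 1–12, the realistic bacterial range); EPC draws per-member
protein masses from lognormal(0, 0.5) and sets cells ∝ 1/mass; UEC is a
log-uniform ladder over four orders of magnitude with the four rare
classes pinned at the `low_abundance_tail`. Reads are 2 × 300 with a
position-dependent substitution rate rising exponentially from 0.1% to
1% across the read; the emitted Phred score is the rounded −10·log10 of
that rate and errors are injected at exactly `10^(−Q/10)`, so qualities
and error rates agree by construction. Cross-talk reassigns each read
pair to a uniformly random other sample with the configured probability
and logs every move.

The simulator does **not** model indels, PCR chimeras (chimera tests
construct chimeras directly), primer-site mutations, length variation,
or run-to-run carry-over. Passing the end-to-end checks therefore shows
the pipeline's bookkeeping, clustering and statistics are correct under
substitution noise at realistic depths — it does not certify behaviour
on real data with indel errors or amplification bias.

## Cross-talk detection

`crosstalk_report` flags (OTU, sample) pairs where an OTU is a trace
presence (below 0.1%, at least `min_reads` reads) while being a major
member (above 1%) of another sample — the signature of index hopping.
The thresholds are the report's definition of "major" and "trace" and are
configurable. A threshold arithmetic worth knowing: with misassignment
rate x and d donor samples among n, a donor OTU at abundance a lands in
a recipient at about `x·a·d/(n−1)`; at 2% cross-talk the 0.1% trace
ceiling is honoured only when that product stays below it. The built-in
validation therefore uses a 12-sample layout (2 ECC + 2 EPC + 8 UEC at
20,000 pairs) in which contamination peaks near 0.07%; cross-talk into an
OTU already abundant in the recipient is undetectable by definition and
excluded from the recall denominator.

## Problem sizes and determinism

The validation runs the simulator at 4 replicates × 5,000 pairs for the
three-profile recovery study and 12 × 20,000 pairs for cross-talk —
depths at which every per-stage statistic is comfortably estimated while
a full run stays in the minutes range on one core. One seed governs
reference generation, read simulation, rarefaction, classifier
bootstraps, NMDS restarts and permutation tests; identical inputs and
seed reproduce byte-identical tabular outputs.

Degenerate inputs are handled explicitly: empty FASTQ files parse to
empty sets; samples below the rarefaction depth are dropped with a
warning; constant vectors are skipped in correlation; a single-OTU
sample has Shannon 0 and Simpson 1; groups of one sample are rejected by
AMOVA/HOMOVA rather than silently absorbed.

## Known limitations

No denoising/ASV mode; no reference-based chimera detection; no UniFrac
or parsimony tests (they need an OTU phylogeny this pipeline does not
build); single-end FASTA+qual input is supported but primer orientation
is not inferred from the mapping strand column, which is recorded and
otherwise ignored; gzip input relies on R's transparent decompression.
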
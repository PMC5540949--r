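# ampliforge

A self-contained 16S rRNA gene amplicon analysis pipeline for microbial
ecologists, built around the classic OTU workflow and validated end to end
against simulated mock communities of known composition.

From demultiplexed paired-end FASTQ (or FASTA + qual) files it performs:

- **read preparation** — exhaustive-scan pair merging with posterior
  qualities (agreeing bases: `Q = min(Q1+Q2, 45)`; disagreeing: keep the
  better base at `Q = max(2, |Q1−Q2|)`), anchored IUPAC-aware primer
  trimming, fixed-length truncation and expected-error filtering
  (`EE = Σ 10^(−Q/10) ≤ maxee`);
- **OTU inference** — pooled dereplication, singleton removal, greedy
  centroid clustering at a 97% identity cutoff with a two-parent
  crossover chimera test, read mapping back to centroids, rarefaction;
- **taxonomy** — word-presence naive-Bayes classification (8-mers, word
  prior `(n_w+0.5)/(N+1)`, genus conditional `(m_w+prior)/(M+1)`) with
  bootstrap confidence per rank;
- **diversity** — sobs, Chao1, ACE, jackknife, Shannon, np-Shannon,
  Simpson; Jclass/Jest/θYC/Bray-Curtis distances; UPGMA trees; PCoA and
  NMDS; AMOVA (`F = (SS_among/(k−1))/(SS_within/(N−k))` on squared
  distances) and HOMOVA by label permutation;
- **co-occurrence networks** — abundance/prevalence filtering, Spearman or
  Pearson correlations with t-based p-values, `|r| ≥ 0.6` and
  `p ≤ 0.01` edge thresholds, GEXF 1.2 export;
- **a mock-community simulator** — equal-cell (ECC), equal-protein (EPC)
  and uneven (UEC) designs with 16S copy-number weighting, MiSeq-like
  2×300 reads with position-dependent substitution errors, and injected
  between-sample index cross-talk with a truth log — plus a cross-talk
  detector (`crosstalk_report`) for real multiplexed runs.

## Worked example

Simulate a small two-replicate mock run and push it through the whole
pipeline:

```r
library(ampliforge)
dir <- file.path(tempdir(), "demo")
sim <- simulate_mock_dataset(dir, n_replicates = 2, n_pairs = 1000, seed = 7)
res <- run_pipeline(file.path(dir, "mapping.txt"), file.path(dir, "oligos.txt"),
                    out_dir = file.path(dir, "results"),
                    reference = read_reference_db(
                      file.path(dir, "reference.fasta"),
                      file.path(dir, "reference.tax")),
                    n_perm = 999, seed = 7)
res$table
#> OTU table: 6 sample(s) x 17 OTU(s), 3848 reads
head(res$prep_stats[, c("sample", "input", "merged", "passed")], 3)
#>   sample input merged passed
#> 1  ECC_1  1000   1000    640
#> 2  ECC_2  1000   1000    640
#> 3  EPC_1  1000   1000    651
```

The 17 OTUs are exactly the 17 sequence classes present in the ECC/EPC
designs (the four UEC-only members at ~0.01% are below detection at this
depth). About 64% of pairs survive preparation: merging succeeds for
essentially all pairs, and the expected-error filter removes reads whose
overlap disagreements collapse posterior qualities. Taxonomy resolves
every centroid to its genus with full bootstrap support:

```r
res$taxonomy$taxonomy[1]
#> "Bacteria(100);Phylum_02(100);Class_03(100);Order_06(100);Family_06(100);Genus_12(100)"
head(alpha_diversity_table(res$rarefied)[, c("sample", "sobs", "chao", "shannon")], 3)
#>   sample sobs chao  shannon
#> 1  ECC_1   17   17 2.596511
#> 2  ECC_2   17   17 2.594449
#> 3  EPC_1   17   17 2.489520
res$ordination$nmds$stress
#> 2.7e-05
res$tests$amova$p_value
#> 0.06
```

Shannon diversity sits just below `ln 17 ≈ 2.83` (the communities are
near-uniform after copy-number weighting), and the three community types
separate cleanly in ordination. The AMOVA p of 0.06 is the smallest value
attainable with two samples per group under the permutation estimator
`(1 + more extreme)/(1 + n_perm)` — with 4 replicates per type (the
validation condition) the same contrast yields p ≈ 0.001–0.002.

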
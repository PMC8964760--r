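# donorwatch

Toolkit for predicting which **cryptic splice donor** a genetic variant
will activate.

When a variant damages an annotated 5' splice site (donor), the
spliceosome often falls back on a nearby *decoy* donor — any GT (or GC)
dinucleotide in the surrounding exon or intron. Which decoy is chosen
has direct diagnostic consequences (frameshift vs in-frame), yet is hard
to predict from sequence alone. `donorwatch` implements an empirical
framework for this problem, aimed at splicing researchers and diagnostic
bioinformaticians:

- **Donor/decoy enumeration** — canonical exon–intron junctions from a
  GTF + FASTA, and every GT/GC decoy within ±250 nt of each annotated
  donor (excluding decoys that would leave an intron < 80 nt).
- **Donor Frequency (DF)** — a donor-strength score. The extended donor
  region spans E⁻⁴..D⁺⁸ (last 4 exonic + first 8 intronic nt). For a
  site, count how many annotated donors genome-wide carry the exact same
  9-mer in each of the four 9-nt windows of that 12-mer, take the median
  of the four counts, and report its percentile on the empirical
  distribution over all index donors. DF = 0 means the sequence never
  occurs as a real donor. A decoy is *competitive* when
  DF(decoy) ≥ 0.1 × DF(annotated).
- **Variant classification** — AM (modifies the annotated donor), CM
  (modifies the cryptic donor), AM/CM (both), assigned from the
  intersection of the variant's footprint with each site's E⁻⁴..D⁺⁸
  window, plus the database inclusion/exclusion criteria.
- **Decoy depletion** — observed/expected decoy counts per position,
  where expected counts come from dinucleotide-preserving (Euler)
  shuffles of the exonic and intronic sequence (15 shuffles by default),
  stratified by frame, relative DF and G-triplet overlap.
- **Ranked mis-splicing database** — aggregates per-sample
  splice-junction files (STAR `SJ.out.tab` or TSV) across a population,
  keeps unannotated donors that splice to an annotated acceptor within
  250 nt of the annotated donor in ≥ 3 samples, and ranks events per
  junction by descending sample count (the "40K-RNA" construction).
- **Prediction & evaluation** — the top-4 rule (predict the 4
  highest-ranked events per junction), the Δ-score ≥ 0.1 rule under a
  pluggable scorer, their union, and sensitivity/specificity sweeps.
- **In-silico saturation mutagenesis** — per-position importance
  `s_actual − (s_A + s_C + s_G + s_T)/4` for any scorer.
- **Synthetic data** — a deterministic generator of toy genomes,
  annotations, variants and per-sample junction files with planted
  ground truth, so the whole pipeline is testable offline.

MaxEntScan / NNSplice / SpliceAI are deliberately *not* bundled: they
enter through the scorer contract (a function from 12-nt windows to
scores in [0, 1]) or external score tables. The shipped default scorer
is DF.

## Worked example

```r
library(donorwatch)

cfg <- sim_config(n_genes = 10, n_samples = 100, seed = 42)
sim <- generate_genome(cfg)                         # FASTA+GTF-equivalent in memory
jx  <- enumerate_junctions(sim$transcripts, sim$genome)
idx <- build_df_index(jx, sim$genome)
idx
#> DF index: 20 donors, 4 positional 9-mer tables

ss  <- simulate_junction_samples(sim, cfg)          # 100 samples, planted mis-splicing
db  <- build_missplice_db(ss$samples, jx)           # aggregate, filter, rank
jn  <- jx[1, ]
predict_top_k(db, jn, k = 4)[, c("offset", "sample_count", "total_reads", "rank")]
#>   offset sample_count total_reads rank
#> 4     33           94         235    1
#> 5   -110           33          92    2
#> 6    160           21          39    3
```

The junction's most frequently mis-spliced event across the cohort is a
cryptic donor 33 nt into the intron, seen in 94 of 100 samples (rank 1);
under the top-4 rule all three events are predicted activatable. DF
scores for the decoys around the same donor:

```r
dec <- enumerate_decoys(jn, sim$genome)
s   <- df_score(dec$window, idx)
ann <- df_score(donor_window(sim$genome, jn$contig, jn$donor_pos, jn$strand)$window, idx)
rel <- relative_df(s$percentile, ann$percentile)
head(data.frame(offset = dec$offset, dinuc = dec$dinuc,
                df = s$percentile, relative = round(rel$ratio, 2),
                competitive = rel$competitive))
#>   offset dinuc df relative competitive
#> 1   -149    GT  0        0       FALSE
#> 2   -142    GC  0        0       FALSE
#> 3   -128    GC  0        0       FALSE
#> ...
```

Distal background decoys have DF 0 — their 12-mers never occur as a real
donor — so none is competitive with the annotated donor.

The same pipeline is scriptable from a shell via the thin CLI
(`inst/cli/donorwatch`): `simulate`, `junctions`, `df-index`,
`df-score`, `classify`, `depletion`, `build-db`, `predict`, `evaluate`,
`mutagenesis`, and `reproduce` (a full-scale composition report against
shipped reference values; requires the real genome/annotation/junction
inputs). Every run writes a JSON manifest next to its output.

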
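---
title: "Methods: scoring, shuffling and simulating cryptic splice-donor activation"
author: "donorwatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, shuffling and simulating cryptic splice-donor activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(donorwatch)
```

## The problem and the model

A donor (5' splice site) is recognised through an extended motif
spanning the last four exonic bases and the first eight intronic bases,
written E⁻⁴..D⁺⁸ (12 nt; E⁻¹ is the last exonic base, D⁺¹ the first
intronic base, and D⁺¹D⁺² is almost always GT, rarely GC). Any other
GT/GC near an annotated donor is a *decoy*: a potential splice site the
spliceosome normally ignores. When a variant weakens the annotated
donor (or strengthens a decoy), a decoy can be *activated* as a cryptic
donor. `donorwatch` models three empirical signals around this event:

1. **Strength** — how donor-like a 12-mer is (Donor Frequency);
2. **Depletion** — how strongly evolution has purged competitive decoys
   near real donors (observed/expected against dinucleotide-preserving
   shuffles);
3. **Usage** — whether a decoy is already used, rarely, across a large
   RNA-seq population (the ranked mis-splicing database and its top-4
   prediction rule).

### Coordinate conventions

Internally all genomic coordinates are 1-based inclusive, the native
convention of R, Bioconductor and GTF; junction interchange files use
the STAR convention (first/last intronic base). Offsets of decoy and
cryptic donors are signed distances between D⁺¹ positions in transcript
orientation: offset 0 is the annotated donor, negative offsets are
exonic (a cryptic at the E⁻⁴ position has offset −4), positive offsets
are intronic (a cryptic whose D⁺¹ is the annotated D⁺⁵ has offset +4).
Truncated windows at contig edges are flagged and excluded from DF
scoring rather than padded.

## Donor Frequency (DF)

For every index donor, the 12-nt window is cut into four consecutive
9-nt windows (window *w* covers positions *w..w+8*, *w* = 1..4); each
window position keeps a count table of exact 9-mers over all index
donors. A query's raw counts are the four table lookups (0 when
absent); its raw score is the median — for four values, the mean of the
two middle ones, so `{0, 2, 4, 10}` scores 3 — and the reported DF is
the percentile of that median on the empirical distribution of
per-donor medians: `#(median_i ≤ median_query) / n_donors`.

Design choices, fixed and documented:

- **Inclusive percentile (≤)**: every index donor scores strictly above
  0 against its own index, so DF = 0 is reserved for sequences that
  never occur as a real donor.
- **Window length 9** is the default (it best encompasses the splice
  site); `build_df_index(window_length = )` exposes it for sweeps.
- **Index donor set**: defaults to the filtered canonical junction set;
  the CLI flag `--all-donors` indexes every annotated donor instead.
  Both modes exist because the reference percentile distribution can
  plausibly be parameterised either way.
- GC donors are indexed alongside GT donors — membership comes from the
  annotation, not the dinucleotide.
- A window containing N is *undefined* (NA), distinguishable from a
  genuine 0.

Relative DF of a decoy is `DF(decoy) / DF(annotated)`; a decoy is
*competitive* at ratio ≥ 0.1 (boundary inclusive). The ratio is
undefined when the annotated donor itself scores 0.

## Junction filtering

The reference donor universe keeps junctions that are: not in
single-exon transcripts; not a transcript's first or last intron;
inside the transcript's CDS (both the donor and its paired acceptor —
the stricter of the two readings, chosen so that cryptic splicing at a
retained junction always disturbs the reading frame of the protein);
not flanked by an exon with alternative 5'/3' boundaries in another
transcript of the same gene; and GT/GC at D⁺¹D⁺². Filter counts are
reported in a summary attribute. Decoy enumeration around a retained
junction scans ±250 nt (clipped to the exon and intron), excludes
offset 0, and removes intronic decoys whose use would leave an intron
shorter than 80 nt (the 1st percentile of human intron length). No
minimum-exon-length rule is applied — only the intron rule has a
biological floor.

## Variant classification

Variants are VCF-style, left-anchored, plus-strand alleles. The
*footprint* is the set of reference bases actually changed (anchor
trimmed); an insertion's footprint is its insertion point, which
intersects a window only when both flanking bases are window bases
(pure edge-adjacent insertions outside the window do not count).
Categories follow window intersection: AM touches only the annotated
E⁻⁴..D⁺⁸, CM only a cryptic's, AM/CM both; the three are mutually
exclusive and exhaustive over included variants. Inclusion requires the
variant to touch at least one window, every observed cryptic to lie
between the exon's 5' end and the intron's 3' end, and every cryptic
VAR window to retain GT/GC at D⁺¹D⁺² (guarding against misannotation).
For indels, offsets are re-measured on the VAR sequence via a monotone
REF→VAR coordinate map (deleted bases map to the deletion's left edge);
both REF- and VAR-frame offsets are reported. A variant that deletes
the annotated GT entirely is still AM by footprint; its annotated VAR
window is marked absent. Unmodified cryptics co-activated alongside an
AM/CM variant are flagged out of category-level analyses.

## Dinucleotide-preserving shuffle and depletion

Exonic and intronic sequences around donors have strong positional
dinucleotide structure (G/T-repeat enrichment in the first ~50 intronic
nt), so a fair null for "how many GT/GC would occur by chance" must
preserve dinucleotide composition exactly. `dinucleotide_shuffle()`
implements the Euler method: the sequence is an Eulerian path on its
transition multigraph; a uniformly random ordering of each vertex's
out-edges is accepted when the last edges form an arborescence into the
final character, which makes the resulting walk uniform over all valid
arrangements (rejection sampling over orderings; the
arborescence-ordering correspondence guarantees correctness). The
shuffle preserves the dinucleotide multiset, length, and first/last
characters exactly.

Depletion curves shuffle each junction's exonic segment (up to 150 nt,
clipped to the exon) and intronic segment (up to 150 nt, stopping 50 nt
short of the acceptor) independently, 15 times by default, and compare
observed decoy counts per offset with the mean over shuffles. Numerical
care:

- Observed and expected are counted on an identical positional domain
  per junction — including the min-intron cutoff, which is purely
  positional — so O/E is calibrated at 1 on null sequence (checked: on
  200 i.i.d.-uniform junctions the mean O/E lies within [0.9, 1.1]).
- The shuffled segments are spliced back into the real flanking context,
  so windows that straddle a segment boundary remain well defined; the
  Euler shuffle's endpoint preservation keeps the exon/intron boundary
  dinucleotide comparable between real and shuffled sequence.
- O/E is reported as missing where expected = 0, never infinity.
- Strata: dinucleotide (GT/GC) always; reading frame (exonic in-frame =
  |offset| divisible by 3, everything else "out"); relative-DF bins
  {0, (0,0.1), [0.1,0.5), [0.5,0.9), ≥0.9} — chosen to contain the
  named analysis bins (DF = 0, the 10% competitiveness threshold,
  50–90%, ≥90%); G-triplet overlap (any GGG run intersecting the
  12-nt window, run length ≥ 3). Stratum labels for shuffled decoys are
  computed from the shuffled sequence's own windows, so every stratum
  carries a self-consistent null.
- One seeded generator drives a run sequentially; identical seeds give
  bit-identical curves.

## The ranked mis-splicing database and prediction

Per-sample junction files are aggregated by unique key (contig, first
intronic base, last intronic base, strand): number of supporting
samples, total reads, maximum reads in one sample. The ≥3-sample filter
is applied after merging all sources. An aggregated junction becomes a
mis-splicing event at an annotated junction when it splices to exactly
that junction's acceptor from an unannotated donor lying between the
exon's 5' end and the intron's 3' end, within 250 nt of the annotated
donor. "Unannotated" is scoped to the supplied annotation. Events at
one junction are ranked by sample count; ties break by total reads,
then smaller |offset|, then exonic before intronic — undefined in the
source analyses, fixed here so top-4 membership is deterministic. An
unannotated donor within 250 nt of two annotated junctions is assigned
to both, each with its own offset.

The **top-4 rule** predicts the four highest-ranked events per junction
(all, if fewer). The **Δ-score rule** predicts a candidate when
`score(VAR) − score(REF) ≥ 0.1` under any scorer meeting the contract
(deterministic, range [0, 1], explicit floor for "not recognised");
the shipped scorer is DF — importantly, DF's Δ only reacts when the
variant changes the candidate's own 12-mer, so AM variants (which leave
cryptic windows untouched) are invisible to it; deep-learning scorers
that integrate context are supported only through the plug-in contract
or external score tables. Evaluation pools per-cryptic counts
(sensitivity = TP/(TP+FN) over true cryptics, specificity = TN/(TN+FP)
over non-activated decoys of the same junctions), sweeps rank cut-offs
and Δ thresholds, and asserts monotonicity. Strength-change categories
use the VAR/REF ratio with boundaries at 0.5 (closed on the milder
side), 0.9 and 1.1 — the interior boundaries are implementation choices
where only the outer categories ("weaker by >50%", "stronger by >10%")
are externally fixed.

## In-silico saturation mutagenesis

For a target site and scorer, each position in the analysis window
(E⁻⁴..D⁺⁸ ± 20 nt by default) is substituted with all four bases and
the target rescored; importance is
`s_actual − (s_A + s_C + s_G + s_T)/4`. Substituting the actual base
reproduces `s_actual` exactly (asserted), and substitutions a scorer
cannot score take its floor, flagged. The default DF scorer makes these
tracks DF tracks — they are not SpliceAI tracks.

## The synthetic generator: what it emulates, and what not

The generator is first-class, tested code; its defaults define the
study conditions used by the test suite and the acceptance script:

- 50 genes × 5 exons (one contig per gene, alternating strand), exons
  120–180 nt, introns 300–400 nt, uniform-ACGT background — sized so
  that each gene contributes two usable middle junctions (100
  junctions) and every analysis extent fits.
- Annotated donors drawn from a sharp consensus-like PWM over
  E⁻⁴..D⁺⁸ with variation concentrated at four positions, so exact
  9-mer repeats among donors are common, as they are genome-wide —
  required for a non-degenerate DF distribution at a 100-donor scale.
- Three planted decoys per junction in disjoint offset bands: *strong*
  (consensus GT, |offset| 16–36), *medium* (GC, PWM 30%-mixed with
  uniform, |offset| 80–112), *weak* (random GT, intronic 140–200). The
  bands guarantee planted windows never overlap each other or the
  annotated window, and the tiers separate cleanly in the usage kernel
  (a GC decoy always scores DF 0 against a GT-donor index).
- Usage kernel: each planted decoy is used in a sample with probability
  `plogis(4·DF − 2·|offset|/250)` — strength helps, distance hurts,
  matching the qualitative empirical pattern (proximal, strong decoys
  are seen most often). Annotated junctions get log-normal(meanlog 4,
  sdlog 0.5) read depth; used cryptic junctions get zero-truncated
  Poisson(2) reads.
- Variants: AM = D⁺² T>A at the annotated donor with the strong decoy
  as the observed cryptic; CM = GC→GT at a medium decoy's D⁺²; AM/CM =
  a substitution at a position shared by the annotated window and a
  background decoy's window within ±11 nt, avoiding both essential
  dinucleotides. Labels are provable from the band geometry and close
  the loop through the classifier exactly.

Everything is a deterministic function of the config seed. What the
generator does **not** emulate: real donor-motif covariance beyond a
PWM, splicing regulatory elements (G-runs arise only by chance),
read-depth-dependent detection, sequencing error, exon skipping, intron
retention, and acceptor-side events. Passing tests therefore show that
the machinery is correct and calibrated on known ground truth — not
that real-genome performance numbers are reproduced; those require the
real genome, annotation, variant table and population junction data,
via the `reproduce` CLI path, which recomputes the composition
statistics and compares them with the shipped full-scale reference
values.

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` run at: 1,000 random
junctions for oracle-equivalence checks, 1,000 random sequences
(lengths 2–500) for shuffle exactness, 200 junctions × 15 shuffles for
null calibration, the 50-gene × 200-sample end-to-end recovery, and a
10⁴-donor index for DF distribution properties — sizes chosen to
exercise every code path at statistically meaningful scale while
keeping a full run in a couple of minutes on one CPU. All randomness
flows from explicit seeds; no wall-clock seeding anywhere.

## Known limitations

- Exact-match k-mer counting means DF saturates for very common motifs
  and is 0 for any sequence absent from the index; it has no notion of
  near-miss similarity.
- The alternative-ends filter sees only the supplied annotation.
- Chromosome names must match exactly between FASTA and GTF (no
  chr1/1 aliasing), and GFF3 is not supported.
- The database method cannot, by construction, predict cryptics created
  de novo by a variant (new GT/GC) or never observed in the population;
  the Δ-score path exists for exactly those cases.
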
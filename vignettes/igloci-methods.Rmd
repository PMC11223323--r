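---
title: "Annotating teleost immunoglobulin loci and analysing CDR3 repertoires with igloci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating teleost immunoglobulin loci and analysing CDR3 repertoires with igloci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igloci)
```

## The biological problem

Atlantic cod B-cell receptors diversify without somatic hypermutation: the
species lacks the MHC II pathway and AID activity, so all antibody diversity
must come from the germline segment inventory and from junctional events
during V(D)J recombination (exonucleolytic deletions, palindromic P
additions, non-templated N additions). Understanding its antibody response
therefore splits into two computational problems that this package solves
end to end:

1. **Germline annotation** — find every V, D, J and C gene segment in a
   genomic region, decide which are functional, and describe how the locus
   is organized (heavy-chain *translocons* of many V then D, J, C genes;
   light-chain *mini-clusters* repeating single V–J–C units, with kappa V
   genes mostly inverted relative to their J and C).
2. **Repertoire analysis** — turn 5'RACE paired short reads into CDR3
   clonotypes and summarize their diversity, sharing and germline usage.

Because no public data are needed to exercise the machinery, a first-class
synthetic-data module generates loci, recombined clonotypes and reads with a
complete truth table; the test suite and the acceptance script run the whole
pipeline against that truth.

## Annotation model

### Similarity seeding

Candidate segments are seeded with a two-tier nucleotide BLAST search
(`seed_gene_candidates`): a lenient pass (e-value 0.1) marks regions of
interest and a strict pass (1e-5) defines candidates; J genes keep the
lenient threshold because ~40 nt sequences cannot reach small e-values.
Overlapping hits are merged keeping the best bit-score (ties to the leftmost
start). Seeding uses nucleotide references; each reference carries metadata
(`kind=`, `chain=`, `cys=` for the conserved 2nd-CYS codon of a V, `anchor=`
for the J [FW]GxG anchor) that the refinement step projects onto the genome
through a global-local alignment. Indels in that alignment whose widths are
not multiples of three are reported as frameshifts; the alignment is
restricted to the reference prefix up to the CYS codon so that natural
length differences in the CDR3 tail are not mistaken for indels.

### Motif rules

* **RSS.** `scan_rss` finds heptamer–spacer–nonamer windows on both strands.
  Defaults: heptamer `CACAGTG` or `CACAGCA` with at most 1 mismatch and an
  invariant `CAC` prefix; nonamer `ACAAAAACC` with at most 3 mismatches;
  spacer 12 or 23 ± 1 nt. The invariants 7+12+9 = 28 and 7+23+9 = 39 define
  the window lengths. The 12/23 rule ties spacer classes to chains: heavy
  V23–(12)D(12)–23J; kappa and sigma V12–23J; lambda-2 V23–12J
  (`chain_rss_classes`, `check_1223`).
* **Genome-specific RSS.** V genes lacking a canonical RSS are rescreened
  against a position frequency profile derived from the canonical hits
  (`derive_rss_profile`). Scoring uses only informative columns
  (information content ≥ 0.5 bits) — spacer columns differ between genes and
  carry no signal — and accepts windows above half the mean training score.
  This recovers moderately divergent signals (e.g. two heptamer mismatches)
  while rejecting destroyed ones.
* **V boundaries.** The coding start is the projection of reference position
  1; the 3' end is the base before the RSS heptamer, searched downstream of
  the CYS codon (window 90 nt). When no RSS is found at all, the end falls
  back to the projected reference tail so the segment still has defined
  coordinates, and the segment is a `missing_RSS` pseudogene. The germline
  CDR3 contribution `germ_cdr3_nt` is the number of nucleotides strictly
  after the CYS codon up to the heptamer.
* **Leader and promoter.** The leader intron is the shortest GT..AG intron
  of 60–200 nt whose acceptor abuts the coding start; the promoter is the
  best octamer (`ATGCAAAT`, both orientations, ≤ 1 mismatch) plus TATA box
  (`TATA[AT]A[AT]`, ≤ 1 mismatch) pair in a 300 nt window, ranked by fewest
  mismatches, then smaller gap, then the 3'-most pair.
* **D and J.** D cores are spans of 6–40 nt flanked by two inward-facing
  intact 12-spacer RSS (a core with one destroyed RSS is not reported unless
  rescue is enabled); because the ±1 spacer slack lets one physical signal
  match at shifted windows, overlapping candidate cores are resolved by
  fewest total mismatches, then smallest spacer deviation, then position.
  J candidates must carry a 5' RSS of the chain's class ending at the coding
  start and an in-frame `[FW]GxG`; candidates without the motif are treated
  as spurious similarity hits and dropped.
* **Functionality.** V: RSS + promoter + no frameshift or internal stop;
  D and J: intact RSS (and no stop for J); C: no frameshift or internal stop
  in the first exon. A stop within the final two codons before the heptamer
  is exempt — such V genes still make functional chains whenever
  recombination deletes at least two nucleotides, and several cod heavy V
  genes have exactly this configuration. After a frameshift the reading
  frame downstream is meaningless, so stop-codon reasons are not added on
  top of a frameshift.

### Organization and nomenclature

Segments sorted by position are grouped greedily: a new unit starts whenever
the kind order V → D → J → C resets or the gap exceeds `cluster_gap`
(20 kb). Units containing D genes or multiple segments of a kind are
translocons; single-V/J/C units are mini-clusters, and a V on the opposite
strand to its J and C (inverted kappa V) stays in its cluster. Heavy V names
are `IGHV<family>-<translocon>-<n>*01` with `n` numbering the family's genes
by position; light-chain V, J and C of one cluster share the cluster
ordinal, a deleted J or C skips its number, and a duplicated gene in a
cluster receives a letter suffix. Names are checked unique.

### Coordinates

All coordinates are 1-based inclusive on the plus strand, the native
convention of IRanges/GenomicRanges and of GFF3 output; minus-strand
features keep `start <= end` with the strand recorded separately.

## Classification model

Families are single-linkage connected components of the pairwise-identity
graph at the 80% threshold (identity = matching columns over aligned
columns of a global affine-gap alignment), labelled by decreasing size and
then leftmost position. Identity is computed on nucleotide coding sequences
by default; an amino-acid mode exists. Distances for phylogenies are
p-distance or Kimura two-parameter with pairwise deletion of gap/ambiguous
sites:

$$d_{K2P} = \tfrac12\ln\frac{1}{1-2P-Q} + \tfrac14\ln\frac{1}{1-2Q},$$

with transition fraction $P$ and transversion fraction $Q$; the
gamma-corrected form $\tfrac a2[(1-2P-Q)^{-1/a}-1] +
\tfrac a4[(1-2Q)^{-1/a}-1]$ is available (the cross-species germline
phylogenies in this field conventionally use shape $a = 5$). Saturated pairs
(non-positive logarithm argument) return `NA` with a warning. `nj_tree` is a
classical Saitou–Nei implementation; tied Q-criterion minima are broken by
the lexicographically smallest pair of clade labels and negative branch
lengths are clamped to zero (the count is kept as an attribute). `ape` is
used for tree representation and as an independent cross-check in the tests,
never as the implementation. Bootstrap support resamples alignment columns
with replacement under one seeded RNG stream (no parallel substreams — the
package never builds trees in parallel) and reports the percentage of
replicates containing each original bipartition.

Entropy profiles report per-column Shannon entropy in bits with gaps
excluded from the distribution; columns with more than half gaps get the
consensus symbol `-`, columns whose plurality residue stays below 0.5 get
`?`. The deterministic center-star multiple alignment (center = sequence
with the highest total pairwise score) backs the entropy and family analyses
when no external alignment is supplied; gap-stripping any row reproduces its
input exactly.

## Repertoire model

Read 1 of the 5'RACE design starts 24–42 bp into the C gene and sequences
the junction 3'→5'; read 2 starts at the V 5' end. The assembler therefore
takes V calls from read 2 and J calls plus the junction from read 1 — with
150 bp reads, read 1 frequently covers too little V sequence for a reliable
V call when the junction is long, which is also why the original study
assigned V genes from the reverse read. Reads are quality-trimmed with a
sliding window (cut at the first 4 bp window with mean quality below 20),
deduplicated exactly (duplicates become abundance; the protocol has no
UMIs), and aligned locally against the germline set with thresholds of 60%
identity over at least 40 nt (V) or 18 nt (J); ties go to the higher
identity and then the lexicographically smaller name. Reads that are exact
germline substrings shortcut the alignment — the exact match already attains
the maximal local score. The CDR3 runs from the 2nd-CYS codon (located with
a 15 nt germline probe ending at the CYS codon) through the J anchor codon
(transferred through the read-to-J alignment; at zero error the untrimmed
post-anchor J tail locates it exactly). Clonotypes collapse on the exact
CDR3 nucleotide sequence with majority V/J voting (weighted by reads, ties
by summed score then name), keep productive junctions only (length divisible
by three, no stop), and discard clonotypes with fewer than 5 reads — exactly
5 is kept. C genes are never used to split clones: cod C genes are too
conserved to distinguish from short reads.

Statistics weight each clonotype once (the unit of analysis is the unique
receptor); read-weighted D50 uses the read counts by construction. Sharing
is computed at the CDR3 amino-acid level by default with classes unique /
shared-by-two / widely-shared (3..n−1 fish) / shared-by-all; replicate
overlap reports Jaccard plus both per-sample containments, since either
denominator is defensible for a "percent shared" figure. Rarefaction
subsamples reads without replacement, is exact at full depth, and is tested
against the closed-form hypergeometric expectation
$E[\text{distinct}] = \sum_c 1 - \binom{N-n_c}{d}/\binom{N}{d}$.

## The synthetic-data generator

The generator's defaults are the study conditions, fixed once:

* **Heavy locus**: three translocons of 18/38/25 V genes (≈ 22%
  pseudogenes), 2/3/3 D, 2 J and 2 C genes each; four V families with sizes
  proportional to 4/6/69/2; two J families with no within-family variation.
  The acceptance checks use the spec-scale variant (3 translocons, 50 V at
  20% lesioned).
* **Light loci**: sigma = 14 plus-strand mini-clusters with inter-cluster
  gaps drawn uniformly from 375–3,298 bp; kappa = mini-clusters with 95%
  inverted V genes, two families (the small forward-oriented one), gaps
  712–9,573 bp; lambda-2 = 4 clusters with one J gene whose anchor lies six
  nucleotides later than the rest.
* **Junction model**: geometric deletions at every coding end (heavy mean
  3 nt/end, light 0.5), Poisson N additions (heavy mean 1.5/junction, light
  0), palindromic P additions of ≤ 2 nt with probability 0.5 at untrimmed
  ends, lognormal(0, 1.5) clonal abundances. No somatic hypermutation,
  matching cod biology; sequencing error is a flat per-base substitution
  rate (0 by default).
* **Germline CDR3 lengths**: heavy V tails concentrate at 15 nt with 4%
  each at 12 and 18 nt; kappa tails are bimodal 18/24 nt; sigma uniform
  18 nt; lambda-2 uniform 15 nt. D cores span 6–24 nt (mean 15). Tail and D
  lengths are dealt from balanced shuffled pools, so the locus composition
  is stable across seeds. Together with the heavy J anchor at codon 5
  (15 nt contribution) these choices reproduce the study's observed
  repertoire structure: mean heavy CDR3 near 13.3 amino acids, a
  near-perfect germline-to-expressed length correlation for kappa
  (r ≈ 0.93–0.96: the bimodal germline lengths dominate the ≈ 0.5 nt of
  junctional noise) and a near-zero correlation for heavy chains
  (r ≈ 0.05–0.15: ≈ 8 nt of junctional standard deviation swamps the ≈ 1 nt
  germline spread), the strong JH1-over-JH2 usage bias (7.6:1 between
  families), and steep rank-abundance curves with D50 in the 2–10% range.
* **Lesions**: a lesioned V receives exactly one defect — internal stop
  (30%), 1 nt frameshift (30%), destroyed RSS (20%), destroyed promoter
  (10%), broken splice acceptor (10%) — recorded in the truth table so the
  annotation's pseudogene reasons can be compared one-to-one. Functional V
  genes optionally carry the terminal-stop configuration (7% for heavy
  chains). An RSS-lesioned V keeps its family's reference tail length so
  that even its fallback 3' coordinate is well defined.

Two generator choices trade realism for testability, deliberately:
intergenic filler is scrubbed of motif seeds (`CACAG`, `CTGTG`, octamer and
TATA cores) and leader introns of internal `GT`, so that the planted truth
is the unique solution of the motif rules; and within-family V variants
diverge by substitutions only (5% per base), so reference-projection
arithmetic is exact. Real data contain decoy motifs, indel polymorphism and
allelic variation that these simulations do not probe — passing the planted
tests shows the rules are implemented correctly, not that their defaults are
optimal for every genome. The e-value tiers, tolerances and windows are all
configurable through `annotation_config`.

## Problem sizes and numerical choices

The shipped checks run at desk scale, chosen to keep the whole suite in a
few minutes while leaving the statistics sharp: motif-scanner equivalence on
100 × 10 kb random sequences; locus recovery on the 50-V heavy locus and the
14-cluster sigma locus; end-to-end repertoire recovery at 1,000 clones /
50,000 read pairs with zero sequencing error; the heavy/light correlation
contrast over 10 seeds at 10,000 clones per seed (sampling error of r about
0.017, so the near-zero heavy correlation stays clearly inside |r| < 0.2);
neighbour joining on 1,000 random additive 4–8 taxon matrices. Deterministic
tie-breaks appear wherever order could leak in: lexicographic germline names
in calls, CDR3 sequence in D50 ranking, smallest label pair in NJ merges,
leftmost candidates in annotation merges. All generators and resampling
procedures take explicit seeds and are bit-reproducible.

## Known limitations

C genes are annotated by their first exon only; full exon-chain
reconstruction (e.g. the IgM/IgD alternative-splicing structure) is out of
scope. Read pairs are not stitched into full-length receptors — with 150 bp
reads the whole V region cannot be reconstructed anyway. The aligner has no
hypermutation-aware scoring (irrelevant for cod, relevant for species with
active AID). Reproducing the published Atlantic cod numbers requires the
gadmor3.0 assembly and the deposited read data; `benchmark_targets()`
declares those quantities and tolerances without shipping the data.
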
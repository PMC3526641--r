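---
title: "Methods: characterizing germline small-RNA libraries with srnakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing germline small-RNA libraries with srnakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`srnakit` reimplements, at desk scale, the computational workflow used to
characterize small-RNA sequencing libraries from germline tissue: an
ovary-derived library dominated by miRNAs (length mode at 22 nt), a
testis-derived library with a bimodal 24/27 nt profile, a large
repeat-associated fraction and a 5'-uridine bias typical of
rasiRNAs/piRNAs, and a library of small RNAs co-purified with a PIWI-family
protein by immunoprecipitation (24--25 nt peak, miRNA-depleted). Because no
real sequencing data is bundled, the package pairs every analysis stage
with a synthetic-data generator that emits reads with known ground truth,
so each statistic can be verified against the planted parameters.

The stages are: cleaning (adapter trimming, contaminant and quality
filtering, length selection), collapsing identical reads into unique
families, exhaustive exact-match mapping on both genome strands, one
category per read via a priority cascade, isomiR clustering and miRNA
cataloguing with exact count-based differential expression, rasiRNA
candidate profiling (positional base composition, chromosome-normalized
abundance, sliding-window densities), and cloning-support computations
(ORF/translation, protein MW and pI, UPGMA trees).

# The synthetic world

The generator's defaults are a stated world, fixed once:

* **Genome**: five chromosomes (300, 200, 150, 120, 80 kb; the last two
  play the roles of Z and W), i.i.d. bases at 42% GC. Real genomes have
  repeats with shared sequence; an i.i.d. genome does not, so simulated
  reads map almost always to a single locus. The 1--5 locus multimapping
  filter is therefore exercised by constructed fixtures in unit tests, not
  by the simulation.
* **Annotation**: interval counts and length ranges per category (rRNA,
  tRNA, snRNA, snoRNA, miRNA hairpins with embedded matures, LINE, LTR,
  satellite, other repeats, exons). Repeat intervals are placed with
  per-chromosome weights (default 55% of weight on chrW, 25% on chrZ),
  emulating the concentration of repeats on the female sex chromosome;
  about 8% of the genome is annotated repeat.
* **Libraries**: each archetype fixes a length mixture over 18--32 nt, a
  source-category mixture, a 5'-U bias, isomiR end-offset probabilities
  (0.6 canonical, 0.15 per +/-1, 0.05 per +/-2 at each end), and
  contamination rates (2% adapter dimers, 3% low-quality reads). The
  testis-like category mixture plants a 36% repeat fraction; the IP-like
  mixture approximates the reported ~12.5% repeat / 15% exon / dominant
  single-hit unannotated composition. Values live in a versioned JSON
  config (`inst/extdata/archetype_defaults.json`).
* **Intergenic (unannotated) reads** are placed on chromosomes with
  probability proportional to annotated repeat bases (plus a 5% floor) at
  positions rejected against all annotated intervals. This is the
  package's model of the real situation in which unannotated germline
  small RNAs arise from incompletely annotated repeat-rich regions: it
  yields an unannotated compartment that is genuinely unannotated under
  the cascade yet concentrates on the repeat-rich chromosome, reproducing
  the "highest length-normalized density on chromosome W" observation.
* **5'-U bias** is the *marginal* probability that a repeat- or
  intergenic-derived read starts with uridine. The generator draws a
  Bernoulli(bias) indicator and then places the read at a position whose
  strand-aware 5' base matches the indicator, so reads still map back to
  the genome exactly.

A green archetype-recovery test therefore establishes that the pipeline
measures what the generator planted; it does not establish anything about
real chicken or quail libraries, whose reads were never deposited.

# Numerical and procedural choices

* **Coordinates.** In memory the package uses `GRanges` (1-based, closed),
  the Bioconductor convention; all BED/bedGraph files written or read are
  0-based half-open as the formats require. Using the native convention of
  the host ecosystem, with conversion confined to the I/O layer, was judged
  less error-prone than forcing 0-based arithmetic through R containers.
* **Cleaning.** The 3' adapter is located by exact match of its first 8 nt;
  reads without a match are kept untrimmed if already inside the length
  window. Discard order: empty insert or N-containing (contaminant), mean
  Phred < 20 (low quality), then length. An insert can contain the 8-mer
  key by chance (~5e-4 per read) and be over-trimmed; this is inherent to
  prefix-match trimming and is accounted for in the truth-reconciliation
  test.
* **Mapping** is exact (0 mismatches), all loci on both strands, backed by
  `Biostrings::matchPDict` per read-length group and verified against an
  independent `gregexpr` scan. Minus-strand hits are reported in
  plus-strand coordinates of the matched substring. A reverse-complement
  palindrome yields one hit per strand.
* **Cascade.** Priority rRNA > tRNA > snRNA > snoRNA > miRNA > LINE > LTR >
  satellite > other repeat > exon > intron. ncRNA/miRNA/exon/intron
  overlaps require the same strand; repeat overlaps are strand-agnostic
  (rasiRNAs arise from bidirectional repeat transcription). Overlap is >= 1
  nt; a multi-locus read is annotated from the union of its hits. The
  assignment is provably invariant to track order (minimum rank over all
  overlaps).
* **isomiR reference**: most abundant member by total count, ties to the
  lexicographically smallest sequence. A read overlapping two matures goes
  to the larger overlap (tie: hairpin order) and is logged.
* **Seven groups.** The original grouping is names-only in its source; the
  decision table here (exact mature = gp1a; on-hairpin mature-overlapping
  variant = gp1b; <= 2 nt 3'-shifted mature without hairpin = gp2a;
  antisense = gp2b; same-arm non-mature = gp3a; loop/star arm = gp3b;
  otherwise candidate novel = gp4a) is a documented reconstruction, with
  arm defined by the hairpin midpoint.
* **Differential expression.** The Audic--Claverie conditional law of `y`
  given `x` is negative binomial with size `x + 1` and success probability
  `N_A / (N_A + N_B)`; tails are computed by `pnbinom` in log space. The
  published two-sided construction (twice the smaller tail, conditioning on
  the first library) is *not* exactly symmetric under swapping the two
  libraries when their depths differ — the two orientations differ by a
  one-unit shift in the regularized-beta arguments. Since swap symmetry is
  part of this package's contract, the two-sided p is `min(1, 2 * min)` of
  the four tails from both orientations, which is symmetric by construction
  and identical to the two-tail rule when depths are equal. Normalization
  is counts per million of total clean reads (configurable); multiplicity
  is Benjamini--Hochberg. Underflowing p-values are clamped to the smallest
  positive double so the `(0, 1]` contract holds.
* **rasiRNA candidates**: length in [23, 32], category unannotated, 1--5
  loci. In the default pipeline cleaning occurs at [18, 30] first (the two
  windows of the protocol are applied in sequence, not re-cleaned), so
  end-to-end candidates effectively span 23--30 nt; analyses that need the
  full window clean at [18, 32] explicitly. Reads enter a window by their
  strand-aware 5' end; multi-locus reads are weighted 1/n_loci everywhere
  (no double counting). Windows anchor at 0, advance by `step`, and the
  final partial window is truncated and flagged. Base-composition rows are
  computed over unique reads, unweighted by copy number, and reported in
  the RNA alphabet.
* **Feature densities** (50 kb window / 1 kb step by default) are merged
  base-coverage fractions; **read densities** (5 kb / 100 b) are windowed
  weighted 5'-end counts — the "moving average" of the original display is
  implemented as a windowed count, the averaged quantity being ambiguous in
  its source.
* **ORF/protein.** Longest forward-strand ATG-to-stop span over three
  frames (cDNA is oriented; ties to the leftmost start); the protein
  excludes the stop. A trailing poly(A) run (>= 10 A) is excluded from the
  3' UTR length. Molecular weight uses average residue masses plus one
  water (18.02 Da), matching the "relative molecular mass" convention; pI
  is found by bisection (tolerance 1e-4 pH) on the strictly decreasing
  Henderson--Hasselbalch net charge, with EMBOSS pKa values by default and
  a Bjellqvist-style table selectable — published pI values differ by
  0.1--0.3 between tables, which bounds the interpretability of any single
  number.
* **UPGMA.** Closest pair merged at height d/2; distances updated by
  size-weighted arithmetic means; ties broken by the lexicographically
  smallest pair of cluster representative labels and children ordered by
  representative, so the Newick output is invariant under input row
  permutation. Output is ultrametric by construction and checked
  (root-to-leaf spread < 1e-9); on an ultrametric input matrix the
  cophenetic distances of the result reproduce the input exactly. Distances
  from aligned proteins are uncorrected p-distances over ungapped columns.

# Known limitations

* The i.i.d. genome produces essentially single-locus reads; multimapping
  behaviour is tested on constructed fixtures only.
* Sequencing error is modelled only as whole-read low quality; there are no
  per-base miscalls, so cleaned reads always map.
* Group labels gp2a/gp2b/gp4a rarely occur on the default world (its
  reference sets are complete by construction); they are exercised by
  targeted fixtures.
* Library-level figures from the motivating study (read totals, clean-read
  percentages, Table-1-style counts) are not reproducible from code because
  the underlying data was never deposited; no test asserts them.
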
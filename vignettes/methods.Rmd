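---
title: "Methods: stranding, artifact detection and strand-aware merging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stranding, artifact detection and strand-aware merging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tassel)
```

## The problem

Oxford Nanopore direct- and PCR-cDNA sequencing reads either strand of the
double-stranded cDNA molecule, so the read set carries no strand-of-origin
information. Aligners then map a large fraction of reads to the wrong strand
and assemblers emit transcript models on the wrong strand or split across
strands. A second, subtler problem arises during first-strand synthesis:
the reverse transcriptase can switch template onto its own nascent strand,
producing a *palindromic* read — one half the reverse complement of the
other — that aligns twice at one locus (once as a supplementary alignment)
and inflates coverage and abundance estimates.

This package implements the computational remedies end to end: SLURP
(stranding from primer evidence), a palindrome-artifact detector and
supplementary-alignment filter, TASSEL (strand-aware merging of short-read
and stranded long-read transcript models), the evaluation metrics used to
benchmark these steps, and a seeded simulator providing ground truth.

## Stranding from primer evidence (SLURP)

During library preparation, primer 1 (polyT-ended) primes first-strand
synthesis and primer 2 (GGG-ended) primes the strand-switched second
strand. A read presenting the first strand therefore begins with primer 1
and ends with the reverse complement of primer 2; a second-strand
presentation begins with primer 2 and ends with the reverse complement of
primer 1. Reads are classified by searching the terminal windows (default
100 bp at each end, keeping coincidental interior hits out of scope) for
approximate primer occurrences within a 2-mismatch budget:

* `P1_HEAD` — primer 1 in the head window: first-strand presentation, kept
  as-is;
* `RC_P2_TAIL` — reverse complement of primer 2 in the tail window: also
  first-strand, kept;
* `P2_HEAD` — primer 2 in the head window: second-strand, emitted
  reverse-complemented;
* `RC_P1_TAIL` — reverse complement of primer 1 in the tail window
  (4-criteria mode only): second-strand, reverse-complemented.

Criteria are evaluated in that fixed precedence order; the first satisfied
criterion decides, conflicts (criteria of both orientation classes firing,
as on palindromic reads) are counted and reported rather than silently
resolved, and the union of branch outputs is deduplicated by read id with
first-wins survivorship. The default is the 3-criteria configuration
(without `RC_P1_TAIL`), which balances yield against correctness; the
4-criteria variant is available. Unstranded reads are dropped — the yield
loss is the price of a consistently oriented library.

### Matching metric

The default metric is **edit distance** (substitutions, insertions and
deletions each costing 1, budget 2 on a 14-mer), with a pure substitution
(Hamming) mode available via `primer_config(metric = "hamming")`. The
choice is deliberate: nanopore basecalls are indel-rich, and at a 3%
per-base indel rate the probability that a 14-base primer region contains
no indel is only about 0.65. A substitutions-only scan therefore misses
roughly a third of true primer occurrences, which matters most where both
ends of a read must be recognised (the artifact screen below). The Hamming
mode is retained because it admits a simple exhaustive oracle, against
which the implementation is tested, and is marginally faster. Matching is
implemented as minimum-cost-first passes (cost 0, 1, 2) so the best hit
minimises mismatches with ties broken by smallest offset; `N` bases never
match a primer base.

### Orientation conventions

The emitted library is uniformly oriented: every read is p1-headed (or the
global reverse complement of that, with `output_orientation =
"first_strand"`). Whether that orientation is sense or antisense to the
mRNA is a property of the kit chemistry that the partial primer sequences
do not determine, so the package fixes an internal convention instead of
guessing: the simulator renders the second-strand presentation as
`p2 + sense + rc(p1)` (the strand-switch primer's GGG end leads the
sense-oriented second strand), which makes SLURP's default p1-headed
output antisense to the source transcript *in simulator coordinates*. The
default output keeps the name `second_strand` after the method's own
nomenclature, and `evaluate_stranding()` derives the expected presentation
from the requested orientation, so every accuracy statement in the package
is about internal consistency, not about kit biochemistry.

## Palindrome artifact detection

A template-switch palindrome carries primer 1 at its head *and* the
reverse complement of primer 1 at its tail — a geometry the chemistry
cannot produce from an intact template — and its second half mirrors its
first. The detector requires both lines of evidence:

1. **Terminal primer pair** — approximate matches of p1 (head) and rc(p1)
   (tail), each within the mismatch budget.
2. **Self-complementarity** — the first half of the read is globally
   aligned (match +1, mismatch −1, gap −2) against the reverse complement
   of the second half; every aligned match column pairs its two read
   positions, written as `(` and `)` in a dot-bracket string. Because the
   alignment is monotone, the pairing is always balanced and nested. The
   *paired fraction* is the fraction of bases paired; a read is called an
   artifact when it has the terminal primer pair and paired fraction at
   least 0.7.

The alignment construction replaces thermodynamic secondary-structure
prediction, which answers a more detailed question than needed here: for
palindrome detection only the extent of self-complementarity matters, the
alignment is O(n²) rather than O(n³), and it provably yields nested
pairings. The 0.7 threshold was calibrated once against the simulator's
nulls and signals: uniform-random reads align their halves at a paired
fraction near 0.55 and never reached 0.7 in the calibration runs, while
simulated palindromes at 6% total base error stay above 0.8; the threshold
sits between the two populations and is exposed as a parameter. The
*mountain profile* (+1 per `(`, −1 per `)`, 0 per `.`, cumulated and
averaged into 100 equal-width position bins) summarises where pairing
concentrates: palindromes produce a triangular mountain peaking
mid-read, at half the read length for a perfect palindrome.

Aligned palindromes map twice at one locus, with one record flagged as a
supplementary alignment (SAM flag bit 2048). `filter_supplementary()`
removes those records, and `coverage_profile()` (depth over
reference-consuming CIGAR blocks; deletions covered, introns not)
quantifies the effect — depth halves wherever the read mapped twice.

## Strand-aware merging (TASSEL)

TASSEL consolidates a quantitatively deep short-read assembly with a
qualitatively long stranded long-read assembly. The merge is defined by
explicit rules applied within connected components of same-chromosome,
same-strand exonic overlap (strand awareness is the method's point:
opposite strands never interact, and `.`-strand models merge only among
themselves), iterated to a fixed point:

1. multi-exon transcripts with identical intron chains collapse to one
   model spanning their extremes;
2. a transcript whose intron chain is a contiguous sub-chain of another's,
   with its span contained, is absorbed by the longer model;
3. a mono-exon transcript contained in an exon of another retained
   transcript is absorbed;
4. mono-exon transcripts overlapping by at least `mono_overlap_frac`
   (default 0.3) of the shorter merge transitively into their union span.

The 0.3 fraction sits between two failure modes: any-overlap merging fuses
adjacent genes, while containment-only merging leaves fragmented models
unrepaired. Output identifiers (`TSL.<n>`) are regenerated in genomic sort
order, making the merge independent of input order; each output records
its contributing inputs (`sources`) and whether two or more inputs agree
(`consensus`), and carries the best supporting input coverage as its
`cov`.

**Stringency.** The `min_cov` parameter mirrors an assembler's
minimum-read-count option: a merged model is reported when its best
supporting input transcript has coverage at least `min_cov`. Applying the
threshold to merged models rather than pre-filtering the inputs was a
deliberate design choice: pre-filtering can *remove a bridging model and
split a merged cluster in two*, so the output count would not fall
monotonically with stringency; thresholding the consolidated models keeps
the sweep monotone and keeps every model's full support visible. The plain
input filter is available separately as `filter_by_coverage()`.

This rule set repairs fragmentation and truncation but deliberately does
not *stitch* partial intron chains into longer novel chains — a merged
multi-exon model always has the intron chain of one of its inputs.

## Evaluation metrics

Assemblies are scored against a reference with gffcompare-style class
codes (`=`, `c`, `k`, `j`, `o`, `s`, `i`, `u`, in that precedence; the two
antisense codes are collapsed into `s`, and codes the benchmarks do not
use are out of scope). Multi-exon equality is intron-chain identity;
mono-exon equality requires reciprocal overlap of at least 0.8, a recorded
and configurable choice since the canonical tool's mono-exon criterion is
not fully published. Transcript-level sensitivity is the fraction of
reference transcripts matched `=` by some query, precision the fraction of
queries coded `=`. Loci are connected components of same-strand exonic
overlap; a locus is detected when any query overlaps it exonically on the
same strand. Transcript end quality is measured as signed distances from
each query TSS/TTS to the nearest same-strand reference end, with
cumulative fractions within 50/100/500/1000 bp. Segmentation is counted on
gene models versus consolidated spans: an original gene is segmented when
its consolidated span also captures another original gene; the
before/after comparison consolidates each annotation together with the
truth so that fragments of one true transcript count as segmented before
merging and a repaired model does not after.

## The simulator

The simulator is the package's ground truth and defines the study
conditions. It emulates an ONT direct-cDNA chromatin-RNA-like experiment:

* a uniform-random 2 Mb genome carrying 200 non-overlapping genes (1–8
  exons; kilobase-scale spans for mono-exon genes, mimicking unspliced
  chromatin-enriched transcripts; optional second 5'-truncated isoform
  sharing the remaining introns) with log-normal expression (meanlog 1,
  sdlog 1);
* a 92-transcript mono-exonic spike-in ladder, each transcript its own
  contig, lengths 250–2000, concentrations doubling every group of four —
  the standard external-control design with a 2-fold abundance ladder;
* reads drawn proportionally to expression/concentration, full length with
  probability 0.6 or 3'-anchored truncated (a Geometric prefix of mean
  300 bp removed from the 5' end, the polyA end always retained, mirroring
  the 3' coverage bias of cDNA long reads); a 20-base polyA tail; primer
  decoration per the rendering convention above; 50/50 strand
  presentation; i.i.d. per-base errors at 3% substitution, 1% insertion,
  2% deletion (~6% total, nanopore-like); and, in direct-cDNA mode, a 6%
  palindrome-artifact rate — the prevalence observed in direct-cDNA
  libraries — realised as a first-strand rendering concatenated with its
  own reverse complement. Direct-RNA mode emits bare sense fragments with
  no primers and no artifacts;
* paired assembly fixtures: a "short-read-like" GTF with transcripts split
  into gapped (≥100 bp), end-trimmed (50–200 bp) fragments at probability
  0.6, and a "long-read-like" GTF with 5'-truncation at probability 0.5
  and a 7% strand-flip fraction, the proportion of wrong-strand models
  seen in unstranded long-read assemblies.

All generators are pure functions of the configuration seed and are
bit-reproducible. What the simulator does **not** model: homopolymer-
dependent errors, quality-score structure, chimeric (non-palindromic)
fusions, expression-dependent truncation, overlapping genes and antisense
transcription, and genome repeats. Passing tests therefore demonstrate
the methods' internal correctness and their behaviour under idealised
nanopore-like noise, not performance on any particular real library.

## Problem sizes and numerical choices

The package's own acceptance checks run the full pipeline on 20,000
simulated reads from the spike-in ladder (stranding accuracy and artifact
recovery) and merge fixtures of 50–200 genes — sizes at which every check
completes in minutes on one CPU while keeping binomial noise on a 6%
prevalence below half a percentage point. Degenerate inputs are defined,
not errors: empty read sets strand to empty libraries with rate 0,
`restrand_check` reports fraction 1 with an explicit zero count, empty
transcript sets compare with a zero-denominator flag, and odd-length reads
leave their middle base unpaired in the fold. Coordinates are 0-based
half-open internally and 1-based inclusive on disk, converted only at the
GTF boundary.

## Known limitations

* The stranding criteria assume the two kit primers; other chemistries
  need their primers supplied in the configuration.
* Palindrome detection flags whole reads; it does not split a palindrome
  back into its true half.
* The merge does not re-estimate abundance on the merged models and does
  not invent intron chains absent from its inputs.
* Sense/antisense labelling relative to the mRNA is a convention (see
  above); the `first_strand` flip is provided for pipelines that need the
  opposite orientation.
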
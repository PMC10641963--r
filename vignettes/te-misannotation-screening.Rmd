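---
title: "Screening and structural curation of misannotated transposable elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening and structural curation of misannotated transposable elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tescreen)
```

## The problem

Gene-prediction pipelines lean heavily on homology, and a transposase is a
perfectly respectable protein.  When a host gene has exapted a
transposase domain — as the mammalian transcription factor GTF2IRD2/2A
has exapted a Charlie8-like (hAT superfamily) element — every
free-standing copy of a related DNA transposon becomes a candidate
"gene", and annotation sets accumulate transcription factors that are in
fact mobile elements.  `tescreen` implements the three procedures needed
to quantify, curate and prevent this failure mode, together with a
synthetic-genome generator that provides ground truth for all of them.

This vignette records the package's methodological choices: the models
and rules, the tunable parameters and why their defaults are what they
are, what the generator does and does not emulate, and the numerical
conventions (tie-breaks, guards, calibrations) that make results
reproducible.

## Containment screen

A repeat annotation and a gene model overlap in many harmless ways; the
signature of a *misannotated* TE is a repeat that lies **entirely inside
coding sequence**.  `contained_overlaps()` therefore emits one event per
(repeat, CDS interval) pair whose overlap covers at least
`min_te_fraction` of the repeat, with 1.00 — full containment — as the
default.

Three semantic decisions matter here:

* **Containment is tested against individual CDS intervals, not the
  spliced CDS union.**  Interval files are flat; a TE spanning an intron
  of a two-exon gene is not 100% contained in any single CDS record and
  is deliberately not reported at `f = 1.00`.  The generator's `spliced`
  option builds exactly this decoy to keep the rule honest.
* **Strand is ignored by default** (`strand_aware = FALSE`): containment
  of the annotation is a coordinate property, and a plain interval
  intersection carries no strand constraint.
* **Simple repeats are excluded** (`Simple_repeat`, `Low_complexity`
  classes) because microsatellites inside codons are commonplace and are
  not misannotation; `exclude_simple_repeats = FALSE` restores them.
  Records flagged as overlapped by a higher-scoring repeat hit are
  retained, as raw genome-browser RepeatMasker tracks retain them.

Events are sorted by (sequence, start, repeat name, gene, transcript) so
reports are byte-identical across runs.  `summarize_by_class()` keeps the
`Class/Family` granularity and rolls up to class 1 (LINE, SINE, LTR,
Penelope-like retroelements) versus class 2 (DNA transposons, including
rolling-circle elements).  `select_review_sample()` retains loci whose
repeat is *strictly* longer than 1000 bp — long enough that a contained
copy plausibly carries ORF remnants worth manual review — deduplicated to
one event per gene.

The implementation delegates interval intersection to
`GenomicRanges::findOverlaps()`; the test suite holds it to exact
agreement with an all-pairs brute-force oracle on hundreds of random
instances, at both `f = 1.00` and `f = 0.5`.

## Structural curation of hAT candidates

`curate_element()` automates the classical manual test for an autonomous
hAT DNA transposon.  The verdict rule is a strict conjunction:

> **autonomous** ⇔ TSD present ∧ TIR present ∧ ORF ≥ `orf_min_aa`
> ∧ all five DDE/RW residues found.

If the conjunction fails but at least one structural feature is present —
a TIR, a TSD, or an ORF with substantial catalytic homology — the element
is `partial_non_autonomous`; otherwise `not_te`.  "Substantial catalytic
homology" is defined as at least three of the five residues anchoring
(a majority of the catalytic machinery), a package decision where the
underlying procedure is qualitative.

### Parameters and defaults

| parameter | default | rationale |
|---|---|---|
| `flank_bp` | 1000 bp | flanks extended 1000 bp where possible before searching, clipped at chromosome ends |
| `tsd_len_range` | (8, 8) | 8-bp TSDs are the hAT hallmark; widen for other superfamilies |
| `tsd_max_mismatch` | 0 | a TSD is by origin an exact duplication; divergence tolerance is opt-in |
| `tsd_search_window` | 20 bp | TSDs abut the element; a short window bounds false pairing |
| `tir_min_len`–`tir_max_len` | 10–30 bp | brackets known hAT TIR lengths |
| `tir_search_window` | 50 bp | TIRs are terminal; the window allows modest boundary error in the input locus |
| `tir_max_mismatch_frac` | 0.15 | accepts diverged TIR pairs while bounding the search |
| `orf_min_aa` | 300 aa | deliberately permissive: hAT transposases are substantially longer |
| `min_entropy` | 1.0 bit/base | low-complexity guard (below) |

### Numerical conventions

* **TIR scoring and ties.**  Candidate pairs (prefix, suffix) are scored
  `matches − mismatches` under the mismatch-fraction cap; ties prefer the
  longer pair, then the 5′-most (smaller start offset, then smaller end
  offset).  The search is exhaustive over all offsets and lengths within
  the windows (implemented as per-shift cumulative-sum scans; the test
  suite checks exact agreement with a direct triple-loop search).
* **TSD preference.**  Among qualifying direct-repeat pairs, the pair
  abutting the element boundaries wins (smallest total gap), then the
  longer, then the fewer-mismatch pair.  When a TIR pair is available its
  outer edges define the boundaries.
* **Low-complexity guard.**  Any TIR/TSD candidate whose sequence has
  Shannon entropy below 1.0 bit/base is rejected.  Without it, poly-A
  tracts pair with themselves and produce confident nonsense.
* **ORF finding** is a deterministic six-frame stop-to-stop scan: within
  each stop-bounded segment the call runs from the first ATG to the
  segment end; codons containing ambiguity letters translate to `X` and
  never initiate.  Using an internal finder instead of an external gene
  predictor removes an unreproducible dependency; the cost is that
  GENSCAN-style composite gene models are out of scope, which is
  appropriate for single-ORF transposase detection.  Calls shorter than
  `orf_min_aa` are retained and flagged so the classifier, not the
  finder, applies the intactness threshold.
* **DDE/RW anchoring.**  "Search for the catalytic residues" is made
  deterministic by global alignment (BLOSUM62, affine gaps 10/0.5) to a
  *marked reference transposase* whose D, D, E, R, W coordinates are
  part of the object.  A residue is found iff the aligned query letter
  equals the expected letter at the marked column.  The packaged
  reference is a synthetic peptide (constant, hAT-like residue spacing);
  it is not a natural transposase, and users curating real loci should
  supply one (e.g. a Charlie/hAT transposase) via
  `transposase_reference()`.  Aligning the reference to itself recovers
  the marked coordinates under any scoring scheme, which the suite
  asserts.
* **TIR conservation and identity.**  `tir_conservation()` left-anchors
  equal-orientation TIRs (3′ TIRs are reverse-complemented), pads to
  equal length, and reports per-column base frequencies with a
  majority-rule consensus; ties become IUPAC ambiguity letters.
  `pairwise_identity_matrix()` computes
  `100 × matches / columns where neither sequence is gapped` on
  pre-aligned input — gap columns carry no identity information.

## Homology screen

The final-step filter translates each gene model's spliced CDS
(strand-aware; trailing partial codons trimmed with a warning; internal
stops permitted and counted, since TE-derived "genes" often contain them)
and locally aligns it against every peptide of a TE protein library
(BLOSUM62, affine gaps 11/1, best hit per gene × peptide pair).

The screen runs at **protein level** because transposase homology
persists at protein level across far deeper divergence than DNA-level
similarity, and a misannotated gene model is by construction a protein
prediction.

The flagging cutoff is **calibrated, not asserted**: for each gene, its
translated CDS is shuffled 1000 times (preserving length and
composition), each shuffle is aligned against the library, and the 99th
percentile of the best-hit null scores becomes that gene's cutoff.  A
flag therefore means the alignment score is unattainable by composition
alone at the 1% level.  The calibration is seeded and deterministic.  A
fixed `cutoff` can be supplied to bypass calibration.  Note the
calibration targets a ~1% per-gene false-flag rate by construction;
observed rates on small gene sets fluctuate accordingly.

## The synthetic genome generator

`simulate_genome()` emulates the inputs the analyses expect:

* background sequence i.i.d. at `gc_content` (default 0.41,
  vertebrate-like);
* elements implanted as `[TSD][TIR]core[revcomp(TIR)][TSD]` with
  identical 8-bp TSD copies and 15-bp TIRs by default; autonomous cores
  carry an ATG-initiated 600-aa transposase ORF whose D, D, E, R, W
  positions are recorded in the truth table, truncated cores a 400-bp
  stretch that cannot encode one; element strands are random;
* uniform point mutations applied to each inserted block at
  `mutation_rate` after construction, with the realized per-element
  divergence written into the `.out` divergence column so the annotation
  file is self-consistent;
* gene models: `n_misannotated_genes` single-CDS genes strictly
  containing an element, frame-compatible with the transposase ORF where
  one exists (so the translated CDS genuinely contains the transposase —
  the realistic misannotation); the remaining genes are TE-free coding
  genes; the `spliced` option adds the intron-crossing decoy; `(TA)n`
  simple-repeat tracts exercise the exclusion rule, one inside a TE-free
  gene's CDS when possible;
* everything deterministic given `seed`: equal seeds give byte-identical
  files.

Two construction details guarantee that the truth tables are
*unambiguous* rather than merely correct.  Implanted TSDs and TIR seeds
are resampled until their entropy clears the detector's low-complexity
guard with margin (a degenerate hallmark sequence would be undetectable
by design, not by defect).  And the five base pairs just inside the TIRs
are forced non-complementary, so no extended TIR candidate can tie or
outscore the implanted one under the mismatch budget — without this, a
quarter of simulated elements would, by chance, support a TIR call one
or two bases longer than the implanted truth, and coordinate-exactness
checks would measure coin flips instead of the detector.

What the generator does **not** emulate: isochore structure, nested or
bursting insertions, TE age distributions, assembly gaps, UTRs and
alternative transcripts.  Tests passing on this generator show the
detectors recover the structures they target under clean and uniformly
mutated conditions; they do not certify performance on real genomes,
where boundary ambiguity and nesting dominate the difficulty.

## Recovery under divergence: what the numbers mean

On unmutated genomes the pipeline is exact: 100% of implanted autonomous
elements are classified autonomous with TSD and TIR coordinates recovered
to the base pair, and no truncated copy is ever called autonomous (the
suite asserts both at 20 autonomous + 10 truncated elements per genome).

Under uniform mutation the autonomous verdict decays *by design*,
because the verdict is a conjunction of fragile evidence:

* the TSD test requires its two 8-bp copies to remain identical
  (`tsd_max_mismatch = 0`), and a pair survives 2% per-site mutation
  with probability only about `0.98^16 ≈ 0.72`;
* a 1803-bp transposase ORF acquires about 1.4 premature stop codons at
  2% mutation (roughly 4% of random substitutions in coding sequence
  create a stop), so the probability that an intact ≥300-aa,
  residue-complete ORF survives is small;
* each catalytic residue must survive untouched at the aligned position.

Multiplying these out predicts recovery in the 10–25% range at 2%
mutation, and the measured value in the acceptance runs (about 17–21%,
60 elements over 3–10 replicate genomes) agrees.  The package reports
this honestly rather than loosening the conjunction: divergence
tolerance is a *parameter* (raise `tsd_max_mismatch`, lower
`orf_min_aa`), not a hidden default.  What remains strict at every
divergence level is the safety property — a copy without a transposase
ORF is never classified autonomous.

## Problem sizes

The shipped tests and the acceptance script use genomes of 120–300 kb
with 6–30 implanted elements, 5–24 gene models, 1000-shuffle homology
calibration, and 3–10 replicate genomes for mutated-recovery rates.
These sizes were chosen so the whole suite exercises every code path at
statistically meaningful scale while remaining comfortable to run on a
laptop; all of them are configuration, not constants.

## Known limitations

* TSD detection reports the *best* direct-repeat pair; at
  `tsd_max_mismatch > 0` on highly repetitive flanks the best pair can
  be a spurious one even when the guard passes.
* The TIR search is windowed (50 bp from each end by default); elements
  whose boundaries are off by more than the window will not recover.
* The homology screen's null model shuffles residues i.i.d.; it does not
  preserve local composition structure (e.g. acidic runs), which can make
  cutoffs slightly liberal for low-complexity proteins.
* The packaged reference transposase is synthetic; verdicts on real loci
  should anchor to a curated transposase of the target superfamily.
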
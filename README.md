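# tescreen

Genome annotation pipelines sometimes predict a transposable element (TE)
to be a protein-coding gene.  The best-documented cascade of this kind
involves hAT DNA transposons annotated as the general transcription factor
GTF2IRD2/2A in non-mammalian vertebrates: the real mammalian gene carries
an exapted Charlie8-like transposase at its C terminus, so homology-driven
gene prediction happily labels free-standing hAT transposons in fish,
reptile and amphibian genomes as "GTF2IRD2-like" transcription factors.
`tescreen` packages the three computational procedures needed to detect,
curate and prevent this class of misannotation, plus a synthetic-genome
generator that makes every stage testable offline.

## What it computes

**1. Containment screen** (`contained_overlaps`).  Given RepeatMasker
annotations and gene models, report every repeat whose span is covered by
a single CDS interval at fraction *f* ≥ `min_te_fraction` (default 1.00 —
full containment, the semantics of
`bedtools intersect -a repeats.bed -b cds.bed -wo -f 1.00`).  Simple and
low-complexity repeats are excluded; per-class summaries roll events up to
class 1 (retrotransposons) vs class 2 (DNA transposons); loci longer than
1000 bp (strictly) are selected for manual review.

**2. Structural curation** (`curate_element`, `curate_loci`).  A candidate
locus is an *autonomous* hAT transposon iff it has:

* a target-site duplication (TSD): direct repeat of length 8 (hAT
  hallmark) flanking the element, found by scanning windows immediately
  outside the element boundaries;
* terminal inverted repeats (TIRs): the highest-scoring prefix/suffix pair
  with `prefix ≈ revcomp(suffix)` (length 10–30, mismatch fraction
  ≤ 0.15, score = matches − mismatches);
* an intact ORF ≥ 300 aa from a deterministic six-frame stop-to-stop
  scan; and
* all five DDE/RW catalytic residues (the transposase DDE triad plus
  conserved R and W), located by global alignment to a *marked reference
  transposase* and accepted only when the aligned query letter matches.

Candidates with some but not all of this evidence are
`partial_non_autonomous`; the rest are `not_te`.  Flanks are extended
1000 bp where possible before searching.  `tir_conservation` summarizes a
TIR family column-by-column and `pairwise_identity_matrix` computes
percent identity over ungapped columns of pre-aligned sequences.

**3. Homology screen** (`screen_gene_models`).  The proposed last-step
annotation filter: translate each gene model's spliced CDS and locally
align it (BLOSUM62, affine gaps) against a TE protein library.  A gene is
flagged when its score reaches a per-gene cutoff calibrated as the 99th
percentile of 1000 composition-preserving shuffles, so flags reflect
order-level homology, not amino-acid composition.

**4. Synthetic genomes** (`simulate_genome`).  Implants
`[TSD][TIR]core[revcomp(TIR)][TSD]` elements — autonomous copies carrying
a 600-aa transposase ORF with recorded catalytic positions, truncated
copies without one — into an i.i.d. background, builds gene models whose
CDS fully contain some elements, and emits FASTA, RepeatMasker `.out`,
GFF3 and truth tables, byte-identical for equal seeds.

## Worked example

```r
library(tescreen)

cfg <- sim_config(genome_length = 120000, n_autonomous = 5, n_truncated = 3,
                  n_genes = 6, n_misannotated_genes = 3, seed = 42)
sim <- simulate_genome(cfg)

## which repeats sit entirely inside coding sequence?
events <- contained_overlaps(sim$repeats, sim$genes)
events[, c("seq_id", "te_start", "te_end", "repeat_class", "gene_id",
           "overlap_bp", "te_fraction")]
#>   seq_id te_start te_end repeat_class    gene_id overlap_bp te_fraction
#> 1   chr1     5330   5760      DNA/hAT gene_mis_1        430           1
#> 2   chr1    57302  57732      DNA/hAT gene_mis_3        430           1
#> 3   chr1   102701 104594      DNA/hAT gene_mis_2       1893           1

summarize_by_class(events)
#>   repeat_class category n_events n_genes total_bp
#> 1      DNA/hAT   class2        3       3     2753

## structurally curate one element
te <- sim$truth_elements[1, ]
res <- curate_element(genomic_interval(te$seq_id, te$start, te$end),
                      sim$genome, sim$reference, element_id = te$element_id)
curation_evidence(list(res))[, c("element_id", "tir_len", "tsd_seq",
                                 "orf_len_aa", "residues_found", "verdict")]
#>   element_id tir_len  tsd_seq orf_len_aa residues_found    verdict
#> 1     auto_1      15 TTTTCGGC        600    D1,D2,E,R,W autonomous
```

All three misannotated genes are exactly the genes the generator built
around elements (100% containment, fraction 1.0), and the first implanted
element is recovered as an autonomous hAT: 15-bp TIR, 8-bp TSD, 600-aa
ORF, and all five catalytic residues at the marked positions.

The same workflows are available from the shell via the installed
`tescreen` script (`exec/tescreen`) with subcommands `simulate`, `screen`,
`curate` and `homology`; every run writes a `manifest.yaml` with its
configuration and input digests.

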
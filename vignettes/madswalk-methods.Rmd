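---
title: "Methods: gene-family identification and read-based gene-model completion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family identification and read-based gene-model completion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(madswalk)
```

## The problem

Draft plant genome assemblies routinely carry broken gene models for large
transcription-factor families. For the MADS-box family the damage follows a
recognisable pattern: an annotated protein lacks the N-terminal MADS (M)
domain, lacks the C-terminal half including the keratin-like (K) domain, or
carries a stretch of foreign sequence where its true 5' region should be.
Because type I versus type II membership in this family is *defined* by K
domain presence, such defects corrupt family censuses, phylogenies, and
downstream expression work.

`madswalk` packages a complete, testable workflow around this situation:

1. **Domain scanning** — per-position log-odds profiles for the M and K
   domains, scanned over proteins or six-frame scaffold translations, with
   rule-based type I / type II / non-MADS classification.
2. **Read walking** — iterative extension of an incomplete coding sequence
   with optimally aligned transcriptome reads until no read extends either
   end, recovering the full transcript without whole-transcriptome
   assembly.
3. **ORF completion** — domain-anchored selection of the corrected open
   reading frame, with a before/after report per gene.
4. **Phylogenetic clade assignment** — progressive alignment, cropping to
   well-occupied columns, p-distance neighbor joining with Felsenstein
   bootstrap, collapse of weakly supported edges, and reference-guided
   clade labels.
5. **Cis-element enumeration** — IUPAC degenerate-motif scanning of
   promoters (1.5 kb upstream of the translational start) and introns,
   summarised over nine functional categories.
6. **Relative expression** — the 2^-ddCt method with a housekeeping
   reference gene, pooled-variance t tests, and average-linkage clustering
   of the gene-by-sample log2 fold-change matrix.

Every stage is exercised against synthetic data whose ground truth is
recorded at generation time, so the pipeline's claims are checked by
construction rather than by eyeballing.

## The read walk

The walk is the core algorithm. Reads are indexed by k-mers on both
strands. Given a growing contig, each round takes the terminal stretch of
the contig (one read length), collects all reads sharing at least one
k-mer with it, and anchors each read to the contig by the implied ungapped
offset. A read is accepted when its *optimal* placement — longest overlap,
then fewest mismatches, then smallest offset, a deterministic order —
overlaps the terminus by at least `min_overlap`, mismatches at most
`max_mismatch_rate` of the overlap, and overhangs the contig end.
Accepted overhangs are stacked and a consensus is appended column by
column while each column has at least `min_support` reads and a strict
majority; an exact tie stops that end with reason `ambiguous`. The 5' and
3' ends alternate until both report `no_new_reads`, `ambiguous`, or hit
the iteration/length caps. The 5' round is implemented as a 3' round on
the reverse complement, so both ends share one code path.

Two design points deserve comment:

* **Optimal placement, not all placements.** Anchoring a read at every
  shared k-mer would let short tandem repeats extend a contig without
  bound: a read ending in a repeat unit can always re-anchor one period
  further out. Keeping only each read's best alignment makes a read whose
  best placement is containment contribute nothing, which is exactly the
  behaviour wanted: extension evidence must come from reads that
  genuinely protrude.
* **Stop on ties.** At a paralog branch point the overhang columns
  disagree; the walk stops rather than exploring branches, so each seed
  yields a single deterministic sequence.

Free parameters default to `k = 21`, `min_overlap = 31`,
`max_mismatch_rate = 0.05`, `min_support = 2`, `max_iterations = 200`,
`max_length = 20` kb. They were chosen once so that error-free recovery is
provable on planted transcripts and 1% substitution noise at 30x coverage
is absorbed by the consensus vote; all are user-configurable.

Before walking, `trim_to_read_support()` removes leading and trailing seed
regions covered by no indexed k-mer. This is the package's
operationalisation of "use the optimally aligned reads": a model whose 5'
region is foreign sequence gets no read support there, and without
trimming the foreign terminus would block extension entirely. Interior
coverage gaps are left alone.

**Recovery metric.** Read start positions are drawn uniformly along the
transcript, so the expected number of reads covering the extreme terminal
base is `depth / read_len` — well below one at realistic settings. Full
recovery to the literal first and last base of a transcript is therefore
not a meaningful target; recovery is instead measured as percent identity
of the walked sequence against the corresponding region of the planted
transcript (100% means the walk introduced no erroneous base), and
ORF-level completeness is assessed separately on the defect panel, where
transcripts carry UTRs of at least 60 nt so the start and stop codons sit
in well-covered territory.

## Domain profiles

The M and K domains are modelled as ungapped per-position log-odds
profiles in bits:
`log2(((count + pseudocount) / (N + 20 * pseudocount)) / background)`,
with a uniform 1/20 background and pseudocount 1. This is a deliberate
simplification of full profile HMMs: the two domains are short and well
conserved, insert/delete states add little, and an ungapped profile can be
verified *exactly* against a brute-force window scorer, which the test
suite does. The hit threshold defaults to 60% of the minimum self-score of
the seed rows — an invented but configurable rule; no published cut-off
exists for this family's profiles. Windows containing a stop codon are
invalid, which is what makes six-frame scaffold scanning safe.

The package ships small *synthetic* seed alignments for both domains
(consensus sequences invented for this package, with 10% per-column
noise). The synthetic-data generator plants its domain instances by
drawing from the same seed rows with further per-column noise, which
guarantees planted domains are detectable without tuning, and is the
reason the type I / type II census on synthetic families is exact.

## Phylogeny

Distances are p-distances on the cropped alignment: no substitution-model
correction, partly because the closed form makes correctness oracles
possible (three-taxon branch lengths, additive-matrix recovery, and
agreement with minimum evolution on four taxa are all tested exactly).
Neighbor joining is the classical Saitou–Nei agglomeration with the
standard branch-length formulas; ties in the Q matrix are broken by the
smallest row/column index pair, so the output is deterministic; negative
branch lengths are retained and flagged rather than clamped, since
clamping breaks additive recovery. Bootstrap resamples alignment columns
with replacement (the resampling unit is a column), rebuilds the tree per
replicate, and scores each internal edge by the percentage of replicates
containing the same bipartition; 1000 replicates is the conventional
default, and the test suite uses 100 for speed. Edges *strictly below*
the 50% threshold are contracted into polytomies; an edge at exactly the
threshold is retained.

Clade assignment is deliberately simple: an unlabelled leaf takes the
label of the smallest side of any edge that contains it together with at
least one labelled reference; conflicting reference labels give
`unresolved`. The reference vocabulary is user-supplied.

## Cis elements

The bundled dictionary (`inst/extdata/cis_elements.tsv`) lists IUPAC
consensus patterns for commonly reported plant promoter elements across
nine categories (core promoter, protein binding, hormone response,
tissue-specific, light response, stress response, circadian, cell cycle,
other). The consensus strings are configuration data, not measurements —
users with curated collections should supply their own TSV. The CArG box
is fixed at the standard SRF-site definition `CCWWWWWWGG`. Matching is
exact degenerate matching on both strands; a pattern equal to its own
IUPAC reverse complement is palindromic and reported once per position
with strand `±`, so palindromic sites are never double-counted.
Overlapping occurrences of the same motif at different offsets all count;
no overlap policy beyond that is imposed. Promoters are the 1500 nt
immediately 5' of the translational start on the coding strand, truncated
silently at scaffold edges with the actual length recorded.

## Expression

The 2^-ddCt computation assumes amplification efficiency 2 for every
assay (no Pfaffl correction) and normalises each target to the reference
gene within sample, then to the calibrator sample — by convention the
sample named `leaf` when present. SDs are propagated from replicate-level
dCt values and the per-sample test against the calibrator is a
pooled-variance Student t test; no multiple-testing correction is
applied. Genes without detectable expression surface as flagged rows, are
excluded from clustering, and are listed in the clustering report.
Clustering defaults to 1 − Pearson distance with average linkage —
the common choice for expression heatmaps — with euclidean distance
available; a constant row under correlation distance is an explicit
error rather than a NaN.

## What the synthetic data does and does not emulate

`gen_gene_family()` plants multi-exon genes (4–7 introns for type II,
intronless type I, one gene per scaffold, 2 kb upstream flank) whose
proteins follow the M–I–K–C layout, with clade structure simulated by
deriving members from shared ancestor proteins at 5% substitution noise.
Coding sequences are re-sampled codon by codon, so paralogs that are
similar at the protein level are deeply divergent at the nucleotide
level — which is why reads do not cross-map between clade members and
walk recovery is clean. Real transcriptomes are harsher: shared recent
duplicates, alternative splicing, expression-dependent coverage, indel
errors and quality-score structure are all absent (reads carry a constant
placeholder quality, emitted only for format fidelity). Passing tests
therefore demonstrate algorithmic correctness under the stated model, not
robustness to every pathology of real data. The defect panel mirrors the
documented failure modes — six K-domain losses, seven M-domain losses,
four corrupted 5' regions, seventeen genes in all — with defect lengths
drawn once per panel under a fixed seed.

A note on the defect-mode bookkeeping: pure truncation modes require the
emitted annotation to be shorter than the truth, but field reports include
"lacks the M domain" cases whose annotations are *longer* than the
corrected gene. Those are representable here as `corrupt_5prime` (foreign
prefix replacing the true start), which reproduces the same observable:
no M-domain hit before correction, full-length model after.

## Problem sizes and determinism

The shipped checks run 50-transcript walk panels at 10x and 30x, a
17-gene correction panel, 200-protein scanner-oracle comparisons,
100 additive NJ recoveries, 1000-sequence scanner/regex comparisons and
1000 simulated Ct tables — sizes chosen so the whole suite completes
comfortably on a single CPU while still estimating rates with useful
resolution. Every random stage takes an explicit integer seed, derived
seeds stay below 2^31, and the end-to-end pipeline is byte-reproducible:
two runs with the same seed produce identical files, which the acceptance
suite verifies by hashing.

## Known limitations

* The walk is transcript-space only: it will not jump introns, and
  splice-aware genome walking is out of scope.
* Ungapped profiles cannot model domains with common indels; for the M/K
  domains this is acceptable, for other families it may not be.
* `local_align` is exact dynamic programming, not a seeded heuristic; it
  is meant for probe-scale searches, not genome-scale BLAST replacement,
  and computes no E-values.
* Clade assignment requires at least one labelled reference per clade in
  the tree and degrades to `unresolved` inside label-mixed polytomies.
* The paired accession-scale integration case (walking a real 105-codon
  truncated model against ten SRA runs to a 215-codon full-length model)
  requires downloading the public runs and is documented here rather than
  executed in the test suite; the in-repo analog plants the same
  truncation (105 of 215 codons) synthetically and recovers it exactly.
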
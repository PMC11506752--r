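---
title: "Characterizing annotated mitochondrial genomes with mitoprofile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing annotated mitochondrial genomes with mitoprofile}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoprofile)
```

## What this package computes, and why

A newly sequenced vertebrate mitogenome is conventionally characterized by a
fixed battery of statistics: partitioned base composition with AT/GC strand
skews, gene-layout arithmetic (intergenic nucleotides, overlaps, start/stop
codon classes), relative synonymous codon usage (RSCU), pairwise Ka/Ks,
sliding-window nucleotide diversity, substitution-saturation checks, control
region (CR) motif structure, tRNA cloverleaf conformation, and a
concatenated protein-coding-gene (PCG) supermatrix for phylogenetics.
`mitoprofile` implements that battery as composable, tested R functions over
a single container, the `mitogenome()`: an optional circular heavy-strand
sequence plus an ordered gene table.

The packaged annotation table (`selene_table1()`) describes the mitogenome
of the African moonfish *Selene dorsalis* (GenBank accession PP857611): a
16,541 bp circle carrying 13 PCGs, 22 tRNAs, 2 rRNAs and one control
region. It ships table-only: the sequence itself is a GenBank resource that
users supply when they want composition statistics on the real genome. All
layout arithmetic — sizes, intergenic nucleotides, overlap totals, the
incomplete-stop classification — is computable (and is tested) from the
table alone.

## Coordinate and strand conventions

* Coordinates are **1-based inclusive on the heavy strand**, exactly as
  annotation tables print them. Internal conversions to half-open intervals
  never leak into any interface.
* A feature with `stop < start` wraps across the origin and is legal only on
  a circular genome.
* `extract_gene_sequence()` always returns the **coding strand**:
  light-strand genes are reverse-complemented, so downstream codon work
  never needs to think about strand.
* The control region is an ordinary `GeneRecord` of kind `CR`, so spacer and
  overlap arithmetic treats it like any gene.
* Intergenic nucleotides follow
  `IN(gene_i) = start(gene_{i+1}) - stop(gene_i) - 1`, attributed to the
  *earlier* feature of each adjacent pair; the final feature's IN closes the
  circle. Consequently `sum(IN) = genome length - sum(gene sizes)` on any
  circular layout, which is one of the package's property tests.

## Genetic code

All translation uses NCBI table 2 (vertebrate mitochondrial): `ATA` is Met,
`TGA` is Trp, `AGA`/`AGG` are stops. This matters quantitatively: leucine
(`TTR` + `CTN`) and serine (`TCN` + `AGY`) keep six-codon families, arginine
drops to four, and the stop set `{TAA, TAG, AGA, AGG}` changes NG86 site
counts at many second and third positions. ND6's codons are always computed
from sequence, never read from an annotation table, because published tables
routinely leave the light-strand PCG's codons blank.

Stop-codon classification in `codon_endpoints()` is driven by gene size
modulo 3: `0` demands a complete terminal stop, `2` the incomplete `TA-`,
`1` the incomplete `T--` (both completed to `TAA` by polyadenylation of the
mature transcript). On the packaged table this arithmetic identifies exactly
seven genes (ND2, ND3, ND4, COII, COIII, ATP6, CYTB) as
polyadenylation-completed. Where a published table's printed stop column
disagrees with its own printed sizes, the arithmetic is authoritative here.

## Composition and skew

`AT-skew = (A - T)/(A + T)` and `GC-skew = (G - C)/(G + C)` on raw counts;
zero denominators give `NA` rather than an error. Percentages use total
sequence length as denominator, so ambiguity codes dilute all four base
percentages symmetrically (the convention used when reading MEGA-style
reports). Partition profiles concatenate member genes **on their coding
strands**; published composition tables do not state their strand handling,
so this is a package decision, with `reference_strand = TRUE` providing the
heavy-strand alternative. Report output rounds percentages to 2 and skews to
3 decimals; raw values are retained everywhere internally.

One known rounding curiosity: 11,427/16,541 = 69.08%, while the source
report prints 69.10% for the same ratio. The package reports the raw value
and its tests compare at 0.05 percentage points.

## NG86 Ka/Ks

`ng86_pair()` implements Nei–Gojobori (1986) pathway counting:

* **Sites**: per codon position, the fraction of the three possible changes
  that are synonymous, *among changes that do not create a stop codon*
  (stop-creating changes leave both numerator and denominator; a position
  whose every change creates a stop contributes no sites). Site totals are
  averaged over the two sequences.
* **Differences**: codons differing at *d* positions are resolved over all
  *d*! mutational pathways; pathways traversing a stop codon are excluded,
  and if every pathway is excluded the count falls back to averaging over
  all pathways (flagged in `pathway_fallbacks`). DnaSP and MEGA differ
  subtly in exactly this stop handling; the package documents its variant
  and exposes `include_stop_paths = TRUE` as the alternative.
* **Correction**: Jukes–Cantor, `d = -3/4 log(1 - 4p/3)`; a proportion at or
  beyond 3/4 yields `NA` (saturation), and `Ks = 0` yields an undefined
  ratio reported as `NA` — never 0 or infinity, since "no synonymous
  change observed" is not evidence of an infinite rate.

The implementation is checked, codon pair by codon pair, against an
independent brute-force oracle that enumerates every pathway explicitly
(200 random 30-codon pairs in the acceptance suite).

## Diversity, windows, saturation

Nucleotide diversity is the mean pairwise per-site difference proportion.
The default is **complete deletion** (every column containing a gap or
ambiguity in any sequence is dropped before comparison), matching common
DnaSP defaults; `deletion = "pairwise"` is the switch. Sliding windows
default to 200 bp / 25 bp step, start at 1, and only full windows are
emitted (a window longer than the alignment produces a single truncated,
flagged window). Saturation records give per-pair transition (`p`) and
transversion (`q`) proportions and the Kimura 2-parameter distance; the K2P
values are cross-checked against `ape::dist.dna(model = "K80")` in the test
suite.

## Control-region motifs and tRNA folding

CSB detection is an IUPAC-aware Hamming scan: a motif symbol matches a query
base only when the symbol's IUPAC set contains it, so `Y` matches `C`/`T`
but a plain base never matches an ambiguous query. The shipped motif set
(`csb_motifs()`) is **configuration, not biology**: published CSB consensus
figures are images, so the package ships placeholder motifs at the
characteristic lengths (CSB-D 18, CSB-1 22, CSB-2 17, CSB-3 19 bp) and
expects real analyses to override them via `read_motifs()`. `find_csb()`
keeps the best (fewest mismatches, then leftmost) hit per motif and checks
the canonical D < 1 < 2 < 3 ordering.

`fold_trna()` is a transparent heuristic, not a covariance model: acceptor
stem by best 7-mer antiparallel pairing (Watson–Crick plus GU wobble, at
least 5/7 paired), anticodon arm as the leftmost perfect 5 bp stem + 7 nt
loop hairpin near the middle third (loop centre = anticodon), DHU arm as a
perfect hairpin of stem at least 3 bp between acceptor and anticodon arms, T
arm of at least 4 bp after the anticodon arm. A trailing CCA is recognized
and ignored. GU wobble makes short spurious stems easy, so *absence* calls
are only meaningful on constructed sequences — which is how the tests use
them (including the DHU-less serine tRNA case). This is deliberate: the
package validates structure on sequences it builds, and leaves genuine tRNA
discovery to covariance-model tools.

## Supermatrix and smoke tree

`build_supermatrix()` concatenates per-gene alignments in canonical
mitochondrial gene order (ND1, ND2, COI, COII, ATP8, ATP6, COIII, ND3,
ND4L, ND4, ND5, ND6, CYTB — source reports rarely state their concatenation
order, so the canonical order is adopted and documented), gap-fills missing
taxa per gene, and tracks charset ranges that tile the matrix exactly.
Exports (relaxed PHYLIP, NEXUS + charsets, RAxML-style partition lines) are
byte-stable for identical input because downstream Bayesian/ML runs should
be reproducible from identical files. Tree inference itself is delegated to
external tools; `nj_tree()` exists as a deterministic neighbor-joining smoke
check (negative branches clamped to zero, taxa pre-sorted so ties break by
name). Codon-position sub-partitioning is not emitted by default (per-gene
partitioning is the norm); it would simply triple the charset lines.

## The synthetic genome generator

`generate_mitogenome()` exists so every stage is testable without network
downloads. Its defaults *are* the study conditions: the packaged 38-feature
layout and the moonfish whole-genome composition (A+T 53.13%, AT-skew
0.034, GC-skew −0.288). The generator:

1. samples background bases i.i.d. from the distribution implied by the
   A+T fraction and both skews;
2. walks PCGs in table order, writing (on the coding strand) a legal start
   codon (`ATG`; `GTG` for COI), the terminal codon dictated by size mod 3,
   and resampling third positions to remove internal in-frame stops —
   *locking* each gene's positions so that in overlap zones the earlier
   template gene wins and later conflicting writes are logged, exactly as
   real overlapping genes (ATP8/ATP6, ND4L/ND4, ND5/ND6) constrain each
   other;
3. optionally plants instantiated CSB motifs in canonical order in the CR,
   and idealized cloverleaves (with template anticodons; serine S1 without
   a DHU arm) in the tRNA genes;
4. finally *repairs composition*: every constrained overwrite is recorded
   as an (old, new) base pair and undone at a random unlocked position, so
   the realized genome-wide composition tracks the dials despite the
   constraints. Without this step the systematic removal of A-rich stop
   codons visibly depresses the AT skew.

Composition targets are met in expectation, not exactly; tests use binomial
tolerances (±0.02 on fractions and skews at 16.5 kb, about five standard
deviations). A single seeded RNG stream drives every stochastic step in
documented order, and the caller's RNG state is saved and restored, so the
same spec and seed give byte-identical genomes on any platform.

`mutate_cds()` places exactly the requested numbers of synonymous and
nonsynonymous single-nucleotide changes in *distinct* codons, never creating
stops — which makes pathway counting exact (`Sd`, `Nd` recover the requested
counts precisely, a property the acceptance suite asserts).
`simulate_alignment()` evolves a star tree under a transition-biased
single-hit model with a closed-form collision correction, so the expected
pairwise p-distance equals the dial; it is an alignment generator for
testing estimators, not a substitute for a full substitution-process
simulator (no rate heterogeneity, no indels, divergence capped below the
model's reachable maximum).

What passing tests on generated data do **not** show: real mitogenomes have
autocorrelated composition, strand-asymmetric mutation pressure, structured
rRNAs, and CR tandem repeats, none of which the generator emulates. The
generated data validate the *arithmetic* of the analyses, and the packaged
annotation table validates the layout statistics against a real genome's
published numbers; composition statistics on the real sequence require the
user to fetch the accession.

## Problem sizes and determinism

The test and acceptance workloads are sized for quick desk runs: 16.5 kb
genomes, 10 kb two-taxon alignments for divergence recovery, 30-codon pairs
(200 of them) for the Ka/Ks oracle, alignments up to 200 nt for the
exhaustive motif-scan comparison. All stochastic tests fix seeds; the
pipeline smoke test runs the simulate → profile → genes → RSCU → Ka/Ks →
supermatrix chain twice from one seed and compares outputs byte for byte.

## Known limitations

* GenBank parsing targets single-record mitogenome flat files (the common
  case); multi-record files, `order()` locations and joins not spanning the
  origin are rejected loudly rather than guessed at.
* `ng86_pair()` drops codon pairs containing gaps or ambiguity symbols
  pairwise; site totals therefore vary slightly with alignment cleanliness.
* Ka/Ks on extremely short or extremely diverged pairs returns `NA` markers
  rather than numbers; consumers must handle them.
* The cloverleaf heuristic over-calls arm presence on random sequence (GU
  wobble); treat absence calls as meaningful only on constructed input.
* The packaged CSB motifs are placeholders at the published lengths, not
  validated consensus sequences.
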
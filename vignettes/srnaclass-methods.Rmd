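---
title: "Methods: sequential small-RNA classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequential small-RNA classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, the tunable parameters, what the synthetic generator does and
does not emulate, and the numerical and design choices made where the
underlying method left them open. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The classification model

Plant sRNA populations mix products of distinct biogenesis pathways that
overlap in length (18–26 nt) but differ in genomic origin. The package
classifies collapsed reads *sequentially*, so that each class is defined on
the residue of the previous ones: miRNAs first (hairpin-derived), then
ra-siRNAs (repeat-derived), then pha-siRNAs (21-nt-registered products of
transcript dicing), then nat-siRNAs (from overlapping or complementary
transcript pairs). The order matters: a 24-nt read inside a transposon is
a ra-siRNA even if the transposon sits inside an annotated transcript, and
a phased read is not re-counted as a nat-siRNA. The sequential exclusion is
asserted in the pipeline and tested.

Two deliberate representation choices underlie everything: sequences are
held in the DNA alphabet (U→T on input) so reads and genomes compare
bit-exactly, and all coordinates are 0-based half-open internally, with
GFF3's 1-based closed convention converted only at the file boundary.

## miRNA locus discovery

A locus is an sRNA cluster (hits within 200 nt of each other; the gap is a
package default, exposed as `max_gap`, since the upstream tool's grouping
is unpublished). Four printed thresholds gate acceptance:

* candidate mature abundance ≥ 10 reads and ≤ 5000 genomic copies;
* strand bias = sense reads / total reads ≥ 0.8;
* abundance bias = reads of the top-3 sRNAs / total reads ≥ 0.6;
* ≤ 4 mature/star duplex mismatches on the folded precursor, with the star
  placed consistently with 2-nt 3′ overhangs (± 3 nt).

Two semantic decisions deserve attention because they are invisible in a
threshold list:

**Who gets filtered.** The ≥10-read filter selects the candidate *mature*;
the cluster itself — bias tallies and the star search — sees every mapped
sRNA. A star at the canonical 20:1 mature:star ratio carries ~5 reads and
would never survive a global ≥10-read cut; filtering globally would make
canonical duplexes undiscoverable by construction.

**Strand bias at perfect duplexes.** A mature whose star arm is its exact
reverse complement maps to the locus on *both* strands. Counting those
hits as antisense evidence would push strand bias toward 0.5 at precisely
the cleanest hairpins. Each distinct sequence therefore contributes its
reads once, on the sense strand if it has any sense-strand hit; when the
top sRNA itself maps to both strands the sense choice is ambiguous, and
discovery tries the read-preferred strand first, then the alternative,
keeping the first validating duplex.

**Folding.** Hairpin validation is a contract on a dot-bracket string, not
on a thermodynamic model: any `fold_fn(sequence) -> dot-bracket` can be
plugged in. The bundled default is Nussinov base-pair maximisation
(minimum loop 3, G:U pairs allowed, deterministic traceback) compiled via
Rcpp, so the package folds without external libraries. Its known
limitation — no stacking energies, so ties can re-pair a mismatched stem
off register — costs exactly one of the 22 implanted hairpins in the
default synthetic world (recall 21/22 ≈ 0.95); a thermodynamic folder
supplied as `fold_fn` removes that artifact. Duplex mismatches are counted
as mature-arm positions not paired into the star (and vice versa, taking
the larger arm count), excluding the 2-nt 3′ overhangs, with G:U counting
as paired — standard plant miRNA annotation practice.

## Conservation, families, gene context

Conservation is decided by a substitution distance to a known-miRNA
catalogue: the best ungapped sliding alignment, with each overhanging
nucleotide costing one substitution. This is deterministic and
conservative; an indel-tolerant aligner would only loosen the ≤ 3 boundary
the method prints. Lineage-specific matures are grouped by single linkage
at the same ≤ 3 radius — the method does not state how novel families were
delimited, so the package uses the one radius it does print and records
family ids (`miRLS-0001`, …) in lexicographic order of each family's
smallest sequence for reproducibility.

Precursor gene context is typed against transcript models: fully inside an
intron → `intron`; fully inside an exon → `exon`; otherwise, overlapping a
boundary → `junction`; and when two transcripts at one locus disagree
(intron for one, exon for the other) the merged context is `intron_exon`,
the alternative-splicing candidate class. The supporting
transcript-to-genome alignment filter (≥ 96% identity, ≤ 3 mismatches, no
indel, ≤ 5000 nt) is applied to *supplied* alignment statistics; the
package deliberately does not implement a spliced aligner — the filter is
the method, the alignment is infrastructure.

## ra-siRNA taxonomy

Any non-miRNA sRNA overlapping a repeat feature by ≥ 1 nt is a ra-siRNA
("matching repeat DNAs" is unqualified upstream, so the loosest reading is
used). An sRNA can overlap several repeat classes; the taxonomy counts it
once, under the highest-priority class (retrotransposon > DNA transposon >
rRNA > simple repeat > others — a package invention, recorded in output
metadata), while all classes are retained in the detail records. Per-class
totals satisfy `total = A2_only + D5_only + both` by construction, which
is also the column semantics of the taxonomy the method prints.

## Phasing statistic and PYT calling

For a window of `m` 21-nt cycles anchored at an occupied position, with
`N = 21m` candidate positions of which `n` are occupied and `k` in
register, the p-value is the hypergeometric upper tail
`P(X ≥ k | N, m, n)` computed by a log-space tail sum (exact for all
practical sizes; the acceptance suite checks it against an exhaustive
combinatorial oracle and a 10⁵-draw Monte-Carlo null). Occupancy is
*positional*: read counts do not enter `(n, k)` because the null models
positions, not reads; read weights enter only the post-filters.

Choices the upstream description leaves open:

* **Window**: `m = 11` cycles (231 nt), scanned anchored at every occupied
  position, truncated at the transcript end (minimum 2 cycles);
  configurable as `phase_cycles`.
* **Antisense reads** register after a +2 nt shift of their interval
  start — the 2-nt 3′ overhang geometry of DCL duplexes.
* **Phased ratio**: the printed "pha-siRNAs/non-pha-siRNAs ≥ 0.6" is
  ambiguous between a ratio and a fraction; the package uses in-register
  reads / all window reads, which is bounded in [0, 1] so the 0.6
  threshold is well-defined.
* Overlapping significant windows on one transcript merge into one locus,
  keeping the minimal p-value and its anchor.

Initiator prediction slides each miRNA across the region within 148 nt of
a phased locus, scoring the first 18 positions from the miRNA 5′ end
(mismatch 1.0, G:U 0.5, doubled at positions 2–13; the scheme's indel
penalty of 2.0 cannot fire in this ungapped implementation) and calls a
trigger when the expectation is ≤ 4.0 and the cleavage position (opposite
miRNA positions 10–11) lies within 1 nt of the phase register.

## NAT pairs

Cis pairs are opposite-strand transcripts with ≥ 50 nt *genomic* span
overlap (whether the upstream method measured the overlap in genomic or
spliced-transcript coordinates is unstated; genomic is implemented and
noted here). Orientation typing is a total, deterministic partition:
`coincided` requires identical spans; containment — including containment
with one shared endpoint — is `enclosed`; remaining partial overlaps are
`convergent` when the overlap contains both 3′ termini and `divergent`
when both 5′ termini.

Trans pairs are found by local alignment of each sequence against the
partner's reverse complement (match +1, mismatch −2, gap −4; the search
engine is infrastructure — the method is the ≥ 100 nt block and the
duplex filter). The duplex filter accepts a pair when some alignment
window of ≥ 50 columns has ≥ 90% paired positions (Watson–Crick or G:U;
gaps unpaired). Pairing is alignment-based, not thermodynamic: the 50
nt/90% rule is checkable without free energies, and cofolding would add a
dependency without changing the decision rule. Reads straddling an overlap
boundary are assigned by their midpoint — a determinism choice where the
method is silent.

## The synthetic world

`sim_config()` defaults state the world the tests run in: two 100-kb
uniform-random references (`A2`, `D5`); 20 genomic and 2 transcript-borne
hairpins built as true reverse-complement stems with 2-nt 3′ overhangs and
0–2 engineered duplex mismatches, expressed at 100 mature / 5 star reads
(20:1) with 3% antisense noise; 50 repeat features over ten repeat
classes, 30% of them copied to the other sub-genome so the "both" taxonomy
column is exercised; 10 phased transcripts of 8 cycles whose trigger site
is the exact reverse complement of a designated mature (cleavage on the
anchor) and 20 unphased decoy transcripts with 8 random read positions; 8
cis pairs (two per orientation, overlaps 200–900 nt); 6 trans pairs with a
150-nt complementary block at ~4% mismatch plus 3 reversed-polarity decoy
pairs (same-sense copy of the block, which must fail the complementarity
search); 200 background reads avoiding repeat features. Matures start with
U and repeat/background read starts are biased ~70% toward A/U,
reproducing the 5′-nucleotide signature the field reports for AGO sorting.

What a green recovery test establishes — and what it does not: signals are
implanted, not evolved; the background is i.i.d. uniform, so there is no
genomic repeat structure, no homeolog divergence, no expression noise
model, and no multi-mapping ambiguity beyond what the implants themselves
create. The tests therefore validate the *decision rules* at their printed
thresholds, not robustness to real-library artifacts.

Determinism: `generate_reference()` seeds the RNG with `config$seed` and
`simulate_reads()` with `seed + 1`; identical config + seed reproduces
byte-identical FASTA/GFF3/TSV/JSON outputs (tested).

## Numerical notes and degenerate inputs

* `phasing_pvalue` is a log-space `lchoose` tail sum; `k = 0` returns 1
  exactly; `k > min(n, m)` is a domain error; `N` not a multiple of the
  phase is rejected.
* Clusters with zero total reads are rejected rather than producing NaN
  biases; empty inputs return typed empty frames throughout.
* Ties are broken lexicographically (most-abundant sRNA, family labels,
  pair ids `a|b` with `a < b`) so reruns are identical.
* Genome Ns never match reads; reads containing N are mappable nowhere and
  simply absent from hit tables.
* The Nussinov traceback prefers pairing the outer bases, then left/right
  unpaired, then the first admissible bifurcation — one deterministic
  structure per sequence.

## Known limitations

* The bundled folder can mis-register imperfect stems (see above); supply
  a thermodynamic `fold_fn` for production annotation.
* Exact matching only: a single SNP between sub-genomes hides a read from
  one of them. The upstream method states no mismatch allowance, so none
  is implemented.
* Gene-context typing consumes precomputed transcript-to-genome alignment
  statistics; Venn/origin summaries count detection, not expression.
* `find_trans_nats` is all-vs-all local alignment (quadratic in transcript
  count) — appropriate at desk scale, not for a full transcriptome.
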
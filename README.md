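# srnaclass

Sequential classification of plant small RNAs (sRNAs) into the five major
classes — microRNAs (miRNAs), repeat-associated siRNAs (ra-siRNAs), 21-nt
phased siRNAs (pha-siRNAs), and cis-/trans-natural-antisense-transcript
siRNAs (nat-siRNAs) — from collapsed sRNA-seq libraries, one or more
reference genomes (e.g. the two diploid sub-genomes of an allotetraploid
cotton), transcript models and repeat annotations.

The package is aimed at desk-scale methodological work: every stage of the
classification is an exported, unit-tested function, and a synthetic
genome/read generator with a serialized truth manifest makes the whole
pipeline verifiable with precision/recall scoring — no external data
downloads are required.

## What it computes

Reads are collapsed to distinct 18–26 nt sequences with per-library counts,
mapped to the references by exact full-length matching on both strands, and
classified in the exclusion order **miRNA → ra-siRNA → pha-siRNA →
nat-siRNA**:

* **miRNA loci** — sRNA clusters are screened by total abundance (≥ 10
  reads for the candidate mature), genomic copy number (≤ 5000), strand
  bias ≥ 0.8 (sense reads / total reads) and abundance bias ≥ 0.6 (reads of
  the top-3 sRNAs / total reads); a mature/miRNA\* duplex within 450 nt is
  then validated on a folded precursor, requiring ≤ 4 duplex mismatches and
  2-nt 3′-overhang geometry (± 3 nt shift). Folding is a pluggable contract;
  the bundled default is base-pair maximisation (Nussinov, min loop 3, G:U
  allowed) in C++.
* **Conservation & context** — matures within ≤ 3 substitutions of a known
  plant miRNA are conserved and inherit its family; the rest are
  single-linkage grouped into novel lineage-specific families. Precursors
  inside protein-coding genes are typed intron / exon / junction /
  intron-exon (alternative-splicing candidate).
* **ra-siRNAs** — non-miRNA sRNAs with ≥ 1 nt overlap of a repeat feature,
  tabulated per repeat class × sub-genome (A2-only / D5-only / both / total).
* **pha-siRNAs** — for a window of `m` phase cycles (`N = 21·m` positions,
  `n` occupied, `k` in register) the phasing p-value is the hypergeometric
  upper tail

      p = Σ_{j=k}^{min(n,m)} C(m,j)·C(N−m, n−j) / C(N,n)

  computed in log space. Loci with `p < 1e-3` are kept if they have ≥ 2
  pha-siRNAs, a pha-siRNA with ≥ 5 reads, and an in-register read fraction
  ≥ 0.6. miRNA initiators are predicted with a psRNATarget-style penalty
  (mismatch 1, G:U 0.5, positions 2–13 doubled; expectation ≤ 4.0 over 18
  scored positions) within 148 nt of the locus, allowing a 1-nt shift of
  the cleavage site from the phase register.
* **nat-siRNAs** — cis-NAT pairs are opposite-strand transcripts with ≥ 50
  nt genomic overlap, typed convergent / divergent / enclosed / coincided;
  trans-NAT pairs have a ≥ 100 nt complementary block (local alignment
  against the reverse complement) containing a ≥ 50 nt window with ≥ 90%
  paired positions. sRNAs on pair members are profiled by overlap /
  non-overlap region, exon / intron, and strand.

## Worked example

Simulate the default synthetic world (two 100-kb sub-genomes `A2`/`D5`, 20
genomic + 2 transcript-borne hairpins at a 20:1 mature:star read ratio, 50
repeat features, 10 phased transcripts of 8 cycles with miRNA trigger
sites, 20 unphased decoys, 8 cis pairs — two per orientation — 6 trans
pairs plus reversed-polarity decoys, and background reads), then classify
and score it:

```r
library(srnaclass)
cfg  <- sim_config(seed = 42)
ref  <- generate_reference(cfg)
libs <- simulate_reads(ref, cfg)
res  <- run_pipeline(list(reads = libs, genome = ref$genome,
                          tx_seqs = ref$tx_seqs, tx_models = ref$tx_models,
                          repeats = ref$repeats, known = ref$known))
#> reads: 819 distinct sRNAs (6607/6607 reads) after 18-26 nt filter
#> miRNA: 26 loci, 42 mature/star sequences
#> ra-siRNA: 149 sequences
#> pha-siRNA: 10 PYTs, 110 pha-siRNAs, 15 initiator calls
#> cis-NAT: 8 pairs, 85 cis-nat siRNAs
#> trans-NAT: 6 pairs, 47 trans-nat siRNAs

evaluate_recovery(res, ref$truth, origin = attr(libs, "origin"))
#>         class  tp fp fn precision    recall
#> 1 mirna_locus  21  0  1         1 0.9545455
#> 2     rasirna 149  0  0         1 1.0000000
#> 3         pyt  10  0  0         1 1.0000000
#> 4    cis_pair   8  0  0         1 1.0000000
#> 5  trans_pair   6  0  0         1 1.0000000
#> 6   initiator  10 NA  0        NA 1.0000000
```

The 26 called loci are the 22 implanted hairpins seen from the genome and
again through transcripts that carry them (matched by identical
mature/star duplex); the single miss is a hairpin with two engineered
duplex mismatches that the bundled base-pair-maximising folder re-pairs
off register (see the methods vignette). All 10 phased transcripts are
recovered at `p = 2.3e-12` with in-register read fractions ≈ 0.99, their
implanted miRNA triggers are all identified, the 8 cis pairs are typed
with orientation accuracy 1.0, and per-class read profiles reproduce the
designed 5′-U bias of the matures:

```r
round(res$profiles$mirna$five_prime, 3)
#>     A     C     G     U
#> 0.190 0.095 0.095 0.619
```

A command-line wrapper with `simulate` / `classify` / `evaluate` /
`profile` subcommands is installed under
`system.file("scripts", "srnaclass-cli.R", package = "srnaclass")`.

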
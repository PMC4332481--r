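# Fixture builders shared across test files. Everything is generated in
# code; no data files.

rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# srna_set with given sequences and total counts (single library)
srna_fixture <- function(sequences, counts) {
  collapse_reads(list(L1 = data.frame(sequence = sequences, count = counts)))
}

# a designed hairpin segment: flank + mature + loop + revcomp(mature) + flank;
# star (2-nt 3' overhang geometry) starts 2 nt into the second arm
hairpin_fixture <- function(mature = NULL, flank = 20L, loop = 15L) {
  if (is.null(mature)) mature <- paste0("T", rand_dna(20))
  seg <- paste0(rand_dna(flank), mature, rand_dna(loop), rc(mature),
                rand_dna(flank))
  list(segment = seg, mature = mature,
       mature_off = flank, star_off = flank + 21L + loop + 2L,
       star = substr(seg, flank + 21L + loop + 2L + 1L,
                     flank + 21L + loop + 2L + 21L))
}

# stub folding function returning a canned structure (for contract tests)
fold_stub <- function(structure) function(sequence) structure

# overlap of two 0-based half-open intervals given as c(start, end)
interval_overlap_test <- function(a, b) min(a[2], b[2]) - max(a[1], b[1])

# shared state between the acceptance criteria (the default-world pipeline
# run is expensive; criterion 5 reuses criterion 4's run when available)
.acceptance_cache <- new.env(parent = emptyenv())
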
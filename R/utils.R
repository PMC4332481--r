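# Internal helpers shared across modules. Coordinates are 0-based half-open
# everywhere inside the package; GFF3 (1-based closed) is converted at the
# file boundary only.

#' Canonicalise nucleotide sequences to the DNA alphabet
#'
#' Uppercases and replaces U with T. The package stores all sequences in the
#' DNA alphabet so reads (often RNA) and genomes (DNA) are comparable.
#'
#' @param x character vector of sequences.
#' @return character vector over ACGTN (validity is not checked here).
#' @keywords internal
dna_canon <- function(x) toupper(chartr("uU", "tT", x))

#' Reverse complement of DNA strings
#' @param x character vector over ACGTN.
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# overlap length of [s1,e1) and [s2,e2); <= 0 means disjoint
interval_overlap <- function(s1, e1, s2, e2) {
  pmin(e1, e2) - pmax(s1, s2)
}

# TRUE where sequences contain only ACGTN (after canonicalisation)
valid_dna <- function(x) {
  !grepl("[^ACGTN]", x)
}

pipeline_log <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
  invisible(NULL)
}

# stable order: by numeric value then lexicographic tiebreak on key
order_desc_with_tie <- function(value, key) {
  order(-value, key, method = "radix")
}
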
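# Pluggable folding contract: a fold function takes one sequence (ACGTN,
# DNA alphabet) and returns one dot-bracket string of equal length.

#' Fold a sequence by base-pair maximisation
#'
#' The bundled default folding engine: Nussinov base-pair maximisation with a
#' minimum hairpin loop of `min_loop` unpaired nucleotides; G:U (G:T in DNA
#' alphabet) counts as paired, N never pairs. Any function with the same
#' signature (sequence in, dot-bracket out), e.g. a wrapper around a
#' thermodynamic folder, can replace it wherever a `fold_fn` argument is
#' accepted.
#'
#' @param sequence one DNA/RNA string.
#' @param min_loop minimum unpaired loop length (default 3).
#' @return dot-bracket string of the same length.
#' @examples
#' fold_nussinov("GGGGAAAACCCC")
#' @export
fold_nussinov <- function(sequence, min_loop = 3L) {
  stopifnot(length(sequence) == 1)
  .nussinov_fold(dna_canon(sequence), as.integer(min_loop))
}

#' Pairing partners from a dot-bracket string
#' @param db dot-bracket string (one of `().`).
#' @return integer vector, 1-based partner index per position (NA unpaired).
#' @export
dotbracket_pairs <- function(db) {
  ch <- strsplit(db, "")[[1]]
  n <- length(ch)
  partner <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  partner
}
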
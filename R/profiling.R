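# Length and 5'-nucleotide composition summaries for any sRNA class.

#' Length distribution of an sRNA class
#'
#' @param srnas an `srna_set` (or any data frame with `sequence` and,
#'   when `weighted`, `total_count`).
#' @param weighted count reads instead of distinct sequences.
#' @param lengths histogram support (default 18:26).
#' @return named numeric vector over `lengths`.
#' @export
length_distribution <- function(srnas, weighted = FALSE, lengths = 18:26) {
  len <- nchar(srnas$sequence)
  w <- if (weighted) srnas$total_count else rep(1, nrow(srnas))
  h <- vapply(lengths, function(l) sum(w[len == l]), numeric(1))
  setNames(h, as.character(lengths))
}

#' 5'-first-nucleotide composition of an sRNA class
#'
#' Reported over the RNA alphabet A/C/G/U (T is counted as U).
#'
#' @param srnas an `srna_set`.
#' @param weighted weight by read counts.
#' @return named fractions summing to 1; a zero-length class yields an
#'   empty result with a warning.
#' @export
five_prime_composition <- function(srnas, weighted = FALSE) {
  if (!nrow(srnas)) {
    warning("empty sRNA class: no 5' composition")
    return(setNames(numeric(0), character(0)))
  }
  first <- substr(srnas$sequence, 1, 1)
  first[first == "T"] <- "U"
  w <- if (weighted) srnas$total_count else rep(1, nrow(srnas))
  tot <- sum(w)
  frac <- vapply(c("A", "C", "G", "U"), function(b) sum(w[first == b]) / tot,
                 numeric(1))
  frac
}

#' Histogram of NAT overlap lengths
#'
#' Bins pair overlap lengths into fixed-width bins with a single open
#' top bin (default 100-nt bins up to 1000, then `">1000"`).
#'
#' @param pairs data frame with an `overlap_length` column.
#' @param bin_width bin width in nt (default 100).
#' @param top open-bin threshold (default 1000).
#' @return named integer vector of bin counts.
#' @export
overlap_length_histogram <- function(pairs, bin_width = 100L, top = 1000L) {
  breaks <- seq(0L, top, by = bin_width)
  labels <- c(paste0("[", head(breaks, -1), ",", breaks[-1], ")"),
              paste0(">", top))
  counts <- integer(length(labels))
  ol <- pairs$overlap_length
  for (i in seq_len(length(breaks) - 1L)) {
    counts[i] <- sum(ol >= breaks[i] & ol < breaks[i + 1L])
  }
  counts[length(labels)] <- sum(ol >= top)
  setNames(counts, labels)
}
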
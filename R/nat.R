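# Natural antisense transcripts: cis pairs from genomic overlap geometry,
# trans pairs from complementary local alignment with a 50 nt / 90% duplex
# window filter, and nat-siRNA assignment/enrichment.

#' Find cis-NAT pairs from transcript genomic spans
#'
#' All opposite-strand transcript pairs sharing a genomic locus with an
#' overlap of at least `min_overlap` nt. Each pair is reported once
#' (`a < b` by id) with its overlap interval and orientation.
#'
#' @param spans data frame with `id`, `seqid`, `start`, `end`, `strand`
#'   (0-based half-open genomic spans).
#' @param min_overlap minimum overlap in nt (default 50).
#' @return data frame: `pair_id`, `a`, `b`, `seqid`, `a_start`, `a_end`,
#'   `a_strand`, `b_start`, `b_end`, `b_strand`, `overlap_start`,
#'   `overlap_end`, `overlap_length`, `orientation`.
#' @export
find_cis_nats <- function(spans, min_overlap = 50L) {
  empty <- data.frame(pair_id = character(), a = character(), b = character(),
                      seqid = character(), a_start = integer(),
                      a_end = integer(), a_strand = character(),
                      b_start = integer(), b_end = integer(),
                      b_strand = character(), overlap_start = integer(),
                      overlap_end = integer(), overlap_length = integer(),
                      orientation = character(), stringsAsFactors = FALSE)
  if (nrow(spans) < 2) return(empty)
  out <- list()
  for (chr in unique(spans$seqid)) {
    s <- spans[spans$seqid == chr, , drop = FALSE]
    s <- s[order(s$id), , drop = FALSE]
    n <- nrow(s)
    if (n < 2) next
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (s$strand[i] == s$strand[j]) next
      ov <- interval_overlap(s$start[i], s$end[i], s$start[j], s$end[j])
      if (ov < min_overlap) next
      orient <- classify_orientation(s$start[i], s$end[i], s$strand[i],
                                     s$start[j], s$end[j], s$strand[j])
      out[[length(out) + 1L]] <- data.frame(
        a = s$id[i], b = s$id[j], seqid = chr,
        a_start = s$start[i], a_end = s$end[i], a_strand = s$strand[i],
        b_start = s$start[j], b_end = s$end[j], b_strand = s$strand[j],
        overlap_start = max(s$start[i], s$start[j]),
        overlap_end = min(s$end[i], s$end[j]),
        overlap_length = ov, orientation = orient,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$a, res$b, method = "radix"), ]
  res <- cbind(pair_id = paste(res$a, res$b, sep = "|"), res,
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Classify the overlap orientation of a cis-NAT pair
#'
#' `coincided`: identical spans. `enclosed`: one span contains the other
#' (containment with one shared endpoint still counts as enclosed, so the
#' four classes partition all geometries). Otherwise the overlap of a
#' partial, opposite-strand pair contains either both 3' termini
#' (`convergent`) or both 5' termini (`divergent`); the 3' terminus of a
#' plus-strand transcript is its right end, of a minus-strand transcript its
#' left end.
#'
#' @param a_start,a_end,a_strand,b_start,b_end,b_strand span geometry
#'   (0-based half-open; strands must differ for a cis pair, but the
#'   classifier is total over all inputs).
#' @return one of `"convergent"`, `"divergent"`, `"enclosed"`, `"coincided"`.
#' @export
classify_orientation <- function(a_start, a_end, a_strand,
                                 b_start, b_end, b_strand) {
  if (a_start == b_start && a_end == b_end) return("coincided")
  if ((a_start <= b_start && a_end >= b_end) ||
      (b_start <= a_start && b_end >= a_end)) return("enclosed")
  os <- max(a_start, b_start); oe <- min(a_end, b_end)
  three_prime <- function(s, e, strand) if (strand == "+") e - 1L else s
  five_prime <- function(s, e, strand) if (strand == "+") s else e - 1L
  in_ov <- function(p) p >= os && p < oe
  a3 <- in_ov(three_prime(a_start, a_end, a_strand))
  b3 <- in_ov(three_prime(b_start, b_end, b_strand))
  a5 <- in_ov(five_prime(a_start, a_end, a_strand))
  b5 <- in_ov(five_prime(b_start, b_end, b_strand))
  if (a3 && b3) return("convergent")
  if (a5 && b5) return("divergent")
  # mixed terminus pair (same-strand or degenerate input): classify by the
  # terminus pair present, preferring convergent for determinism
  if (a3 || b3) "convergent" else "divergent"
}

#' Find trans-NAT candidate pairs by complementary local alignment
#'
#' Aligns every transcript pair (excluding self-pairs and, typically,
#' cis-NAT members) locally against the reverse complement of the partner
#' (match +1, mismatch -2, gap -4 by default) and keeps pairs whose best
#' complementary block spans at least `min_overlap` nt on each sequence.
#'
#' @param seqs named [Biostrings::DNAStringSet] (cis-NAT members removed).
#' @param min_overlap minimum complementary block length (default 100).
#' @param match,mismatch,gap alignment scores.
#' @return data frame: `pair_id`, `a`, `b`, `a_start`, `a_end`, `b_start`,
#'   `b_end` (0-based spans of the complementary block on each transcript),
#'   `overlap_length`, `aligned_a`, `aligned_b` (alignment strings, a vs
#'   reverse complement of b).
#' @export
find_trans_nats <- function(seqs, min_overlap = 100L, match = 1,
                            mismatch = -2, gap = -4) {
  empty <- data.frame(pair_id = character(), a = character(), b = character(),
                      a_start = integer(), a_end = integer(),
                      b_start = integer(), b_end = integer(),
                      overlap_length = integer(), aligned_a = character(),
                      aligned_b = character(), stringsAsFactors = FALSE)
  ids <- sort(names(seqs))
  if (length(ids) < 2) return(empty)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = TRUE)
  out <- list()
  for (i in 1:(length(ids) - 1)) for (j in (i + 1):length(ids)) {
    a <- seqs[[ids[i]]]
    brc <- Biostrings::reverseComplement(seqs[[ids[j]]])
    al <- Biostrings::pairwiseAlignment(
      a, brc, type = "local", substitutionMatrix = sm,
      gapOpening = 0, gapExtension = abs(gap))
    pa <- Biostrings::pattern(al)
    su <- Biostrings::subject(al)
    a_span <- c(Biostrings::start(pa), Biostrings::end(pa))
    s_span <- c(Biostrings::start(su), Biostrings::end(su))
    len_a <- a_span[2] - a_span[1] + 1L
    len_b <- s_span[2] - s_span[1] + 1L
    if (len_a < min_overlap || len_b < min_overlap) next
    lb <- length(seqs[[ids[j]]])
    # subject coordinates are on the reverse complement; map back to b
    b_start <- lb - s_span[2]
    b_end <- lb - s_span[1] + 1L
    out[[length(out) + 1L]] <- data.frame(
      a = ids[i], b = ids[j],
      a_start = a_span[1] - 1L, a_end = a_span[2],
      b_start = b_start, b_end = b_end,
      overlap_length = min(len_a, len_b),
      aligned_a = as.character(pa), aligned_b = as.character(su),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- cbind(pair_id = paste(res$a, res$b, sep = "|"), res,
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

# per-column pairedness of an alignment of a against revcomp(b): equal
# non-gap characters are Watson-Crick pairs; G~A and T~C columns are G:U
# wobbles in the original a/b orientation; gaps are unpaired.
alignment_paired <- function(aligned_a, aligned_b) {
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  (ca == cb & ca %in% c("A", "C", "G", "T")) |
    (ca == "G" & cb == "A") | (ca == "T" & cb == "C")
}

#' Duplex filter for trans-NAT candidates
#'
#' Accepts a candidate when some alignment window of at least `min_window`
#' columns has a paired fraction (Watson-Crick or G:U) of at least
#' `min_fraction`. The paired fraction of the best qualifying window (or,
#' failing acceptance, the best window overall) is reported.
#'
#' @param aligned_a,aligned_b alignment strings from [find_trans_nats()].
#' @param min_window minimum duplex window (default 50 columns).
#' @param min_fraction minimum paired fraction (default 0.9).
#' @return list with `paired_fraction` and `accepted`.
#' @export
duplex_filter <- function(aligned_a, aligned_b, min_window = 50L,
                          min_fraction = 0.9) {
  paired <- alignment_paired(aligned_a, aligned_b)
  L <- length(paired)
  if (L < min_window) return(list(paired_fraction = 0, accepted = FALSE))
  cs <- c(0, cumsum(paired))
  best_ok <- -Inf
  best_any <- -Inf
  for (s in 0:(L - min_window)) {
    w <- min_window:(L - s)
    frac <- (cs[s + w + 1L] - cs[s + 1L]) / w
    mx <- max(frac)
    best_any <- max(best_any, mx)
    ok <- frac >= min_fraction
    if (any(ok)) best_ok <- max(best_ok, max(frac[ok]))
  }
  if (is.finite(best_ok)) {
    list(paired_fraction = best_ok, accepted = TRUE)
  } else {
    list(paired_fraction = best_any, accepted = FALSE)
  }
}

#' Assign sRNA hits to NAT pairs
#'
#' Labels each hit on a pair member by region (`overlap`/`non_overlap`,
#' decided by the hit midpoint against the pair's overlap span), feature
#' (`exon`/`intron`, by midpoint against the member transcript model;
#' transcripts without introns are all-exon), and strand (`plus`/`minus`).
#'
#' @param hits genomic hits from [map_exact()] for cis pairs, or
#'   transcript-space hits for trans pairs.
#' @param pairs cis pairs from [find_cis_nats()] (uses genomic member spans
#'   and overlap interval) or trans pairs from [find_trans_nats()] (uses
#'   per-member block spans; `seqid` is then the member transcript id).
#' @param models optional transcript models from [read_transcripts()] for
#'   the exon/intron label (cis pairs); without models every hit is `exon`.
#' @param srnas optional `srna_set` for read counts (else reads = 1).
#' @param kind `"cis"` or `"trans"`.
#' @return data frame: `sequence`, `pair_id`, `member`, `region`, `feature`,
#'   `strand`, `reads`.
#' @export
assign_nat_sirnas <- function(hits, pairs, models = NULL, srnas = NULL,
                              kind = c("cis", "trans")) {
  kind <- match.arg(kind)
  empty <- data.frame(sequence = character(), pair_id = character(),
                      member = character(), region = character(),
                      feature = character(), strand = character(),
                      reads = numeric(), stringsAsFactors = FALSE)
  if (!nrow(hits) || !nrow(pairs)) return(empty)
  reads_of <- function(s) {
    if (is.null(srnas)) return(rep(1, length(s)))
    r <- srnas$total_count[match(s, srnas$sequence)]
    r[is.na(r)] <- 1
    r
  }
  out <- list()
  for (pi in seq_len(nrow(pairs))) {
    p <- pairs[pi, ]
    members <- if (kind == "cis") {
      data.frame(id = c(p$a, p$b), seqid = p$seqid,
                 start = c(p$a_start, p$b_start),
                 end = c(p$a_end, p$b_end),
                 ov_start = p$overlap_start, ov_end = p$overlap_end,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(id = c(p$a, p$b), seqid = c(p$a, p$b),
                 start = NA_integer_, end = NA_integer_,
                 ov_start = c(p$a_start, p$b_start),
                 ov_end = c(p$a_end, p$b_end), stringsAsFactors = FALSE)
    }
    for (mi in 1:2) {
      mm <- members[mi, ]
      h <- hits[hits$seqid == mm$seqid, , drop = FALSE]
      if (kind == "cis" && nrow(h)) {
        h <- h[interval_overlap(h$start, h$end, mm$start, mm$end) > 0, ,
               drop = FALSE]
      }
      if (!nrow(h)) next
      mid <- (h$start + h$end) %/% 2L
      region <- ifelse(mid >= mm$ov_start & mid < mm$ov_end,
                       "overlap", "non_overlap")
      feature <- rep("exon", nrow(h))
      if (kind == "cis" && !is.null(models)) {
        intr <- transcript_introns(models, mm$id)
        if (nrow(intr)) {
          for (ii in seq_len(nrow(intr))) {
            feature[mid >= intr$start[ii] & mid < intr$end[ii]] <- "intron"
          }
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        sequence = h$sequence, pair_id = p$pair_id, member = mm$id,
        region = region, feature = feature,
        strand = ifelse(h$strand == "+", "plus", "minus"),
        reads = reads_of(h$sequence), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read-fraction enrichment profile of nat-siRNAs
#'
#' Read fractions for the three dichotomies of nat-siRNA derivation:
#' overlap/non-overlap region, exon/intron feature, plus/minus strand.
#' Each dichotomy sums to 1.
#'
#' @param assignments output of [assign_nat_sirnas()].
#' @return data frame with `dichotomy`, `level`, `reads`, `fraction`; empty
#'   when there are no assignments.
#' @export
enrichment_profile <- function(assignments) {
  if (!nrow(assignments)) {
    return(data.frame(dichotomy = character(), level = character(),
                      reads = numeric(), fraction = numeric(),
                      stringsAsFactors = FALSE))
  }
  dims <- list(region = c("overlap", "non_overlap"),
               feature = c("exon", "intron"),
               strand = c("plus", "minus"))
  out <- list()
  for (d in names(dims)) {
    tot <- sum(assignments$reads)
    for (lev in dims[[d]]) {
      r <- sum(assignments$reads[assignments[[d]] == lev])
      out[[length(out) + 1L]] <- data.frame(
        dichotomy = d, level = lev, reads = r, fraction = r / tot,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
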
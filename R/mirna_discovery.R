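# miRNA hairpin locus discovery: cluster genome-mapped sRNAs, apply the
# abundance/copy-number pre-filter and the strand/abundance-bias locus
# filters, then search mature/star duplex pairs validated on a folded
# precursor (<= 4 duplex mismatches, 2-nt 3' overhang geometry).

#' Group alignment hits into loci by positional proximity
#'
#' Maximal strandless clusters in which consecutive hits are separated by at
#' most `max_gap` nt (gap measured from the rightmost end seen so far).
#'
#' @param hits data frame from [map_exact()].
#' @param max_gap maximum allowed gap in nt between adjacent hits.
#' @return `hits` with an added integer `cluster` column.
#' @export
cluster_hits <- function(hits, max_gap = 200L) {
  if (!nrow(hits)) {
    hits$cluster <- integer(0)
    return(hits)
  }
  hits <- hits[order(hits$seqid, hits$start, hits$end, method = "radix"), ]
  cl <- integer(nrow(hits))
  cur <- 0L
  last_seqid <- ""
  last_end <- -Inf
  for (i in seq_len(nrow(hits))) {
    if (hits$seqid[i] != last_seqid || hits$start[i] - last_end > max_gap) {
      cur <- cur + 1L
      last_end <- hits$end[i]
    } else {
      last_end <- max(last_end, hits$end[i])
    }
    last_seqid <- hits$seqid[i]
    cl[i] <- cur
  }
  hits$cluster <- cl
  rownames(hits) <- NULL
  hits
}

#' Pre-filter sRNAs for miRNA candidacy
#'
#' Keeps sequences with total abundance >= `min_total` reads and at most
#' `max_genome_hits` exact genomic copies.
#'
#' @param srnas an `srna_set`.
#' @param genome_hits named hit-count vector from [hit_counts()].
#' @param min_total minimum total read count (default 10).
#' @param max_genome_hits maximum genomic copy number (default 5000).
#' @return the filtered `srna_set`.
#' @export
candidate_filter <- function(srnas, genome_hits, min_total = 10,
                             max_genome_hits = 5000) {
  nh <- genome_hits[srnas$sequence]
  nh[is.na(nh)] <- 0L
  out <- srnas[srnas$total_count >= min_total & nh <= max_genome_hits, ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

# distinct (sequence, strand) records of one cluster with read totals
cluster_members <- function(chits, srnas) {
  key <- !duplicated(paste(chits$sequence, chits$strand))
  mem <- chits[key, c("sequence", "seqid", "start", "end", "strand")]
  mem$reads <- srnas$total_count[match(mem$sequence, srnas$sequence)]
  mem$reads[is.na(mem$reads)] <- 0
  rownames(mem) <- NULL
  mem
}

#' Strand bias and abundance bias of an sRNA cluster
#'
#' The sense strand is the strand of the most abundant sRNA in the cluster
#' (ties broken by lexicographically smallest sequence). Strand bias is the
#' fraction of cluster reads on the sense strand; abundance bias is the
#' fraction contributed by the three most abundant distinct sRNAs.
#'
#' @param members data frame with columns `sequence`, `strand`, `reads`
#'   (one row per distinct sequence/strand in the cluster).
#' @return list with `strand_bias` and `abundance_bias`, both in `[0, 1]`.
#' @details Each distinct sequence contributes its reads once. A sequence
#'   that maps to the cluster on both strands (as happens at a perfectly
#'   complementary duplex arm) is counted on the sense strand: it cannot
#'   serve as antisense evidence against the locus. The sense strand is the
#'   strand of the most abundant sRNA; if that sRNA itself maps to both
#'   strands, the strand carrying more cluster reads wins (ties to `+`).
#' @export
locus_biases <- function(members) {
  seqs <- unique(members$sequence)
  reads <- members$reads[match(seqs, members$sequence)]
  total <- sum(reads)
  if (total <= 0) stop("cluster with zero total reads")
  on_strand <- function(s) {
    vapply(seqs, function(q) any(members$strand[members$sequence == q] == s),
           logical(1))
  }
  on_plus <- on_strand("+"); on_minus <- on_strand("-")
  top <- seqs[order_desc_with_tie(reads, seqs)[1]]
  ti <- match(top, seqs)
  sense <- if (on_plus[ti] && on_minus[ti]) {
    if (sum(reads[on_minus & !on_plus]) > sum(reads[on_plus & !on_minus]))
      "-" else "+"
  } else if (on_plus[ti]) "+" else "-"
  sense_seqs <- if (sense == "+") on_plus else on_minus
  strand_bias <- sum(reads[sense_seqs]) / total
  abundance_bias <- sum(head(sort(reads, decreasing = TRUE), 3)) / total
  list(strand_bias = strand_bias, abundance_bias = abundance_bias,
       sense_strand = sense)
}

# strand bias for a given sense choice: each distinct sequence counts once,
# on the sense strand iff it has a sense-strand hit in the cluster
strand_bias_for <- function(members, sense) {
  seqs <- unique(members$sequence)
  reads <- members$reads[match(seqs, members$sequence)]
  on_sense <- vapply(seqs, function(q) {
    any(members$strand[members$sequence == q] == sense)
  }, logical(1))
  sum(reads[on_sense]) / sum(reads)
}

#' Validate a precursor hairpin for a mature/star duplex
#'
#' Folds the precursor with `fold_fn` and counts duplex mismatches: mature
#' positions not paired to a star position, and vice versa, taking the larger
#' of the two arm counts. The terminal two nucleotides of each arm (the 2-nt
#' 3' overhangs of a canonical DCL duplex) are excluded from counting. The
#' duplex is accepted when the mismatch count is <= `max_mismatch` and the
#' two arms pair with each other (opposite arms of one stem).
#'
#' @param precursor_seq precursor sequence (plus-orientation of the locus).
#' @param mature_off,mature_len 0-based offset and length of the mature arm
#'   within the precursor.
#' @param star_off,star_len offset and length of the star arm.
#' @param fold_fn folding function (default [fold_nussinov()]).
#' @param max_mismatch maximum allowed duplex mismatches (default 4).
#' @return list with `structure` (dot-bracket), `duplex_mismatches`,
#'   `accepted`, and `pairs` (1-based partner vector).
#' @export
validate_hairpin <- function(precursor_seq, mature_off, mature_len,
                             star_off, star_len,
                             fold_fn = fold_nussinov, max_mismatch = 4L) {
  db <- fold_fn(precursor_seq)
  partner <- dotbracket_pairs(db)
  m_idx <- (mature_off + 1L):(mature_off + mature_len)   # 1-based
  s_idx <- (star_off + 1L):(star_off + star_len)
  # exclude the 2-nt 3' overhang at each arm's 3' end
  m_core <- head(m_idx, -2L)
  s_core <- head(s_idx, -2L)
  m_bad <- sum(is.na(partner[m_core]) | !(partner[m_core] %in% s_idx))
  s_bad <- sum(is.na(partner[s_core]) | !(partner[s_core] %in% m_idx))
  mm <- max(m_bad, s_bad)
  opposite <- sum(partner[m_core] %in% s_idx, na.rm = TRUE) >= length(m_core) / 2
  list(structure = db, duplex_mismatches = mm,
       accepted = (mm <= max_mismatch) && opposite, pairs = partner)
}

# geometry check: star 5' end consistent, after folding, with a duplex
# having 2-nt 3' overhangs (see canonical duplex: partner(mature_3'-2) is the
# star 5' start; partner(mature_5') + 2 is the star 3' end), +-tolerance.
duplex_geometry_ok <- function(partner, mature_off, mature_len,
                               star_off, star_len, tol = 3L) {
  m1 <- mature_off + 1L
  m2 <- mature_off + mature_len
  s1 <- star_off + 1L
  s2 <- star_off + star_len
  ok <- FALSE
  p <- partner[m2 - 2L]
  if (!is.na(p)) ok <- ok || abs(p - s1) <= tol
  p <- partner[m1]
  if (!is.na(p)) ok <- ok || abs(p + 2L - s2) <= tol
  ok
}

#' Search mature/star duplex pairs within one cluster
#'
#' The mature is the most abundant sRNA of the cluster (lexicographic
#' tie-break); star candidates are distinct same-strand sRNAs whose start
#' lies within `max_distance` nt and whose position is consistent, after
#' folding the extracted precursor, with a duplex having 2-nt 3' overhangs
#' (allowing `shift_tolerance` nt deviation). The most abundant validating
#' star wins.
#'
#' @param members output of the internal cluster-member tally (distinct
#'   sequence/strand records with `reads`); must all share one `seqid`.
#' @param genome a [Biostrings::DNAStringSet].
#' @param sense_strand strand of the mature sRNA.
#' @param fold_fn folding function.
#' @param max_distance maximum mature-to-star start distance (default 450).
#' @param shift_tolerance positional tolerance in nt (default 3).
#' @param flank precursor flank beyond the duplex span (default 20).
#' @param max_mismatch maximum duplex mismatches (default 4).
#' @return one-row data frame describing the accepted locus, or NULL.
#' @export
find_duplex_pairs <- function(members, genome, sense_strand,
                              fold_fn = fold_nussinov,
                              max_distance = 450L, shift_tolerance = 3L,
                              flank = 20L, max_mismatch = 4L) {
  sense <- members[members$strand == sense_strand, , drop = FALSE]
  if (nrow(sense) < 2) return(NULL)
  o <- order_desc_with_tie(sense$reads, sense$sequence)
  sense <- sense[o, , drop = FALSE]
  mature <- sense[1, ]
  chrlen <- length(genome[[mature$seqid]])
  for (i in 2:nrow(sense)) {
    star <- sense[i, ]
    if (star$sequence == mature$sequence) next
    if (abs(star$start - mature$start) > max_distance) next
    if (interval_overlap(mature$start, mature$end, star$start, star$end) > 0) next
    pre_start <- max(0L, min(mature$start, star$start) - flank)
    pre_end <- min(chrlen, max(mature$end, star$end) + flank)
    pre_seq <- as.character(Biostrings::subseq(genome[[mature$seqid]],
                                               pre_start + 1L, pre_end))
    if (sense_strand == "-") {
      pre_seq <- revcomp(pre_seq)
      m_off <- pre_end - mature$end
      s_off <- pre_end - star$end
    } else {
      m_off <- mature$start - pre_start
      s_off <- star$start - pre_start
    }
    m_len <- mature$end - mature$start
    s_len <- star$end - star$start
    val <- validate_hairpin(pre_seq, m_off, m_len, s_off, s_len,
                            fold_fn = fold_fn, max_mismatch = max_mismatch)
    if (!val$accepted) next
    if (!duplex_geometry_ok(val$pairs, m_off, m_len, s_off, s_len,
                            tol = shift_tolerance)) next
    return(data.frame(
      seqid = mature$seqid, strand = sense_strand,
      pre_start = pre_start, pre_end = pre_end,
      precursor_seq = pre_seq,
      mature_seq = mature$sequence, mature_start = mature$start,
      mature_end = mature$end, mature_reads = mature$reads,
      star_seq = star$sequence, star_start = star$start,
      star_end = star$end, star_reads = star$reads,
      duplex_mismatches = val$duplex_mismatches,
      structure = val$structure,
      stringsAsFactors = FALSE))
  }
  NULL
}

#' Discover miRNA loci on one reference
#'
#' Runs the full locus search: abundance/copy-number pre-filter, proximity
#' clustering, strand-bias (>= `min_strand_bias`) and abundance-bias
#' (>= `min_abundance_bias`) filters, then duplex-pair search with hairpin
#' validation. Every returned locus satisfies all four printed thresholds.
#'
#' @param srnas an `srna_set`.
#' @param hits alignment hits of `srnas` on `genome` from [map_exact()].
#' @param genome a [Biostrings::DNAStringSet].
#' @param source label recorded per locus (e.g. `"A2-genome"`).
#' @param min_total,max_genome_hits pre-filter thresholds (10, 5000).
#' @param max_gap cluster gap (default 200 nt).
#' @param min_strand_bias,min_abundance_bias locus bias thresholds (0.8, 0.6).
#' @param max_distance,shift_tolerance,flank,max_mismatch duplex-search
#'   parameters (450, 3, 20, 4).
#' @param fold_fn folding function (default [fold_nussinov()]).
#' @return data frame of accepted loci (one row per locus), including bias
#'   values, duplex mismatch counts and the dot-bracket structure.
#' @export
discover_mirna_loci <- function(srnas, hits, genome, source = "genome",
                                min_total = 10, max_genome_hits = 5000,
                                max_gap = 200L,
                                min_strand_bias = 0.8,
                                min_abundance_bias = 0.6,
                                max_distance = 450L, shift_tolerance = 3L,
                                flank = 20L, max_mismatch = 4L,
                                fold_fn = fold_nussinov) {
  # the abundance/copy-number filter selects candidate matures; clustering,
  # bias tallies and the star search see every mapped sRNA at the locus
  cand <- candidate_filter(srnas, hit_counts(hits),
                           min_total = min_total,
                           max_genome_hits = max_genome_hits)
  if (!nrow(hits)) return(empty_mirna_loci())
  hits <- cluster_hits(hits, max_gap = max_gap)
  out <- list()
  for (cl in unique(hits$cluster)) {
    chits <- hits[hits$cluster == cl, , drop = FALSE]
    mem <- cluster_members(chits, srnas)
    if (sum(mem$reads) <= 0) next
    b <- locus_biases(mem)
    seqs <- unique(mem$sequence)
    reads <- mem$reads[match(seqs, mem$sequence)]
    mature_seq <- seqs[order_desc_with_tie(reads, seqs)[1]]
    if (!(mature_seq %in% cand$sequence)) next
    if (b$abundance_bias < min_abundance_bias) next
    # a mature mapping to both strands of the locus (perfect duplex arm)
    # makes the sense strand ambiguous: try the preferred strand first,
    # then the alternative, keeping the first validating duplex
    cand_strands <- unique(c(b$sense_strand,
                             mem$strand[mem$sequence == mature_seq]))
    for (s in cand_strands) {
      sb <- strand_bias_for(mem, s)
      if (sb < min_strand_bias) next
      loc <- find_duplex_pairs(mem, genome, s,
                               fold_fn = fold_fn,
                               max_distance = max_distance,
                               shift_tolerance = shift_tolerance,
                               flank = flank, max_mismatch = max_mismatch)
      if (is.null(loc)) next
      loc$strand_bias <- sb
      loc$abundance_bias <- b$abundance_bias
      loc$source <- source
      out[[length(out) + 1L]] <- loc
      break
    }
  }
  if (!length(out)) return(empty_mirna_loci())
  res <- do.call(rbind, out)
  res <- res[order(res$seqid, res$pre_start, method = "radix"), ]
  res$locus_id <- sprintf("MIR-%s-%04d", source, seq_len(nrow(res)))
  rownames(res) <- NULL
  res
}

empty_mirna_loci <- function() {
  data.frame(seqid = character(), strand = character(),
             pre_start = integer(), pre_end = integer(),
             precursor_seq = character(), mature_seq = character(),
             mature_start = integer(), mature_end = integer(),
             mature_reads = numeric(), star_seq = character(),
             star_start = integer(), star_end = integer(),
             star_reads = numeric(), duplex_mismatches = integer(),
             structure = character(), strand_bias = numeric(),
             abundance_bias = numeric(), source = character(),
             locus_id = character(), stringsAsFactors = FALSE)
}
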
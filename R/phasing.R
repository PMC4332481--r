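# 21-nt phased siRNA detection: hypergeometric phasing statistic over
# occupied transcript positions, post-filters (>=2 pha-siRNAs, max read
# count >=5, phased ratio >=0.6) and miRNA initiator prediction with a
# psRNATarget-style complementarity penalty.

#' Phase register occupancy of a transcript window
#'
#' The window is `[anchor, anchor + phase * m)`. `N` is the number of
#' candidate positions (`phase * m`), `n` the number of distinct occupied
#' positions inside the window, and `k` the number of those congruent to the
#' anchor modulo `phase` (in-register). Positions are 5'-start coordinates;
#' minus-strand hits must be shifted +2 nt by the caller before registration
#' (2-nt 3' overhang geometry of DCL products, see [register_positions()]).
#'
#' @param positions integer vector of occupied positions (0-based, distinct
#'   or not; duplicates are collapsed).
#' @param anchor window anchor (0-based).
#' @param m number of phase cycles (>= 2).
#' @param phase phase length in nt (default 21).
#' @return list with `N`, `n`, `k`.
#' @export
phase_register_counts <- function(positions, anchor, m, phase = 21L) {
  if (m < 2) stop("m must be >= 2")
  N <- as.integer(phase * m)
  pos <- unique(positions[positions >= anchor & positions < anchor + N])
  n <- length(pos)
  k <- sum((pos - anchor) %% phase == 0L)
  list(N = N, n = n, k = as.integer(k))
}

#' Hypergeometric phasing p-value
#'
#' Under the null that `n` occupied positions are drawn uniformly without
#' replacement from `N = phase * m` candidate positions, of which `m` are
#' in-register, the p-value is the upper tail of in-register occupancy:
#' \deqn{p = \sum_{j=k}^{\min(n,m)} \binom{m}{j}\binom{N-m}{n-j} /
#'   \binom{N}{n}.}
#' Computed in log space (no overflow for `N` up to 1e4).
#'
#' @param N candidate positions (`phase * m`, a multiple of `phase`).
#' @param n occupied positions, `0 <= n <= N`.
#' @param k_obs observed in-register occupancy, `0 <= k_obs <= min(n, m)`.
#' @param phase phase length (default 21).
#' @return the p-value in `(0, 1]`.
#' @examples
#' phasing_pvalue(63, 4, 3) # ~1.007e-4
#' @export
phasing_pvalue <- function(N, n, k_obs, phase = 21L) {
  if (N %% phase != 0) stop("N must be a multiple of the phase length")
  m <- N %/% phase
  if (n < 0 || n > N) stop("n out of range")
  if (k_obs < 0 || k_obs > min(n, m)) stop("k_obs out of range [0, min(n, m)]")
  if (k_obs == 0) return(1)
  j <- k_obs:min(n, m)
  lt <- lchoose(m, j) + lchoose(N - m, n - j) - lchoose(N, n)
  mx <- max(lt)
  exp(mx) * sum(exp(lt - mx))
}

#' Phase-register positions of transcript hits
#'
#' Converts alignment hits on transcripts to register positions: the 5'
#' start for plus-strand hits, start + 2 for minus-strand hits.
#'
#' @param tx_hits hits from [map_exact()] against transcript sequences.
#' @return `tx_hits` with an added `pos` column.
#' @export
register_positions <- function(tx_hits) {
  tx_hits$pos <- ifelse(tx_hits$strand == "-", tx_hits$start + 2L,
                        tx_hits$start)
  tx_hits
}

#' Call phased-siRNA-yielding transcripts (PYTs)
#'
#' Scans every occupied position of each transcript as a window anchor
#' (window of `m` cycles of `phase` nt, truncated at the transcript end),
#' computes the hypergeometric phasing p-value, keeps windows with
#' `p < max_p`, merges overlapping significant windows per transcript
#' (keeping the minimal p-value and its anchor), and applies the three
#' post-filters: at least `min_pha` distinct pha-siRNAs, at least one
#' pha-siRNA with total reads >= `min_max_reads`, and an in-register read
#' fraction >= `min_ratio`.
#'
#' @param tx_hits transcript hits from [map_exact()] (both-strand or
#'   sense-only mapping, per upstream choice).
#' @param srnas the `srna_set` (for total read counts).
#' @param tx_lengths named integer vector of transcript lengths.
#' @param phase phase length (21 nt).
#' @param m window size in cycles (default 11).
#' @param max_p p-value threshold (default 1e-3).
#' @param min_pha minimum distinct pha-siRNAs (default 2).
#' @param min_max_reads minimum of the maximum pha-siRNA read count (5).
#' @param min_ratio minimum in-register read fraction (0.6).
#' @return data frame of phased loci: `transcript`, `start`, `end`,
#'   `anchor`, `N`, `n`, `k`, `p_value`, `n_pha`, `max_pha_reads`,
#'   `phased_ratio`, `pha_seqs` (comma-joined).
#' @export
call_pyts <- function(tx_hits, srnas, tx_lengths, phase = 21L, m = 11L,
                      max_p = 1e-3, min_pha = 2L, min_max_reads = 5,
                      min_ratio = 0.6) {
  empty <- data.frame(transcript = character(), start = integer(),
                      end = integer(), anchor = integer(), N = integer(),
                      n = integer(), k = integer(), p_value = numeric(),
                      n_pha = integer(), max_pha_reads = numeric(),
                      phased_ratio = numeric(), pha_seqs = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(tx_hits)) return(empty)
  tx_hits <- register_positions(tx_hits)
  tx_hits$reads <- srnas$total_count[match(tx_hits$sequence, srnas$sequence)]
  tx_hits$reads[is.na(tx_hits$reads)] <- 0
  out <- list()
  for (tid in unique(tx_hits$seqid)) {
    h <- tx_hits[tx_hits$seqid == tid, , drop = FALSE]
    L <- tx_lengths[[tid]]
    if (is.null(L) || is.na(L)) next
    pos <- sort(unique(h$pos))
    wins <- list()
    for (anchor in pos) {
      m_eff <- min(m, (L - anchor) %/% phase)
      if (m_eff < 2) next
      prc <- phase_register_counts(h$pos, anchor, m_eff, phase)
      p <- phasing_pvalue(prc$N, prc$n, prc$k, phase)
      if (p < max_p) {
        wins[[length(wins) + 1L]] <- data.frame(
          anchor = anchor, N = prc$N, n = prc$n, k = prc$k, p = p)
      }
    }
    if (!length(wins)) next
    w <- do.call(rbind, wins)
    w$start <- w$anchor
    w$end <- w$anchor + w$N
    w <- w[order(w$start), , drop = FALSE]
    # merge overlapping significant windows
    grp <- integer(nrow(w)); cur <- 1L; last_end <- w$end[1]; grp[1] <- 1L
    if (nrow(w) > 1) for (i in 2:nrow(w)) {
      if (w$start[i] < last_end) {
        grp[i] <- cur
        last_end <- max(last_end, w$end[i])
      } else {
        cur <- cur + 1L
        grp[i] <- cur
        last_end <- w$end[i]
      }
    }
    for (g in unique(grp)) {
      wg <- w[grp == g, , drop = FALSE]
      best <- wg[order(wg$p, wg$anchor)[1], ]
      lo <- min(wg$start); hi <- max(wg$end)
      hw <- h[h$pos >= lo & h$pos < hi, , drop = FALSE]
      in_reg <- (hw$pos - best$anchor) %% phase == 0L
      pha_seq <- sort(unique(hw$sequence[in_reg]))
      if (!length(pha_seq)) next
      pha_reads <- srnas$total_count[match(pha_seq, srnas$sequence)]
      # window read tallies count each distinct (sequence, pos) once
      key <- !duplicated(paste(hw$sequence, hw$pos))
      total_reads <- sum(hw$reads[key])
      inreg_reads <- sum(hw$reads[key & in_reg])
      locus <- data.frame(
        transcript = tid, start = lo, end = hi,
        anchor = best$anchor, N = best$N, n = best$n, k = best$k,
        p_value = best$p, n_pha = length(pha_seq),
        max_pha_reads = max(pha_reads),
        phased_ratio = inreg_reads / total_reads,
        pha_seqs = paste(pha_seq, collapse = ","),
        stringsAsFactors = FALSE)
      if (locus$n_pha >= min_pha && locus$max_pha_reads >= min_max_reads &&
          locus$phased_ratio >= min_ratio) {
        out[[length(out) + 1L]] <- locus
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$transcript, res$start, method = "radix"), ]
  rownames(res) <- NULL
  res
}

#' Complementarity penalty (expectation) of a miRNA target site
#'
#' psRNATarget-style penalty over the first `scoring_len` positions from the
#' miRNA 5' end, aligned ungapped to the site read 3'->5': each mismatch
#' scores 1.0, each G:U wobble 0.5, and penalties are doubled at miRNA
#' positions 2-13 (the seed-extended region). Lower is better. (The scheme's
#' indel penalty of 2.0 never applies in this ungapped implementation.)
#'
#' @param mirna mature miRNA sequence (5'->3').
#' @param site target site on the transcript (5'->3'), at least
#'   `scoring_len` nt; its last (3'-most) base is opposite miRNA position 1.
#' @param scoring_len complementarity scoring length (default 18).
#' @return the expectation (penalty sum), or `NA` when the site is shorter
#'   than `scoring_len`.
#' @export
target_penalty_score <- function(mirna, site, scoring_len = 18L) {
  mir <- strsplit(dna_canon(mirna), "")[[1]]
  st <- strsplit(dna_canon(site), "")[[1]]
  if (length(mir) < scoring_len || length(st) < scoring_len) return(NA_real_)
  mir <- mir[seq_len(scoring_len)]
  st <- rev(st)[seq_len(scoring_len)]       # target base opposite position i
  pen <- numeric(scoring_len)
  for (i in seq_len(scoring_len)) {
    a <- mir[i]; b <- st[i]
    wc <- (a == "A" && b == "T") || (a == "T" && b == "A") ||
      (a == "G" && b == "C") || (a == "C" && b == "G")
    gu <- (a == "G" && b == "T") || (a == "T" && b == "G")
    pen[i] <- if (wc) 0 else if (gu) 0.5 else 1
    if (i >= 2 && i <= 13) pen[i] <- pen[i] * 2
  }
  sum(pen)
}

#' Predict miRNA initiators of phased loci
#'
#' Slides each miRNA along the transcript region within `flank` nt of each
#' phased locus, scores candidate sites with [target_penalty_score()], and
#' calls an initiator when the expectation is <= `max_e` and the predicted
#' cleavage position (opposite miRNA positions 10-11) falls within
#' `max_shift` nt of a phase-register boundary of the locus. The best site
#' per (miRNA, locus) is reported.
#'
#' @param mirnas data frame with `id` and `sequence` of mature miRNAs.
#' @param phased_loci output of [call_pyts()].
#' @param tx_seqs transcript [Biostrings::DNAStringSet].
#' @param max_e maximum expectation (default 4.0).
#' @param flank maximum distance from the phased region (default 148 nt).
#' @param max_shift allowed shift from the in-register cleavage site (1 nt).
#' @param scoring_len complementarity scoring length (default 18).
#' @param phase phase length (21).
#' @return data frame of calls: `mirna`, `transcript`, `locus_start`,
#'   `site_start`, `site_end`, `expectation`, `cleavage`, `shift`.
#' @export
predict_initiators <- function(mirnas, phased_loci, tx_seqs, max_e = 4.0,
                               flank = 148L, max_shift = 1L,
                               scoring_len = 18L, phase = 21L) {
  empty <- data.frame(mirna = character(), transcript = character(),
                      locus_start = integer(), site_start = integer(),
                      site_end = integer(), expectation = numeric(),
                      cleavage = integer(), shift = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(mirnas) || !nrow(phased_loci)) return(empty)
  out <- list()
  for (li in seq_len(nrow(phased_loci))) {
    loc <- phased_loci[li, ]
    tseq <- as.character(tx_seqs[[loc$transcript]])
    L <- nchar(tseq)
    e_lo <- max(scoring_len, loc$start - flank)
    e_hi <- min(L, loc$end + flank + scoring_len)
    if (e_lo > e_hi) next
    for (mi in seq_len(nrow(mirnas))) {
      best <- NULL
      for (e in e_lo:e_hi) {
        site <- substr(tseq, e - scoring_len + 1L, e)
        sc <- target_penalty_score(mirnas$sequence[mi], site, scoring_len)
        if (is.na(sc) || sc > max_e) next
        cleave <- e - 10L
        d <- (cleave - loc$anchor) %% phase
        shift <- if (d <= phase / 2) d else d - phase
        if (abs(shift) > max_shift) next
        cand <- data.frame(
          mirna = mirnas$id[mi], transcript = loc$transcript,
          locus_start = loc$start, site_start = e - scoring_len,
          site_end = e, expectation = sc, cleavage = cleave,
          shift = as.integer(shift), stringsAsFactors = FALSE)
        if (is.null(best) || sc < best$expectation ||
            (sc == best$expectation && abs(shift) < abs(best$shift))) {
          best <- cand
        }
      }
      if (!is.null(best)) out[[length(out) + 1L]] <- best
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
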
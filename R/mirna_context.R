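# Conservation typing against a known-miRNA catalogue, family assignment,
# protein-coding-gene context typing and origin sharing.

#' Substitution distance between two sequences
#'
#' Best ungapped sliding alignment: the distance at a given offset is the
#' Hamming distance over the overlapping stretch plus one substitution per
#' overhanging nucleotide on either sequence; the minimum over all offsets
#' with at least one overlapping position is returned. Equal-length
#' sequences at offset zero reduce to plain Hamming distance.
#'
#' @param a,b sequences (DNA alphabet; U tolerated).
#' @return integer substitution count.
#' @export
substitution_distance <- function(a, b) {
  a <- strsplit(dna_canon(a), "")[[1]]
  b <- strsplit(dna_canon(b), "")[[1]]
  la <- length(a); lb <- length(b)
  best <- Inf
  for (off in (-(lb - 1L)):(la - 1L)) {
    ia <- max(1L, 1L + off):min(la, lb + off)
    ib <- ia - off
    mism <- sum(a[ia] != b[ib])
    d <- mism + (la - length(ia)) + (lb - length(ib))
    if (d < best) best <- d
  }
  as.integer(best)
}

#' Read a known-miRNA catalogue from FASTA
#'
#' Family labels are parsed from the name: the `miR<number><letters>` token
#' with any species prefix and variant suffix stripped (e.g.
#' `gma-miR156a-5p` -> `miR156`).
#'
#' @param path FASTA file of known mature miRNAs.
#' @return data frame with `name`, `family`, `sequence`.
#' @export
read_known_mirnas <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  fam <- sub("^.*?(miR[0-9]+).*$", "\\1", nm, ignore.case = TRUE)
  fam[!grepl("miR[0-9]+", nm, ignore.case = TRUE)] <- nm[!grepl("miR[0-9]+", nm, ignore.case = TRUE)]
  data.frame(name = nm, family = fam,
             sequence = dna_canon(as.character(ss)), stringsAsFactors = FALSE)
}

#' Classify mature miRNAs as conserved or lineage-specific
#'
#' A mature is conserved when its substitution distance
#' ([substitution_distance()]) to some known plant miRNA is at most
#' `max_subs`; it then inherits that miRNA's family label. Otherwise it is a
#' lineage-specific candidate.
#'
#' @param matures character vector of mature sequences.
#' @param known known-miRNA catalogue from [read_known_mirnas()] (columns
#'   `name`, `family`, `sequence`).
#' @param max_subs maximum substitutions (default 3).
#' @return data frame with `sequence`, `conservation`
#'   (`conserved`/`lineage_specific`), `family` (NA for lineage-specific),
#'   `best_match`, `substitutions`.
#' @export
classify_conservation <- function(matures, known, max_subs = 3L) {
  matures <- unique(dna_canon(matures))
  if (is.null(known) || !nrow(known)) {
    warning("empty known-miRNA catalogue: all matures lineage-specific")
    return(data.frame(sequence = matures, conservation = "lineage_specific",
                      family = NA_character_, best_match = NA_character_,
                      substitutions = NA_integer_, stringsAsFactors = FALSE))
  }
  res <- lapply(matures, function(m) {
    d <- vapply(known$sequence, substitution_distance, integer(1), a = m)
    # deterministic best match: min distance, then family, then name
    o <- order(d, known$family, known$name, method = "radix")[1]
    if (d[o] <= max_subs) {
      data.frame(sequence = m, conservation = "conserved",
                 family = known$family[o], best_match = known$name[o],
                 substitutions = d[o], stringsAsFactors = FALSE)
    } else {
      data.frame(sequence = m, conservation = "lineage_specific",
                 family = NA_character_, best_match = known$name[o],
                 substitutions = d[o], stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Group matures into miRNA families
#'
#' Conserved matures inherit their matched known family. Lineage-specific
#' matures are grouped by single linkage at a substitution distance of at
#' most `max_subs` and numbered `miRLS-0001`, ... in lexicographic order of
#' each family's smallest member sequence.
#'
#' @param assignments output of [classify_conservation()].
#' @param max_subs linkage radius for novel families (default 3).
#' @return `assignments` with a filled `family` column.
#' @export
assign_families <- function(assignments, max_subs = 3L) {
  ls_idx <- which(assignments$conservation == "lineage_specific")
  if (length(ls_idx)) {
    seqs <- assignments$sequence[ls_idx]
    n <- length(seqs)
    comp <- seq_len(n)
    find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
    if (n > 1) {
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        if (substitution_distance(seqs[i], seqs[j]) <= max_subs) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    root <- vapply(seq_len(n), find, integer(1))
    smallest <- vapply(split(seqs, root), min, character(1))
    fam_order <- rank(smallest, ties.method = "first")
    labels <- sprintf("miRLS-%04d", fam_order)
    assignments$family[ls_idx] <- labels[match(as.character(root),
                                               names(smallest))]
  }
  assignments
}

#' Type a precursor by protein-coding-gene context
#'
#' For each associated transcript whose supporting alignment passes the
#' association filter (identity >= 96\%, <= 3 mismatches, no indel, within
#' 5000 nt), the precursor is typed `intron` (fully inside an intron),
#' `exon` (fully inside an exon) or `junction` (spanning an exon-intron or
#' UTR-exon boundary). When two associated transcripts at one locus give
#' `intron` for one and `exon` for the other, the merged context is
#' `intron_exon` (an alternative-splicing candidate).
#'
#' @param precursor list/one-row data frame with `seqid`, `pre_start`,
#'   `pre_end`.
#' @param models transcript models from [read_transcripts()].
#' @param alignment_stats optional data frame (`transcript_id`, `identity`,
#'   `mismatches`, `indels`, `distance`) from a precomputed
#'   transcript-to-genome alignment; transcripts absent from it are assumed
#'   to pass.
#' @param min_identity,max_mismatches,max_indels,max_distance association
#'   thresholds (96, 3, 0, 5000).
#' @return data frame with one row per associated transcript (`transcript_id`,
#'   `context`) plus a `merged_context` column (same value each row).
#' @export
classify_gene_context <- function(precursor, models, alignment_stats = NULL,
                                  min_identity = 96, max_mismatches = 3L,
                                  max_indels = 0L, max_distance = 5000L) {
  tx <- models$transcripts
  tx <- tx[tx$seqid == precursor$seqid, , drop = FALSE]
  if (!is.null(alignment_stats) && nrow(alignment_stats)) {
    st <- alignment_stats
    pass <- st$transcript_id[st$identity >= min_identity &
                               st$mismatches <= max_mismatches &
                               st$indels <= max_indels &
                               st$distance <= max_distance]
    tx <- tx[tx$id %in% pass, , drop = FALSE]
  }
  ps <- precursor$pre_start; pe <- precursor$pre_end
  rows <- list()
  for (i in seq_len(nrow(tx))) {
    t <- tx[i, ]
    if (interval_overlap(ps, pe, t$start, t$end) <= 0) next
    ex <- models$exons[models$exons$transcript_id == t$id, , drop = FALSE]
    intr <- transcript_introns(models, t$id)
    in_exon <- any(ps >= ex$start & pe <= ex$end)
    in_intron <- nrow(intr) > 0 && any(ps >= intr$start & pe <= intr$end)
    ctx <- if (in_exon) "exon" else if (in_intron) "intron" else "junction"
    rows[[length(rows) + 1L]] <- data.frame(transcript_id = t$id,
                                            context = ctx,
                                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(transcript_id = character(), context = character(),
                      merged_context = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  merged <- if (all(c("intron", "exon") %in% out$context)) "intron_exon"
            else out$context[1]
  out$merged_context <- merged
  out
}

#' Venn counts of family origins
#'
#' Counts miRNA families by the subset of reference sources they were
#' detected from, separately for conserved and lineage-specific families.
#'
#' @param family_sources data frame with columns `family`, `conservation`,
#'   `source` (one row per family x source detection).
#' @param sources the universe of sources, default the three used in the
#'   pipeline.
#' @return data frame with `conservation`, `subset` (sources joined by
#'   `"&"`), `families`.
#' @export
origin_sharing <- function(family_sources,
                           sources = c("A2", "D5", "transcript")) {
  subsets <- unlist(lapply(seq_along(sources), function(k) {
    combn(sources, k, paste, collapse = "&", simplify = TRUE)
  }))
  res <- list()
  for (cons in unique(family_sources$conservation)) {
    fs <- family_sources[family_sources$conservation == cons, , drop = FALSE]
    per_fam <- vapply(split(fs$source, fs$family), function(s) {
      paste(sources[sources %in% s], collapse = "&")
    }, character(1))
    tab <- table(factor(per_fam, levels = subsets))
    res[[length(res) + 1L]] <- data.frame(
      conservation = cons, subset = subsets,
      families = as.integer(tab), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
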
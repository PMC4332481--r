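# Repeat-associated siRNAs: intersect non-miRNA sRNA hits with repeat
# features and build the repeat-class taxonomy with sub-genome sharing.

# controlled repeat-class vocabulary (taxonomy rows) plus "Others"
rasirna_classes <- function() {
  c("DNA/MuDR", "DNA/En-Spm", "DNA", "DNA/hAT", "DNA/Harbinger",
    "DNA/TcMar", "DNA/Mite", "RC/Helitron",
    "LTR", "LTR/Gypsy", "LTR/Copia", "Non LTR", "Retroelement",
    "LINE", "SINE", "rRNA", "Simple_repeat", "Others")
}

# class -> priority group; multi-class sRNAs are totalled once under the
# highest-priority group (retrotransposon > DNA transposon > rRNA >
# simple repeat > others); the priority order itself is a package choice.
repeat_class_group <- function(class) {
  grp <- rep("Others", length(class))
  grp[grepl("^(DNA|RC)", class) | class == "Transposon"] <- "DNA transposon"
  grp[grepl("^(LTR|LINE|SINE)", class) | class %in%
        c("Retroelement", "Retrotransposon", "Non LTR")] <- "Retrotransposon"
  grp[class == "rRNA"] <- "rRNA"
  grp[grepl("^Simple", class)] <- "Simple repeat"
  grp
}

repeat_group_priority <- function(group) {
  match(group, c("Retrotransposon", "DNA transposon", "rRNA",
                 "Simple repeat", "Others"))
}

#' Attribute sRNAs to repeat features
#'
#' Any sRNA (outside the exclusion set, typically the identified miRNAs)
#' with at least one alignment hit overlapping a repeat feature by >= 1 nt
#' is a ra-siRNA. One detail row is produced per (sequence, repeat class)
#' with the sub-genome tags of the supporting hits aggregated; the
#' `primary` flag marks, per sequence, the single highest-priority class
#' used for taxonomy totals.
#'
#' @param hits alignment hits from [map_exact()].
#' @param repeats repeat features from [read_repeats()].
#' @param exclude character vector of sequences to exclude (miRNAs).
#' @return data frame with `sequence`, `class`, `group`, `subgenomes`
#'   (comma-joined, sorted), `n_hits`, `primary`.
#' @export
assign_rasirnas <- function(hits, repeats, exclude = character()) {
  hits <- hits[!(hits$sequence %in% exclude), , drop = FALSE]
  empty <- data.frame(sequence = character(), class = character(),
                      group = character(), subgenomes = character(),
                      n_hits = integer(), primary = logical(),
                      stringsAsFactors = FALSE)
  if (!nrow(hits) || !nrow(repeats)) return(empty)
  unknown <- !(repeats$class %in% rasirna_classes())
  if (any(unknown)) {
    warning("unknown repeat class label(s) mapped to Others: ",
            paste(unique(repeats$class[unknown]), collapse = ", "))
    repeats$class[unknown] <- "Others"
  }
  rows <- list()
  for (chr in unique(hits$seqid)) {
    h <- hits[hits$seqid == chr, , drop = FALSE]
    r <- repeats[repeats$seqid == chr, , drop = FALSE]
    if (!nrow(r)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(h$start + 1L, h$end),
      IRanges::IRanges(r$start + 1L, r$end),
      minoverlap = 1L)
    if (!length(ov)) next
    qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    rows[[length(rows) + 1L]] <- data.frame(
      sequence = h$sequence[qi], class = r$class[si],
      subgenome = r$subgenome[si], stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  det <- do.call(rbind, rows)
  key <- paste(det$sequence, det$class, sep = "\r")
  agg <- lapply(split(seq_len(nrow(det)), key), function(ix) {
    data.frame(sequence = det$sequence[ix[1]], class = det$class[ix[1]],
               subgenomes = paste(sort(unique(det$subgenome[ix])),
                                  collapse = ","),
               n_hits = length(ix), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out$group <- repeat_class_group(out$class)
  prio <- repeat_group_priority(out$group)
  out$primary <- FALSE
  for (s in unique(out$sequence)) {
    ix <- which(out$sequence == s)
    best <- ix[order(prio[ix], out$class[ix], method = "radix")[1]]
    out$primary[best] <- TRUE
  }
  out <- out[order(out$sequence, out$class, method = "radix"),
             c("sequence", "class", "group", "subgenomes", "n_hits", "primary")]
  rownames(out) <- NULL
  out
}

#' Repeat-class taxonomy of ra-siRNAs
#'
#' Counts distinct ra-siRNA sequences per repeat class split by sub-genome
#' sharing; each sequence is counted once, under its primary
#' (highest-priority) class. The `total` column equals
#' `A2_only + D5_only + both` by construction.
#'
#' @param assignments output of [assign_rasirnas()].
#' @param subgenomes the two sub-genome tags (default `c("A2", "D5")`).
#' @return data frame with `class`, `A2_only`, `D5_only`, `both`, `total`
#'   (column names follow `subgenomes`).
#' @export
summarize_rasirna <- function(assignments, subgenomes = c("A2", "D5")) {
  a_tag <- subgenomes[1]; b_tag <- subgenomes[2]
  cls <- rasirna_classes()
  res <- data.frame(class = cls, stringsAsFactors = FALSE)
  res[[paste0(a_tag, "_only")]] <- 0L
  res[[paste0(b_tag, "_only")]] <- 0L
  res$both <- 0L
  res$total <- 0L
  prim <- assignments[assignments$primary, , drop = FALSE]
  if (nrow(prim)) {
    sgs <- strsplit(prim$subgenomes, ",", fixed = TRUE)
    cat3 <- vapply(sgs, function(s) {
      has_a <- a_tag %in% s; has_b <- b_tag %in% s
      if (has_a && has_b) "both" else if (has_a) "a" else if (has_b) "b" else "none"
    }, character(1))
    for (i in seq_len(nrow(res))) {
      sel <- prim$class == res$class[i]
      res[[2]][i] <- sum(sel & cat3 == "a")
      res[[3]][i] <- sum(sel & cat3 == "b")
      res$both[i] <- sum(sel & cat3 == "both")
    }
    res$total <- res[[2]] + res[[3]] + res$both
  }
  res
}
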
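# GFF3/BED annotation input and output. Files are 1-based closed (GFF3) or
# 0-based half-open (BED); everything returned to callers is 0-based
# half-open.

gr_to_df0 <- function(gr) {
  data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

df0_to_gr <- function(df, meta = NULL) {
  strand <- df$strand
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqid,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
  if (!is.null(meta)) S4Vectors::mcols(gr) <- meta
  gr
}

#' Load transcript models from GFF3
#'
#' Transcript features (`mRNA` or `transcript` type) need an `ID` attribute
#' and may carry a `Parent` (gene id); `exon` features attach to their
#' transcript via `Parent`. Transcripts without exon features are treated as
#' single-exon (intronless).
#'
#' @param path GFF3 file.
#' @return list with `transcripts` (id, gene_id, seqid, start, end, strand)
#'   and `exons` (transcript_id, start, end), 0-based half-open.
#' @export
read_transcripts <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  ty <- as.character(gr$type)
  tx <- gr[ty %in% c("mRNA", "transcript")]
  ex <- gr[ty == "exon"]
  txd <- gr_to_df0(tx)
  txd$id <- as.character(tx$ID)
  par <- tx$Parent
  txd$gene_id <- vapply(seq_along(tx), function(i) {
    p <- par[[i]]
    if (length(p)) as.character(p[1]) else txd$id[i]
  }, character(1))
  txd <- txd[, c("id", "gene_id", "seqid", "start", "end", "strand")]
  if (length(ex)) {
    exd <- gr_to_df0(ex)
    exd$transcript_id <- vapply(seq_along(ex), function(i) {
      p <- ex$Parent[[i]]
      if (length(p)) as.character(p[1]) else NA_character_
    }, character(1))
    exd <- exd[!is.na(exd$transcript_id), c("transcript_id", "start", "end")]
    exd <- exd[order(exd$transcript_id, exd$start), ]
  } else {
    exd <- data.frame(transcript_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  }
  # intronless transcripts get their whole span as one exon
  missing_tx <- setdiff(txd$id, exd$transcript_id)
  if (length(missing_tx)) {
    add <- txd[match(missing_tx, txd$id), ]
    exd <- rbind(exd, data.frame(transcript_id = add$id, start = add$start,
                                 end = add$end, stringsAsFactors = FALSE))
  }
  rownames(txd) <- rownames(exd) <- NULL
  list(transcripts = txd, exons = exd)
}

#' Introns of a transcript model
#' @param models output of [read_transcripts()].
#' @param transcript_id one transcript id.
#' @return data frame (start, end) of intron intervals, 0-based half-open.
#' @export
transcript_introns <- function(models, transcript_id) {
  ex <- models$exons[models$exons$transcript_id == transcript_id, , drop = FALSE]
  ex <- ex[order(ex$start), ]
  if (nrow(ex) < 2) {
    return(data.frame(start = integer(), end = integer()))
  }
  data.frame(start = ex$end[-nrow(ex)], end = ex$start[-1])
}

#' Load repeat features from GFF3 or BED
#'
#' GFF3 repeats carry the repeat class in a `repeat_class` (or `class`)
#' attribute and optionally a `subgenome` attribute; BED6 uses
#' `class|subgenome` in the name field. Missing sub-genome tags default to
#' the reference (seqid) name.
#'
#' @param path annotation file.
#' @param format `"auto"`, `"gff3"` or `"bed"`.
#' @return data frame (seqid, start, end, strand, class, subgenome),
#'   0-based half-open.
#' @export
read_repeats <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- rtracklayer::import(path, format = format)
  df <- gr_to_df0(gr)
  if (format == "gff3") {
    cls <- if (!is.null(gr$repeat_class)) as.character(gr$repeat_class)
           else if (!is.null(gr$class)) as.character(gr$class)
           else rep(NA_character_, length(gr))
    sg <- if (!is.null(gr$subgenome)) as.character(gr$subgenome)
          else rep(NA_character_, length(gr))
  } else {
    nm <- if (!is.null(gr$name)) as.character(gr$name) else rep("", length(gr))
    parts <- strsplit(nm, "|", fixed = TRUE)
    cls <- vapply(parts, function(p) if (length(p) >= 1) p[1] else NA_character_, character(1))
    sg <- vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_, character(1))
  }
  cls[is.na(cls) | cls == ""] <- "Others"
  sg[is.na(sg) | sg == ""] <- df$seqid[is.na(sg) | sg == ""]
  df$class <- cls
  df$subgenome <- sg
  df
}

#' Write miRNA loci as GFF3
#'
#' One `miRNA_primary_transcript` feature per locus plus child `miRNA`
#' (mature) and `miRNA_star` features.
#'
#' @param loci data frame from [discover_mirna_loci()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_mirna_gff3 <- function(loci, path) {
  feats <- list()
  for (i in seq_len(nrow(loci))) {
    l <- loci[i, ]
    id <- l$locus_id
    feats[[length(feats) + 1L]] <- data.frame(
      seqid = l$seqid, start = l$pre_start, end = l$pre_end, strand = l$strand,
      type = "miRNA_primary_transcript", ID = id, Parent = NA_character_)
    feats[[length(feats) + 1L]] <- data.frame(
      seqid = l$seqid, start = l$mature_start, end = l$mature_end,
      strand = l$strand, type = "miRNA", ID = paste0(id, ".mature"), Parent = id)
    feats[[length(feats) + 1L]] <- data.frame(
      seqid = l$seqid, start = l$star_start, end = l$star_end,
      strand = l$strand, type = "miRNA_star", ID = paste0(id, ".star"), Parent = id)
  }
  df <- do.call(rbind, feats)
  gr <- df0_to_gr(df)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- df$Parent
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
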
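# Read ingestion, collapsing, length filtering and exact genome placement.

#' Collapse raw small-RNA reads into distinct sequences with per-library counts
#'
#' Each library is either a character vector of raw read sequences (each read
#' counted once) or a data frame with columns `sequence` and `count` (already
#' collapsed input, e.g. from a sequence/count TSV). U and T are
#' interchangeable on input; sequences are stored in the DNA alphabet.
#' Records containing characters outside ACGTN are dropped with a warning
#' rather than aborting the run.
#'
#' @param libraries named list, one element per library. Unnamed input is
#'   given library ids `L1`, `L2`, ...
#' @return a data frame of class `srna_set` with columns `sequence`, `length`,
#'   `total_count` and one `count.<library>` column per library, ordered
#'   lexicographically by sequence.
#' @examples
#' collapse_reads(list(root = c("ACGTACGTACGTACGTACGTA", "ACGTACGTACGTACGTACGTA")))
#' @export
collapse_reads <- function(libraries) {
  if (is.character(libraries) || is.data.frame(libraries)) {
    libraries <- list(libraries)
  }
  if (is.null(names(libraries)) || any(names(libraries) == "")) {
    names(libraries) <- paste0("L", seq_along(libraries))
  }
  if (anyDuplicated(names(libraries))) {
    stop("library ids must be distinct")
  }
  per_lib <- lapply(libraries, function(lib) {
    if (is.data.frame(lib)) {
      seqs <- dna_canon(as.character(lib$sequence))
      cnts <- as.numeric(lib$count)
    } else {
      seqs <- dna_canon(as.character(lib))
      cnts <- rep(1, length(seqs))
    }
    ok <- valid_dna(seqs) & nchar(seqs) > 0 & cnts >= 0
    if (any(!ok)) {
      warning(sum(!ok), " record(s) with non-nucleotide characters dropped")
      seqs <- seqs[ok]; cnts <- cnts[ok]
    }
    if (length(seqs) == 0) {
      return(data.frame(sequence = character(), count = numeric()))
    }
    agg <- rowsum(cnts, group = seqs)
    data.frame(sequence = rownames(agg), count = as.numeric(agg[, 1]))
  })
  all_seqs <- sort(unique(unlist(lapply(per_lib, `[[`, "sequence"))))
  out <- data.frame(
    sequence = all_seqs,
    length = nchar(all_seqs),
    stringsAsFactors = FALSE
  )
  for (lib in names(per_lib)) {
    cnt <- setNames(per_lib[[lib]]$count, per_lib[[lib]]$sequence)
    v <- unname(cnt[all_seqs])
    v[is.na(v)] <- 0
    out[[paste0("count.", lib)]] <- v
  }
  cc <- count_columns(out)
  out$total_count <- if (length(cc)) rowSums(out[, cc, drop = FALSE]) else numeric(nrow(out))
  out <- out[, c("sequence", "length", "total_count", cc)]
  rownames(out) <- NULL
  class(out) <- c("srna_set", "data.frame")
  out
}

count_columns <- function(srnas) {
  grep("^count\\.", names(srnas), value = TRUE)
}

#' Library ids of an srna_set
#' @param srnas an `srna_set` from [collapse_reads()].
#' @return character vector of library ids.
#' @export
srna_libraries <- function(srnas) {
  sub("^count\\.", "", count_columns(srnas))
}

#' Retain small RNAs within a length window
#'
#' The pipeline default keeps 18-26 nt sequences; counts are untouched.
#'
#' @param srnas an `srna_set`.
#' @param min_len,max_len inclusive length bounds in nt.
#' @return the filtered `srna_set`.
#' @export
filter_by_length <- function(srnas, min_len = 18L, max_len = 26L) {
  if (min_len > max_len) stop("min_len must not exceed max_len")
  out <- srnas[srnas$length >= min_len & srnas$length <= max_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a collapsed small-RNA library from FASTA or TSV
#'
#' FASTA headers may carry the read count as a `_xN` suffix (e.g.
#' `>sr1_x154`); absent counts default to 1. TSV input is two columns,
#' sequence then count, without a header.
#'
#' @param path file path.
#' @param format `"fasta"` or `"tsv"`; guessed from the extension by default.
#' @return data frame with columns `sequence` and `count`, suitable as one
#'   element of the `libraries` list of [collapse_reads()].
#' @export
read_srna_library <- function(path, format = c("auto", "fasta", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE)) "fasta" else "tsv"
  }
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    cnt <- suppressWarnings(as.numeric(sub("^.*_x(\\d+)\\s*$", "\\1", names(ss))))
    cnt[is.na(cnt)] <- 1
    data.frame(sequence = dna_canon(as.character(ss)), count = cnt,
               stringsAsFactors = FALSE)
  } else {
    tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    data.frame(sequence = dna_canon(as.character(tab[[1]])),
               count = as.numeric(tab[[2]]), stringsAsFactors = FALSE)
  }
}

#' Load a reference genome (or transcript set) from FASTA
#' @param path FASTA file.
#' @return a [Biostrings::DNAStringSet] with first-word names.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Map small RNAs to a reference by exact full-length matching
#'
#' Reports every exact occurrence of each sequence on both strands. No
#' mismatches are allowed and reference Ns never match. Coordinates are
#' 0-based half-open; a minus-strand hit means the reference interval equals
#' the reverse complement of the read.
#'
#' @param srnas an `srna_set` (or data frame with a `sequence` column).
#' @param reference a [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param both_strands search the minus strand too (default TRUE).
#' @return data frame with columns `sequence`, `seqid`, `start`, `end`,
#'   `strand`, sorted by (seqid, start, end, strand, sequence). Sequences with
#'   no hit are absent.
#' @export
map_exact <- function(srnas, reference, both_strands = TRUE) {
  if (is.character(reference) && length(reference) == 1) {
    reference <- read_genome(reference)
  }
  seqs <- unique(as.character(srnas$sequence))
  seqs <- seqs[!grepl("N", seqs, fixed = TRUE)]
  res <- list()
  if (length(seqs)) {
    by_w <- split(seqs, nchar(seqs))
    for (w in names(by_w)) {
      pats <- by_w[[w]]
      pd_fwd <- Biostrings::PDict(Biostrings::DNAStringSet(pats))
      pd_rev <- if (both_strands) {
        Biostrings::PDict(Biostrings::reverseComplement(Biostrings::DNAStringSet(pats)))
      }
      for (chr in names(reference)) {
        subj <- reference[[chr]]
        m <- Biostrings::matchPDict(pd_fwd, subj)
        st <- Biostrings::startIndex(m)
        hit <- which(lengths(st) > 0)
        for (i in hit) {
          s1 <- st[[i]] - 1L  # to 0-based
          res[[length(res) + 1L]] <- data.frame(
            sequence = pats[i], seqid = chr,
            start = s1, end = s1 + as.integer(w), strand = "+",
            stringsAsFactors = FALSE)
        }
        if (both_strands) {
          m <- Biostrings::matchPDict(pd_rev, subj)
          st <- Biostrings::startIndex(m)
          hit <- which(lengths(st) > 0)
          for (i in hit) {
            s1 <- st[[i]] - 1L
            res[[length(res) + 1L]] <- data.frame(
              sequence = pats[i], seqid = chr,
              start = s1, end = s1 + as.integer(w), strand = "-",
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(res)) {
    return(data.frame(sequence = character(), seqid = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$seqid, out$start, out$end, out$strand, out$sequence,
                   method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Per-sequence genome hit counts
#' @param hits output of [map_exact()].
#' @return named integer vector, hit count per sequence (sequences absent from
#'   `hits` are simply absent).
#' @export
hit_counts <- function(hits) {
  if (!nrow(hits)) return(integer(0))
  tab <- table(hits$sequence)
  setNames(as.integer(tab), names(tab))
}
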
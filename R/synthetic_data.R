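# Synthetic reference + read generator with a serialized truth manifest.
# Every signal class the pipeline detects is implanted explicitly: miRNA
# hairpins (true reverse-complement stems with 2-nt 3' overhangs), repeat
# features of multiple classes, 21-nt phased transcripts with a miRNA
# trigger site, cis-NAT pairs in all four orientations, trans-NAT pairs
# with a >=100 nt complementary block, and positional background noise.

#' Default simulation configuration
#'
#' The defaults describe the stated desk-scale world: two 100-kb
#' sub-genome references, 20 hairpins with mature:star read ratio 20:1 and
#' <= 5\% antisense noise, 50 repeat features, 10 phased transcripts of 8
#' cycles plus unphased decoys, 8 cis pairs (two per orientation), 6 trans
#' pairs plus reversed-polarity decoys, and uniform background reads.
#'
#' @param seed RNG seed; identical config + seed gives identical output.
#' @param ... overrides of any default field.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 42L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    ref_length = 100000L,
    refs = c("A2", "D5"),
    n_hairpins = 20L,          # genomic hairpins, split across refs
    n_tx_hairpins = 2L,        # hairpins carried on transcripts
    n_conserved = 10L,         # matures present in the known catalogue
    hairpin_mismatches = c(0L, 0L, 1L, 2L),  # engineered duplex mismatches, recycled
    mature_reads = 100L,
    star_ratio = 20L,          # mature:star
    antisense_noise = 0.03,    # fraction of mature reads, antisense
    n_repeats = 50L,
    repeat_shared_fraction = 0.3,  # repeats copied to the other sub-genome
    repeat_reads_per_feature = 3L,
    n_phased = 10L,
    phased_cycles = 8L,
    n_decoy_tx = 20L,
    decoy_positions = 8L,
    n_cis = 8L,                # two per orientation
    cis_reads_per_pair = 10L,
    n_trans = 6L,
    n_trans_decoys = 3L,
    trans_block = 150L,
    trans_mismatch_rate = 0.04,
    background_reads = 200L,
    fiveprime_au_bias = 0.7,
    n_libraries = 2L
  )
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = c("sim_config", "list"))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_positions <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}

# sequential non-overlapping slot allocator over one reference
make_allocator <- function(ref_length, start = 1000L) {
  cursor <- start
  function(len) {
    gap <- sample(300:800, 1)
    s <- cursor + gap
    if (s + len > ref_length - 1000L) {
      stop("synthetic signals overflow the configured genome length")
    }
    cursor <<- s + len
    s
  }
}

#' Generate a synthetic reference with implanted signals
#'
#' Builds the genome FASTA content, transcript sequences, annotations and
#' the truth manifest. The random genome background is i.i.d. uniform ACGT;
#' signals are implanted at non-overlapping positions.
#'
#' @param config a [sim_config()].
#' @return list with `genome` ([Biostrings::DNAStringSet]), `tx_seqs`
#'   (transcript DNAStringSet), `tx_models` (transcript models as from
#'   [read_transcripts()]), `repeats` (repeat feature data frame), `known`
#'   (known-miRNA catalogue data frame) and `truth` (the manifest list).
#' @export
generate_reference <- function(config = sim_config()) {
  set.seed(config$seed)
  refs <- lapply(setNames(config$refs, config$refs), function(r) {
    strsplit(random_dna(config$ref_length), "")[[1]]
  })
  alloc <- lapply(setNames(config$refs, config$refs), function(r) {
    make_allocator(config$ref_length)
  })
  truth <- list(seed = config$seed, mirna = list(), repeats = list(),
                phased = list(), cis = list(), trans = list(),
                trans_decoys = list(), context = list())

  # --- miRNA hairpins --------------------------------------------------
  loop_len <- 15L
  flank <- 20L
  mk_hairpin <- function(idx) {
    mature <- paste0("T", random_dna(20))   # 5' U bias of plant miRNAs
    arm2 <- revcomp(mature)
    n_mm <- config$hairpin_mismatches[(idx - 1L) %% length(config$hairpin_mismatches) + 1L]
    if (n_mm > 0) {
      # mutate arm2 interior positions (away from both ends)
      pos <- sample(5:17, n_mm)
      arm2 <- mutate_positions(arm2, pos)
    }
    segment <- paste0(random_dna(flank), mature, random_dna(loop_len),
                      arm2, random_dna(flank))
    list(mature = mature, segment = segment, n_mm = n_mm)
  }
  hp_per_ref <- split(seq_len(config$n_hairpins),
                      rep(config$refs, length.out = config$n_hairpins))
  for (r in config$refs) {
    for (idx in hp_per_ref[[r]]) {
      hp <- mk_hairpin(idx)
      seg_len <- nchar(hp$segment)
      g0 <- alloc[[r]](seg_len)
      refs[[r]][(g0 + 1):(g0 + seg_len)] <- strsplit(hp$segment, "")[[1]]
      m_start <- g0 + flank
      s_start <- g0 + flank + 21L + loop_len + 2L
      star <- substr(hp$segment, flank + 21L + loop_len + 2L + 1L,
                     flank + 21L + loop_len + 2L + 21L)
      truth$mirna[[length(truth$mirna) + 1L]] <- list(
        id = sprintf("hp%02d", idx), seqid = r, source = r,
        pre_start = m_start - flank, pre_end = s_start + 21L + flank,
        mature_start = m_start, mature_end = m_start + 21L,
        star_start = s_start, star_end = s_start + 21L,
        mature = hp$mature, star = star, mismatches = hp$n_mm)
    }
  }

  # --- repeats ---------------------------------------------------------
  cls_pool <- c("LTR/Gypsy", "LTR/Copia", "LTR", "DNA/MuDR", "DNA/En-Spm",
                "DNA/hAT", "LINE", "Retroelement", "rRNA", "Simple_repeat")
  cls_w <- c(0.25, 0.15, 0.1, 0.12, 0.08, 0.05, 0.05, 0.1, 0.05, 0.05)
  rep_rows <- list()
  n_shared <- round(config$n_repeats * config$repeat_shared_fraction / 2)
  n_single <- config$n_repeats - 2L * n_shared
  rep_id <- 0L
  add_repeat <- function(r, len, seq_chars = NULL, class) {
    s <- alloc[[r]](len)
    if (is.null(seq_chars)) seq_chars <- strsplit(random_dna(len), "")[[1]]
    refs[[r]][(s + 1):(s + len)] <<- seq_chars
    rep_id <<- rep_id + 1L
    rep_rows[[length(rep_rows) + 1L]] <<- data.frame(
      seqid = r, start = s, end = s + len, strand = "+",
      class = class, subgenome = r, stringsAsFactors = FALSE)
    list(start = s, chars = seq_chars)
  }
  for (i in seq_len(n_shared)) {
    len <- sample(200:500, 1)
    class <- sample(cls_pool, 1, prob = cls_w)
    a <- add_repeat("A2", len, class = class)
    add_repeat("D5", len, seq_chars = a$chars, class = class)
    truth$repeats[[length(truth$repeats) + 1L]] <-
      list(class = class, shared = TRUE, len = len,
           a_start = a$start)
  }
  for (i in seq_len(n_single)) {
    r <- config$refs[(i - 1L) %% length(config$refs) + 1L]
    len <- sample(200:500, 1)
    class <- sample(cls_pool, 1, prob = cls_w)
    a <- add_repeat(r, len, class = class)
    truth$repeats[[length(truth$repeats) + 1L]] <-
      list(class = class, shared = FALSE, ref = r, len = len,
           a_start = a$start)
  }
  repeats <- do.call(rbind, rep_rows)

  # --- cis-NAT pairs on the genome ------------------------------------
  orientations <- rep(c("convergent", "divergent", "enclosed", "coincided"),
                      length.out = config$n_cis)
  tx_rows <- list(); exon_rows <- list()
  add_tx <- function(id, seqid, start, end, strand, exons = NULL) {
    tx_rows[[length(tx_rows) + 1L]] <<- data.frame(
      id = id, gene_id = id, seqid = seqid, start = start, end = end,
      strand = strand, stringsAsFactors = FALSE)
    if (is.null(exons)) exons <- data.frame(start = start, end = end)
    exon_rows[[length(exon_rows) + 1L]] <<- data.frame(
      transcript_id = id, start = exons$start, end = exons$end,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(config$n_cis)) {
    ori <- orientations[i]
    r <- config$refs[(i - 1L) %% length(config$refs) + 1L]
    g <- alloc[[r]](1500L)
    ida <- sprintf("cisA%02d", i); idb <- sprintf("cisB%02d", i)
    geom <- switch(ori,
      convergent = list(a = c(g, g + 800L, "+"), b = c(g + 600L, g + 1400L, "-")),
      divergent = list(a = c(g, g + 800L, "-"), b = c(g + 600L, g + 1400L, "+")),
      enclosed = list(a = c(g, g + 1200L, "+"), b = c(g + 300L, g + 700L, "-")),
      coincided = list(a = c(g, g + 900L, "+"), b = c(g, g + 900L, "-")))
    add_tx(ida, r, as.integer(geom$a[1]), as.integer(geom$a[2]), geom$a[3])
    add_tx(idb, r, as.integer(geom$b[1]), as.integer(geom$b[2]), geom$b[3])
    truth$cis[[length(truth$cis) + 1L]] <- list(
      pair_id = paste(ida, idb, sep = "|"), a = ida, b = idb, seqid = r,
      orientation = ori,
      overlap_start = max(as.integer(geom$a[1]), as.integer(geom$b[1])),
      overlap_end = min(as.integer(geom$a[2]), as.integer(geom$b[2])))
  }

  # --- protein-coding-gene context transcripts over hairpins -----------
  ctx_cases <- list(
    list(kind = "intron", hp = 1L),
    list(kind = "exon", hp = 2L),
    list(kind = "junction", hp = 3L),
    list(kind = "intron_exon", hp = 4L))
  for (cc in ctx_cases) {
    hp <- truth$mirna[[cc$hp]]
    ps <- hp$pre_start; pe <- hp$pre_end; r <- hp$seqid
    id <- sprintf("ctx_%s", cc$kind)
    if (cc$kind == "intron") {
      add_tx(id, r, ps - 300L, pe + 300L, "+",
             exons = data.frame(start = c(ps - 300L, pe + 50L),
                                end = c(ps - 50L, pe + 300L)))
    } else if (cc$kind == "exon") {
      add_tx(id, r, ps - 200L, pe + 200L, "+")
    } else if (cc$kind == "junction") {
      add_tx(id, r, ps - 300L, pe + 100L, "+",
             exons = data.frame(start = c(ps - 300L, pe + 50L),
                                end = c(ps + 30L, pe + 100L)))
    } else { # intron_exon: two transcripts, one intronic one exonic
      add_tx(paste0(id, "_i"), r, ps - 300L, pe + 300L, "+",
             exons = data.frame(start = c(ps - 300L, pe + 50L),
                                end = c(ps - 50L, pe + 300L)))
      add_tx(paste0(id, "_e"), r, ps - 150L, pe + 150L, "+")
    }
    truth$context[[length(truth$context) + 1L]] <-
      list(mirna_id = hp$id, kind = cc$kind)
  }

  genome <- Biostrings::DNAStringSet(vapply(refs, paste, character(1),
                                            collapse = ""))
  names(genome) <- config$refs

  # --- transcript sequences (phasing, decoys, trans pairs, cis/context) -
  tx_seq <- list()
  for (i in seq_len(config$n_phased)) {
    id <- sprintf("phas%02d", i)
    cyc <- config$phased_cycles
    L <- 60L + 21L * cyc + 40L
    anchor <- 60L
    hp <- truth$mirna[[(i - 1L) %% config$n_hairpins + 1L]]
    s <- strsplit(random_dna(L), "")[[1]]
    site <- strsplit(revcomp(hp$mature), "")[[1]]   # perfect complement
    s[(anchor - 11L + 1L):(anchor + 10L)] <- site
    tx_seq[[id]] <- paste(s, collapse = "")
    truth$phased[[length(truth$phased) + 1L]] <- list(
      id = id, anchor = anchor, cycles = cyc, trigger = hp$id,
      trigger_mature = hp$mature,
      site_start = anchor - 11L, site_end = anchor + 10L)
  }
  for (i in seq_len(config$n_decoy_tx)) {
    id <- sprintf("decoy%02d", i)
    tx_seq[[id]] <- random_dna(300L)
  }
  for (i in seq_len(config$n_trans)) {
    ida <- sprintf("transA%02d", i); idb <- sprintf("transB%02d", i)
    a <- random_dna(600L)
    blk_start <- sample(100:300, 1)
    blk <- substr(a, blk_start + 1L, blk_start + config$trans_block)
    cblk <- revcomp(blk)
    n_mut <- rbinom(1, config$trans_block, config$trans_mismatch_rate)
    if (n_mut > 0) cblk <- mutate_positions(cblk, sample(10:(config$trans_block - 10), n_mut))
    b_pos <- sample(100:300, 1)
    b <- paste0(random_dna(b_pos), cblk,
                random_dna(600L - b_pos - config$trans_block))
    tx_seq[[ida]] <- a; tx_seq[[idb]] <- b
    truth$trans[[length(truth$trans) + 1L]] <- list(
      pair_id = paste(ida, idb, sep = "|"), a = ida, b = idb,
      a_block_start = blk_start, a_block_end = blk_start + config$trans_block,
      b_block_start = b_pos, b_block_end = b_pos + config$trans_block,
      mutations = n_mut)
  }
  for (i in seq_len(config$n_trans_decoys)) {
    # reversed-polarity decoy: b carries a same-sense copy of a's block,
    # which aligns to a only in the non-complementary orientation
    ida <- sprintf("tdecA%02d", i); idb <- sprintf("tdecB%02d", i)
    a <- random_dna(600L)
    blk_start <- sample(100:300, 1)
    blk <- substr(a, blk_start + 1L, blk_start + config$trans_block)
    b_pos <- sample(100:300, 1)
    b <- paste0(random_dna(b_pos), blk,
                random_dna(600L - b_pos - config$trans_block))
    tx_seq[[ida]] <- a; tx_seq[[idb]] <- b
    truth$trans_decoys[[length(truth$trans_decoys) + 1L]] <- list(
      pair_id = paste(ida, idb, sep = "|"), a = ida, b = idb)
  }
  # transcript-borne hairpins
  for (i in seq_len(config$n_tx_hairpins)) {
    id <- sprintf("txhp%02d", i)
    hp <- mk_hairpin(config$n_hairpins + i)
    tx_seq[[id]] <- paste0(random_dna(50L), hp$segment, random_dna(50L))
    m_start <- 50L + flank
    s_start <- 50L + flank + 21L + loop_len + 2L
    star <- substr(hp$segment, flank + 21L + loop_len + 2L + 1L,
                   flank + 21L + loop_len + 2L + 21L)
    truth$mirna[[length(truth$mirna) + 1L]] <- list(
      id = id, seqid = id, source = "transcript",
      pre_start = m_start - flank, pre_end = s_start + 21L + flank,
      mature_start = m_start, mature_end = m_start + 21L,
      star_start = s_start, star_end = s_start + 21L,
      mature = hp$mature, star = star, mismatches = hp$n_mm)
  }
  # cis member and context transcript sequences (strand-aware extraction)
  txd <- do.call(rbind, tx_rows)
  for (i in seq_len(nrow(txd))) {
    t <- txd[i, ]
    sq <- substr(as.character(genome[[t$seqid]]), t$start + 1L, t$end)
    if (t$strand == "-") sq <- revcomp(sq)
    tx_seq[[t$id]] <- sq
  }
  tx_seqs <- Biostrings::DNAStringSet(unlist(tx_seq))

  # --- known-miRNA catalogue ------------------------------------------
  fam_pool <- c("miR156", "miR160", "miR166", "miR167", "miR172", "miR390",
                "miR393", "miR396", "miR399", "miR482", "miR530", "miR827")
  known_rows <- list()
  cons_idx <- seq_len(min(config$n_conserved, length(truth$mirna)))
  for (i in cons_idx) {
    fam <- fam_pool[(i - 1L) %% length(fam_pool) + 1L]
    m <- truth$mirna[[i]]$mature
    n_sub <- sample(0:3, 1)
    seqk <- if (n_sub > 0) mutate_positions(m, sample(21L, n_sub)) else m
    known_rows[[length(known_rows) + 1L]] <- data.frame(
      name = sprintf("syn-%sa", fam), family = fam, sequence = seqk,
      stringsAsFactors = FALSE)
    truth$mirna[[i]]$family <- fam
    truth$mirna[[i]]$conservation <- "conserved"
  }
  for (i in setdiff(seq_along(truth$mirna), cons_idx)) {
    truth$mirna[[i]]$family <- NA
    truth$mirna[[i]]$conservation <- "lineage_specific"
  }
  known <- do.call(rbind, known_rows)

  tx_models <- list(transcripts = txd, exons = do.call(rbind, exon_rows))
  list(genome = genome, tx_seqs = tx_seqs, tx_models = tx_models,
       repeats = repeats, known = known, truth = truth, config = config)
}

# sample a read start inside [lo, hi - len] preferring A/T first bases
biased_read_start <- function(chars, lo, hi, len, au_bias) {
  for (try in 1:10) {
    s <- sample(lo:(hi - len), 1)
    if (chars[s + 1L] %in% c("A", "T") || runif(1) > au_bias) return(s)
  }
  s
}

#' Simulate collapsed small-RNA libraries from a synthetic reference
#'
#' Produces reads for every implanted signal (mature/star at the configured
#' ratio with a little antisense noise, phased registers with at least one
#' pha-siRNA at >= 5 reads, 24-nt-biased repeat reads, NAT overlap reads,
#' decoy positions) plus uniform background, split across
#' `config$n_libraries` libraries.
#'
#' @param reference output of [generate_reference()].
#' @param config the same [sim_config()] used for the reference.
#' @return list of per-library data frames (`sequence`, `count`) suitable
#'   for [collapse_reads()], with the read origin recorded in
#'   `attr(, "origin")`.
#' @export
simulate_reads <- function(reference, config = reference$config) {
  set.seed(config$seed + 1L)
  genome_chars <- lapply(setNames(as.character(reference$genome),
                                  names(reference$genome)),
                         function(s) strsplit(s, "")[[1]])
  tx_chars <- lapply(setNames(as.character(reference$tx_seqs),
                              names(reference$tx_seqs)),
                     function(s) strsplit(s, "")[[1]])
  truth <- reference$truth
  reads <- list()
  add_read <- function(seq, count, origin) {
    reads[[length(reads) + 1L]] <<- data.frame(
      sequence = seq, count = count, origin = origin,
      stringsAsFactors = FALSE)
  }
  # miRNA duplex reads
  for (hp in truth$mirna) {
    add_read(hp$mature, config$mature_reads, "mirna")
    add_read(hp$star, max(1L, config$mature_reads %/% config$star_ratio),
             "mirna")
    n_anti <- round(config$mature_reads * config$antisense_noise)
    if (n_anti > 0 && hp$source != "transcript") {
      ch <- genome_chars[[hp$seqid]]
      w0 <- hp$mature_start + 4L
      anti <- revcomp(paste(ch[(w0 + 1):(w0 + 21L)], collapse = ""))
      add_read(anti, n_anti, "mirna_antisense")
    }
  }
  # repeat-derived 24-nt reads
  for (i in seq_len(nrow(reference$repeats))) {
    rr <- reference$repeats[i, ]
    ch <- genome_chars[[rr$seqid]]
    for (j in seq_len(config$repeat_reads_per_feature)) {
      s <- biased_read_start(ch, rr$start, rr$end, 24L,
                             config$fiveprime_au_bias)
      add_read(paste(ch[(s + 1):(s + 24L)], collapse = ""),
               sample(1:8, 1), "rasirna")
    }
  }
  # phased transcript reads
  for (ph in truth$phased) {
    ch <- tx_chars[[ph$id]]
    for (j in 0:(ph$cycles - 1L)) {
      s <- ph$anchor + 21L * j
      cnt <- if (j == 0L) sample(8:15, 1) else sample(5:12, 1)
      add_read(paste(ch[(s + 1):(s + 21L)], collapse = ""), cnt, "pha")
      if (j %% 3L == 1L) {
        # antisense partner with 2-nt 3' overhang: plus-interval start s-2,
        # registers back in phase after the +2 shift
        s2 <- s - 2L
        add_read(revcomp(paste(ch[(s2 + 1):(s2 + 21L)], collapse = "")),
                 sample(1:4, 1), "pha_antisense")
      }
    }
    # sparse off-register noise, kept far below the 0.6 ratio
    s <- ph$anchor + 10L
    add_read(paste(ch[(s + 1):(s + 21L)], collapse = ""), 1L, "pha_noise")
  }
  # decoy transcript reads at random positions
  for (i in seq_len(config$n_decoy_tx)) {
    id <- sprintf("decoy%02d", i)
    ch <- tx_chars[[id]]
    for (j in seq_len(config$decoy_positions)) {
      len <- sample(20:24, 1)
      s <- sample(0:(length(ch) - len), 1)
      add_read(paste(ch[(s + 1):(s + len)], collapse = ""),
               sample(1:20, 1), "decoy")
    }
  }
  # cis-nat reads: mostly overlap region, plus-biased
  for (cp in truth$cis) {
    ch <- genome_chars[[cp$seqid]]
    pair_tx <- reference$tx_models$transcripts
    a <- pair_tx[pair_tx$id == cp$a, ]
    for (j in seq_len(config$cis_reads_per_pair)) {
      len <- sample(21:24, 1)
      in_ov <- runif(1) < 0.75
      if (in_ov) {
        s <- biased_read_start(ch, cp$overlap_start, cp$overlap_end, len,
                               config$fiveprime_au_bias)
      } else {
        s <- biased_read_start(ch, a$start, a$end, len,
                               config$fiveprime_au_bias)
      }
      sq <- paste(ch[(s + 1):(s + len)], collapse = "")
      if (runif(1) > 0.66) sq <- revcomp(sq)
      add_read(sq, sample(2:8, 1), "cisnat")
    }
  }
  # trans-nat reads from the complementary blocks of both members
  for (tp in truth$trans) {
    for (member in c("a", "b")) {
      ch <- tx_chars[[tp[[member]]]]
      bs <- tp[[paste0(member, "_block_start")]]
      be <- tp[[paste0(member, "_block_end")]]
      for (j in 1:4) {
        len <- sample(21:24, 1)
        s <- sample(bs:(be - len), 1)
        add_read(paste(ch[(s + 1):(s + len)], collapse = ""),
                 sample(2:8, 1), "transnat")
      }
    }
  }
  # uniform background avoiding annotated repeats (by rejection)
  rep_iv <- reference$repeats
  for (j in seq_len(config$background_reads)) {
    r <- sample(names(genome_chars), 1)
    ch <- genome_chars[[r]]
    for (try in 1:20) {
      len <- sample(18:26, 1)
      s <- sample(0:(length(ch) - len), 1)
      riv <- rep_iv[rep_iv$seqid == r, , drop = FALSE]
      if (!nrow(riv) ||
          all(interval_overlap(s, s + len, riv$start, riv$end) <= 0)) break
    }
    sq <- paste(ch[(s + 1):(s + len)], collapse = "")
    if (runif(1) < 0.5) sq <- revcomp(sq)
    add_read(sq, sample(1:3, 1), "background")
  }
  all_reads <- do.call(rbind, reads)
  # split counts across libraries binomially
  libs <- paste0("lib", seq_len(config$n_libraries))
  out <- list()
  split_counts <- matrix(0L, nrow(all_reads), config$n_libraries)
  for (i in seq_len(nrow(all_reads))) {
    remaining <- all_reads$count[i]
    for (l in seq_len(config$n_libraries - 1L)) {
      x <- rbinom(1, remaining, 1 / (config$n_libraries - l + 1))
      split_counts[i, l] <- x
      remaining <- remaining - x
    }
    split_counts[i, config$n_libraries] <- remaining
  }
  for (l in seq_along(libs)) {
    keep <- split_counts[, l] > 0
    out[[libs[l]]] <- data.frame(sequence = all_reads$sequence[keep],
                                 count = split_counts[keep, l],
                                 stringsAsFactors = FALSE)
  }
  attr(out, "origin") <- all_reads
  out
}

#' Write a synthetic dataset to disk
#'
#' Emits exactly the formats the pipeline consumes: genome FASTA,
#' transcript FASTA, transcript GFF3, repeat GFF3, known-miRNA FASTA,
#' per-library sequence/count TSVs and a JSON truth manifest.
#'
#' @param reference output of [generate_reference()].
#' @param libraries output of [simulate_reads()].
#' @param dir output directory (created if needed).
#' @return named list of written paths.
#' @export
write_synthetic_dataset <- function(reference, libraries, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  paths$genome <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(reference$genome, paths$genome)
  paths$transcript_fasta <- file.path(dir, "transcripts.fa")
  Biostrings::writeXStringSet(reference$tx_seqs, paths$transcript_fasta)
  paths$transcript_gff <- file.path(dir, "transcripts.gff3")
  write_transcripts_gff3(reference$tx_models, paths$transcript_gff)
  paths$repeat_gff <- file.path(dir, "repeats.gff3")
  write_repeats_gff3(reference$repeats, paths$repeat_gff)
  paths$known_mirnas <- file.path(dir, "known_mirnas.fa")
  writeLines(paste0(">", reference$known$name, "\n", reference$known$sequence),
             paths$known_mirnas)
  paths$libraries <- character(0)
  for (lib in names(libraries)) {
    p <- file.path(dir, paste0(lib, ".tsv"))
    write.table(libraries[[lib]], p, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    paths$libraries <- c(paths$libraries, setNames(p, lib))
  }
  paths$manifest <- file.path(dir, "truth.json")
  jsonlite::write_json(reference$truth, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")
  paths
}

write_transcripts_gff3 <- function(models, path) {
  tx <- models$transcripts
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(tx))) {
    t <- tx[i, ]
    lines <- c(lines, paste(t$seqid, "srnaclass", "mRNA", t$start + 1L,
                            t$end, ".", t$strand, ".",
                            sprintf("ID=%s;Parent=%s", t$id, t$gene_id),
                            sep = "\t"))
    ex <- models$exons[models$exons$transcript_id == t$id, , drop = FALSE]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, paste(t$seqid, "srnaclass", "exon",
                              ex$start[j] + 1L, ex$end[j], ".", t$strand,
                              ".", sprintf("Parent=%s", t$id), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

write_repeats_gff3 <- function(repeats, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(repeats))) {
    r <- repeats[i, ]
    lines <- c(lines, paste(
      r$seqid, "srnaclass", "dispersed_repeat", r$start + 1L, r$end, ".",
      r$strand, ".",
      sprintf("ID=rep%04d;repeat_class=%s;subgenome=%s", i, r$class,
              r$subgenome), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Score pipeline calls against the truth manifest
#'
#' Matches calls to implanted signals per class: miRNA loci and PYT loci by
#' >= 50\% reciprocal interval overlap on the same reference, ra-siRNAs by
#' sequence identity, cis/trans pairs and initiators by exact id. Precision
#' is `NA` when there are no calls of a class.
#'
#' @param calls pipeline output from [run_pipeline()] (or a list with
#'   elements `mirna_loci`, `rasirna`, `pyts`, `cis_pairs`, `trans_pairs`,
#'   `initiators`).
#' @param truth the truth manifest from [generate_reference()].
#' @param origin optional read-origin table (`attr(libraries, "origin")`
#'   from [simulate_reads()]); required for the ra-siRNA row.
#' @return data frame with `class`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, plus an `orientation_accuracy` attribute for cis pairs.
#' @export
evaluate_recovery <- function(calls, truth, origin = NULL) {
  pr <- function(tp, fp, fn) {
    data.frame(tp = tp, fp = fp, fn = fn,
               precision = if (!is.na(fp) && tp + fp > 0) tp / (tp + fp)
                           else NA_real_,
               recall = if (!is.na(fn) && tp + fn > 0) tp / (tp + fn)
                        else NA_real_)
  }
  rows <- list()
  # miRNA loci: reciprocal >= 50% overlap
  tm <- truth$mirna
  called <- calls$mirna_loci
  matched_truth <- rep(FALSE, length(tm))
  matched_call <- rep(FALSE, nrow(called))
  for (i in seq_along(tm)) {
    t <- tm[[i]]
    for (j in seq_len(nrow(called))) {
      c <- called[j, ]
      if (c$seqid == t$seqid) {
        ov <- interval_overlap(t$pre_start, t$pre_end, c$pre_start, c$pre_end)
        if (ov >= 0.5 * (t$pre_end - t$pre_start) &&
            ov >= 0.5 * (c$pre_end - c$pre_start)) {
          matched_truth[i] <- TRUE
          matched_call[j] <- TRUE
        }
      }
      # one implanted duplex can be rediscovered through a transcript that
      # carries the same hairpin: identical mature/star is the same locus
      if (identical(c$mature_seq, t$mature) && identical(c$star_seq, t$star)) {
        matched_truth[i] <- TRUE
        matched_call[j] <- TRUE
      }
    }
  }
  rows$mirna_locus <- pr(sum(matched_truth), sum(!matched_call),
                         sum(!matched_truth))
  # ra-siRNAs by sequence set
  truth_ra <- if (!is.null(origin)) {
    unique(origin$sequence[origin$origin == "rasirna"])
  }
  if (!is.null(calls$rasirna) && !is.null(truth_ra)) {
    called_ra <- unique(calls$rasirna$sequence)
    tp <- length(intersect(called_ra, truth_ra))
    rows$rasirna <- pr(tp, length(setdiff(called_ra, truth_ra)),
                       length(setdiff(truth_ra, called_ra)))
  }
  # PYTs by transcript id
  truth_pyt <- vapply(truth$phased, `[[`, character(1), "id")
  called_pyt <- unique(calls$pyts$transcript)
  tp <- length(intersect(called_pyt, truth_pyt))
  rows$pyt <- pr(tp, length(setdiff(called_pyt, truth_pyt)),
                 length(setdiff(truth_pyt, called_pyt)))
  # cis pairs by id; orientation accuracy over matched pairs
  truth_cis <- vapply(truth$cis, `[[`, character(1), "pair_id")
  called_cis <- calls$cis_pairs$pair_id
  tp_ids <- intersect(called_cis, truth_cis)
  rows$cis_pair <- pr(length(tp_ids), length(setdiff(called_cis, truth_cis)),
                      length(setdiff(truth_cis, called_cis)))
  ori_ok <- 0L
  for (t in truth$cis) {
    if (t$pair_id %in% tp_ids) {
      called_ori <- calls$cis_pairs$orientation[
        calls$cis_pairs$pair_id == t$pair_id][1]
      if (identical(called_ori, t$orientation)) ori_ok <- ori_ok + 1L
    }
  }
  ori_acc <- if (length(tp_ids)) ori_ok / length(tp_ids) else NA_real_
  # trans pairs by id
  truth_tr <- vapply(truth$trans, `[[`, character(1), "pair_id")
  called_tr <- calls$trans_pairs$pair_id
  tp <- length(intersect(called_tr, truth_tr))
  rows$trans_pair <- pr(tp, length(setdiff(called_tr, truth_tr)),
                        length(setdiff(truth_tr, called_tr)))
  # initiators: trigger recovered per phased locus (matched by transcript
  # and trigger mature sequence)
  if (!is.null(calls$initiators)) {
    tp <- 0L; fn <- 0L
    for (ph in truth$phased) {
      hit <- any(calls$initiators$transcript == ph$id &
                   calls$initiators$mirna_sequence == ph$trigger_mature)
      if (hit) tp <- tp + 1L else fn <- fn + 1L
    }
    rows$initiator <- pr(tp, NA_integer_, fn)
  }
  res <- do.call(rbind, rows)
  res <- cbind(class = names(rows), res, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "orientation_accuracy") <- ori_acc
  res
}
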
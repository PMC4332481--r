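# Pipeline orchestration: sequential classification in the exclusion order
# miRNA -> ra-siRNA -> pha-siRNA -> nat-siRNA, with logging and a
# machine-readable summary.

#' Default pipeline parameters
#'
#' All thresholds of every stage; the defaults are the printed values of the
#' underlying method (18-26 nt length window, >= 10 reads, duplex distance
#' 450, copy cap 5000, shift 3, strand bias 0.8, abundance bias 0.6, <= 4
#' duplex mismatches, <= 3 substitutions, p < 1e-3, >= 2 pha-siRNAs, >= 5
#' reads, ratio 0.6, scoring length 18, expectation 4.0, flank 148, cleavage
#' shift 1, cis overlap 50, trans overlap 100, duplex window 50 at 0.9).
#'
#' @param ... overrides of any default.
#' @return named list of parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(
    min_len = 18L, max_len = 26L,
    min_total = 10, max_genome_hits = 5000,
    max_gap = 200L, min_strand_bias = 0.8, min_abundance_bias = 0.6,
    max_distance = 450L, shift_tolerance = 3L, precursor_flank = 20L,
    max_duplex_mismatches = 4L,
    max_substitutions = 3L,
    min_identity = 96, max_mismatches = 3L, max_indels = 0L,
    max_tx_distance = 5000L,
    phase = 21L, phase_cycles = 11L, max_p = 1e-3,
    min_pha = 2L, min_max_reads = 5, min_ratio = 0.6,
    scoring_len = 18L, max_expectation = 4.0, initiator_flank = 148L,
    max_cleavage_shift = 1L,
    min_cis_overlap = 50L, min_trans_overlap = 100L,
    min_duplex_window = 50L, min_duplex_fraction = 0.9
  )
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  p
}

load_input <- function(input) {
  inp <- input
  if (is.character(inp$genome)) inp$genome <- read_genome(inp$genome)
  if (!is.null(inp$transcript_fasta) && is.null(inp$tx_seqs)) {
    inp$tx_seqs <- read_genome(inp$transcript_fasta)
  }
  if (!is.null(inp$transcript_gff) && is.null(inp$tx_models)) {
    inp$tx_models <- read_transcripts(inp$transcript_gff)
  }
  if (!is.null(inp$repeat_gff) && is.null(inp$repeats)) {
    inp$repeats <- read_repeats(inp$repeat_gff)
  }
  # note [["known"]]: $known would partially match $known_mirnas
  if (!is.null(inp$known_mirnas) && is.null(inp[["known"]])) {
    inp[["known"]] <- if (is.character(inp$known_mirnas)) {
      read_known_mirnas(inp$known_mirnas)
    } else {
      inp$known_mirnas
    }
  }
  if (!is.null(inp$reads) && !inherits(inp$reads, "srna_set")) {
    libs <- inp$reads
    if (is.character(libs)) {
      paths <- libs
      libs <- lapply(paths, read_srna_library)
      names(libs) <- if (!is.null(names(paths))) names(paths) else
        sub("\\.[^.]*$", "", basename(paths))
    }
    inp$reads <- libs
  }
  inp
}

#' Run the sequential small-RNA classification pipeline
#'
#' Stages run in the exclusion order of the method: (1) collapse and length-
#' filter reads; (2) exact genome mapping; (3) miRNA locus discovery per
#' reference plus the transcript set, conservation/family assignment and
#' gene-context typing; (4) ra-siRNA assignment on the non-miRNA sRNAs; (5)
#' pha-siRNA detection and initiator prediction on the remainder; (6) cis-
#' and trans-NAT detection and nat-siRNA assignment on what is left; (7)
#' per-class length / 5'-nucleotide profiles.
#'
#' @param input list of inputs: `reads` (named list of library data frames,
#'   file paths, or an `srna_set`), `genome` (DNAStringSet or FASTA path),
#'   and optionally `tx_seqs`/`transcript_fasta`, `tx_models`/
#'   `transcript_gff`, `repeats`/`repeat_gff`, `known`/`known_mirnas`.
#' @param params [pipeline_params()].
#' @param out_dir optional output directory for TSV/GFF3/JSON artifacts.
#' @param verbose log stage survivor counts (default TRUE).
#' @return list with all stage outputs and a `summary` list.
#' @export
run_pipeline <- function(input, params = pipeline_params(), out_dir = NULL,
                         verbose = TRUE) {
  if (params$min_len > params$max_len) {
    stop("validation error: min_len > max_len")
  }
  inp <- load_input(input)
  for (req in c("genome")) {
    if (is.null(inp[[req]])) stop("missing required input: ", req)
  }
  srnas <- if (inherits(inp$reads, "srna_set")) inp$reads else
    collapse_reads(inp$reads)
  total_raw <- sum(srnas$total_count)
  srnas <- filter_by_length(srnas, params$min_len, params$max_len)
  pipeline_log("reads: ", nrow(srnas), " distinct sRNAs (",
               sum(srnas$total_count), "/", total_raw, " reads) after ",
               params$min_len, "-", params$max_len, " nt filter",
               verbose = verbose)

  geno_hits <- map_exact(srnas, inp$genome)
  tx_hits <- if (!is.null(inp$tx_seqs)) map_exact(srnas, inp$tx_seqs) else
    geno_hits[0, ]

  # --- stage 1: miRNA ------------------------------------------------
  loci_list <- list()
  for (sg in unique(names(inp$genome))) {
    h <- geno_hits[geno_hits$seqid == sg, , drop = FALSE]
    loci_list[[sg]] <- discover_mirna_loci(
      srnas, h, inp$genome, source = sg,
      min_total = params$min_total, max_genome_hits = params$max_genome_hits,
      max_gap = params$max_gap, min_strand_bias = params$min_strand_bias,
      min_abundance_bias = params$min_abundance_bias,
      max_distance = params$max_distance,
      shift_tolerance = params$shift_tolerance,
      flank = params$precursor_flank,
      max_mismatch = params$max_duplex_mismatches)
  }
  if (!is.null(inp$tx_seqs)) {
    loci_list[["transcript"]] <- discover_mirna_loci(
      srnas, tx_hits, inp$tx_seqs, source = "transcript",
      min_total = params$min_total, max_genome_hits = params$max_genome_hits,
      max_gap = params$max_gap, min_strand_bias = params$min_strand_bias,
      min_abundance_bias = params$min_abundance_bias,
      max_distance = params$max_distance,
      shift_tolerance = params$shift_tolerance,
      flank = params$precursor_flank,
      max_mismatch = params$max_duplex_mismatches)
  }
  mirna_loci <- do.call(rbind, loci_list)
  rownames(mirna_loci) <- NULL
  mirna_seqs <- unique(c(mirna_loci$mature_seq, mirna_loci$star_seq))
  pipeline_log("miRNA: ", nrow(mirna_loci), " loci, ",
               length(mirna_seqs), " mature/star sequences",
               verbose = verbose)

  families <- NULL
  if (!is.null(inp[["known"]]) && nrow(mirna_loci)) {
    families <- assign_families(
      classify_conservation(unique(mirna_loci$mature_seq), inp[["known"]],
                            max_subs = params$max_substitutions),
      max_subs = params$max_substitutions)
  }
  gene_context <- NULL
  if (!is.null(inp$tx_models) && nrow(mirna_loci)) {
    ctx <- list()
    genomic <- mirna_loci[mirna_loci$source != "transcript", , drop = FALSE]
    for (i in seq_len(nrow(genomic))) {
      g <- classify_gene_context(genomic[i, ], inp$tx_models,
                                 min_identity = params$min_identity,
                                 max_mismatches = params$max_mismatches,
                                 max_indels = params$max_indels,
                                 max_distance = params$max_tx_distance)
      if (nrow(g)) {
        g$locus_id <- genomic$locus_id[i]
        ctx[[length(ctx) + 1L]] <- g
      }
    }
    gene_context <- if (length(ctx)) do.call(rbind, ctx) else NULL
  }

  # --- stage 2: ra-siRNA ---------------------------------------------
  rasirna <- if (!is.null(inp$repeats)) {
    assign_rasirnas(geno_hits, inp$repeats, exclude = mirna_seqs)
  } else {
    assign_rasirnas(geno_hits[0, ], data.frame())
  }
  ra_seqs <- unique(rasirna$sequence)
  rasirna_table <- summarize_rasirna(rasirna)
  pipeline_log("ra-siRNA: ", length(ra_seqs), " sequences", verbose = verbose)

  # --- stage 3: pha-siRNA --------------------------------------------
  excluded <- union(mirna_seqs, ra_seqs)
  remaining1 <- srnas[!(srnas$sequence %in% excluded), , drop = FALSE]
  stopifnot(!any(ra_seqs %in% remaining1$sequence))
  pyts <- initiators <- NULL
  pha_seqs <- character(0)
  if (!is.null(inp$tx_seqs)) {
    txh <- tx_hits[tx_hits$sequence %in% remaining1$sequence, , drop = FALSE]
    tx_lengths <- setNames(Biostrings::width(inp$tx_seqs), names(inp$tx_seqs))
    pyts <- call_pyts(txh, srnas, tx_lengths, phase = params$phase,
                      m = params$phase_cycles, max_p = params$max_p,
                      min_pha = params$min_pha,
                      min_max_reads = params$min_max_reads,
                      min_ratio = params$min_ratio)
    pha_seqs <- unique(unlist(strsplit(pyts$pha_seqs, ",", fixed = TRUE)))
    matures <- unique(mirna_loci[, c("locus_id", "mature_seq")])
    if (nrow(matures) && nrow(pyts)) {
      mdf <- data.frame(id = matures$locus_id, sequence = matures$mature_seq,
                        stringsAsFactors = FALSE)
      initiators <- predict_initiators(
        mdf, pyts, inp$tx_seqs, max_e = params$max_expectation,
        flank = params$initiator_flank,
        max_shift = params$max_cleavage_shift,
        scoring_len = params$scoring_len, phase = params$phase)
      if (nrow(initiators)) {
        initiators$mirna_sequence <-
          mdf$sequence[match(initiators$mirna, mdf$id)]
      }
    }
    pipeline_log("pha-siRNA: ", nrow(pyts), " PYTs, ", length(pha_seqs),
                 " pha-siRNAs, ",
                 if (is.null(initiators)) 0 else nrow(initiators),
                 " initiator calls", verbose = verbose)
  }

  # --- stage 4: nat-siRNA --------------------------------------------
  remaining2 <- remaining1[!(remaining1$sequence %in% pha_seqs), ,
                           drop = FALSE]
  cis_pairs <- cis_assignments <- cis_enrichment <- NULL
  trans_pairs <- trans_assignments <- trans_enrichment <- NULL
  if (!is.null(inp$tx_models)) {
    cis_pairs <- find_cis_nats(inp$tx_models$transcripts,
                               min_overlap = params$min_cis_overlap)
    ch <- geno_hits[geno_hits$sequence %in% remaining2$sequence, ,
                    drop = FALSE]
    cis_assignments <- assign_nat_sirnas(ch, cis_pairs,
                                         models = inp$tx_models,
                                         srnas = srnas, kind = "cis")
    cis_enrichment <- enrichment_profile(cis_assignments)
    pipeline_log("cis-NAT: ", nrow(cis_pairs), " pairs, ",
                 length(unique(cis_assignments$sequence)), " cis-nat siRNAs",
                 verbose = verbose)
  }
  if (!is.null(inp$tx_seqs)) {
    cis_members <- if (is.null(cis_pairs)) character(0) else
      unique(c(cis_pairs$a, cis_pairs$b))
    trans_input <- inp$tx_seqs[setdiff(names(inp$tx_seqs), cis_members)]
    cand <- find_trans_nats(trans_input,
                            min_overlap = params$min_trans_overlap)
    if (nrow(cand)) {
      keep <- logical(nrow(cand))
      frac <- numeric(nrow(cand))
      for (i in seq_len(nrow(cand))) {
        df <- duplex_filter(cand$aligned_a[i], cand$aligned_b[i],
                            min_window = params$min_duplex_window,
                            min_fraction = params$min_duplex_fraction)
        keep[i] <- df$accepted
        frac[i] <- df$paired_fraction
      }
      cand$paired_fraction <- frac
      trans_pairs <- cand[keep, , drop = FALSE]
      rownames(trans_pairs) <- NULL
    } else {
      cand$paired_fraction <- numeric(0)
      trans_pairs <- cand
    }
    th <- tx_hits[tx_hits$sequence %in% remaining2$sequence, , drop = FALSE]
    trans_assignments <- assign_nat_sirnas(th, trans_pairs, srnas = srnas,
                                           kind = "trans")
    trans_enrichment <- enrichment_profile(trans_assignments)
    pipeline_log("trans-NAT: ", nrow(trans_pairs), " pairs, ",
                 length(unique(trans_assignments$sequence)),
                 " trans-nat siRNAs", verbose = verbose)
  }

  # --- profiles -------------------------------------------------------
  class_seqs <- list(
    mirna = mirna_seqs,
    rasirna = ra_seqs,
    pha = pha_seqs,
    cisnat = setdiff(unique(cis_assignments$sequence), pha_seqs),
    transnat = setdiff(unique(trans_assignments$sequence),
                       unique(cis_assignments$sequence)))
  profiles <- lapply(class_seqs, function(ss) {
    sub <- srnas[srnas$sequence %in% ss, , drop = FALSE]
    list(length = length_distribution(sub),
         length_weighted = length_distribution(sub, weighted = TRUE),
         five_prime = if (nrow(sub)) five_prime_composition(sub) else NULL)
  })

  summary <- list(
    n_srnas = nrow(srnas), total_reads = sum(srnas$total_count),
    n_mirna_loci = nrow(mirna_loci), n_mirna_seqs = length(mirna_seqs),
    n_rasirna = length(ra_seqs),
    n_pyts = if (is.null(pyts)) 0L else nrow(pyts),
    n_pha = length(pha_seqs),
    n_cis_pairs = if (is.null(cis_pairs)) 0L else nrow(cis_pairs),
    n_cisnat = length(unique(cis_assignments$sequence)),
    n_trans_pairs = if (is.null(trans_pairs)) 0L else nrow(trans_pairs),
    n_transnat = length(unique(trans_assignments$sequence)))

  res <- list(srnas = srnas, genome_hits = geno_hits,
              mirna_loci = mirna_loci, families = families,
              gene_context = gene_context, rasirna = rasirna,
              rasirna_table = rasirna_table, pyts = pyts,
              initiators = initiators, cis_pairs = cis_pairs,
              cis_assignments = cis_assignments,
              cis_enrichment = cis_enrichment, trans_pairs = trans_pairs,
              trans_assignments = trans_assignments,
              trans_enrichment = trans_enrichment,
              class_seqs = class_seqs, profiles = profiles,
              summary = summary)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    if (is.null(df) || !nrow(df)) return(invisible(NULL))
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wt(res$mirna_loci, "mirna_loci.tsv")
  if (nrow(res$mirna_loci)) {
    write_mirna_gff3(res$mirna_loci, file.path(out_dir, "mirna_loci.gff3"))
  }
  wt(res$families, "mirna_families.tsv")
  wt(res$gene_context, "gene_context.tsv")
  wt(res$rasirna, "rasirna.tsv")
  wt(res$rasirna_table, "rasirna_taxonomy.tsv")
  wt(res$pyts, "pyts.tsv")
  wt(res$initiators, "initiators.tsv")
  wt(res$cis_pairs, "cis_pairs.tsv")
  wt(res$cis_enrichment, "cis_enrichment.tsv")
  if (!is.null(res$trans_pairs)) {
    tp <- res$trans_pairs
    tp$aligned_a <- tp$aligned_b <- NULL
    wt(tp, "trans_pairs.tsv")
  }
  wt(res$trans_enrichment, "trans_enrichment.tsv")
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
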
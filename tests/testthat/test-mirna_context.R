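test_that("substitution_distance is Hamming for equal lengths and slides", {
  expect_equal(substitution_distance("ACGT", "ACGT"), 0L)
  expect_equal(substitution_distance("ACGT", "ACGA"), 1L)
  # one-nt overhang counts one substitution
  expect_equal(substitution_distance("ACGTA", "ACGT"), 1L)
  # sliding finds the best offset
  expect_equal(substitution_distance("AACGT", "ACGTT"),
               min(2L + 0L, 4L))  # offset 1: overlap ACGT vs ACGT + 2 overhangs
})

test_that("classify_conservation applies the <=3 substitution rule", {
  known <- data.frame(name = c("syn-miR156a", "syn-miR166a"),
                      family = c("miR156", "miR166"),
                      sequence = c("TGACAGAAGAGAGTGAGCACA",
                                   "TCGGACCAGGCTTCATTCCCC"))
  m0 <- known$sequence[1]                       # identical
  m3 <- strsplit(m0, "")[[1]]; m3[c(2, 9, 20)] <- c("C", "T", "G")
  m3 <- paste(m3, collapse = "")                # 3 subs
  m4 <- strsplit(m0, "")[[1]]; m4[c(2, 9, 15, 20)] <- c("C", "T", "A", "G")
  m4 <- paste(m4, collapse = "")                # 4 subs
  out <- classify_conservation(c(m0, m3, m4), known)
  expect_equal(out$conservation[out$sequence == m0], "conserved")
  expect_equal(out$family[out$sequence == m0], "miR156")
  expect_equal(out$conservation[out$sequence == m3], "conserved")
  expect_equal(out$conservation[out$sequence == m4], "lineage_specific")
  expect_warning(classify_conservation(m0, known[0, ]), "empty")
})

test_that("classify_conservation equals a brute-force scan (oracle)", {
  set.seed(41)
  known <- data.frame(name = paste0("k", 1:8), family = paste0("fam", 1:8),
                      sequence = vapply(rep(21, 8), rand_dna, character(1)))
  matures <- c(vapply(rep(21, 10), rand_dna, character(1)),
               vapply(known$sequence[1:3], function(s) {
                 ch <- strsplit(s, "")[[1]]
                 i <- sample(21, 2)
                 ch[i] <- sapply(ch[i], function(b)
                   sample(setdiff(c("A", "C", "G", "T"), b), 1))
                 paste(ch, collapse = "")
               }, character(1)))
  out <- classify_conservation(matures, known)
  # independent brute-force re-derivation of the sliding distance
  slide_dist <- function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    la <- length(ca); lb <- length(cb)
    best <- Inf
    for (off in (-(lb - 1)):(la - 1)) {
      ia <- max(1, 1 + off):min(la, lb + off)
      d <- sum(ca[ia] != cb[ia - off]) + (la - length(ia)) + (lb - length(ia))
      best <- min(best, d)
    }
    best
  }
  for (i in seq_along(matures)) {
    d <- vapply(known$sequence, slide_dist, numeric(1), a = matures[i])
    expect_equal(out$conservation[out$sequence == matures[i]],
                 if (min(d) <= 3) "conserved" else "lineage_specific")
    expect_equal(out$substitutions[out$sequence == matures[i]],
                 as.integer(min(d)))
  }
})

test_that("assign_families links lineage-specific matures at <=3 subs", {
  set.seed(43)
  a <- rand_dna(21)
  a2 <- strsplit(a, "")[[1]]; i <- sample(21, 2)
  a2[i] <- sapply(strsplit(a, "")[[1]][i], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1))
  a2 <- paste(a2, collapse = "")              # 2 subs from a
  b <- paste(rev(strsplit(a, "")[[1]]), collapse = "")  # far away
  cls <- data.frame(sequence = c(a, a2, b),
                    conservation = "lineage_specific",
                    family = NA_character_, best_match = NA_character_,
                    substitutions = NA_integer_, stringsAsFactors = FALSE)
  fam <- assign_families(cls)
  expect_equal(fam$family[fam$sequence == a], fam$family[fam$sequence == a2])
  if (substitution_distance(a, b) > 3 && substitution_distance(a2, b) > 3) {
    expect_false(fam$family[fam$sequence == b] == fam$family[fam$sequence == a])
  }
  expect_true(all(grepl("^miRLS-\\d{4}$", fam$family)))
})

test_that("classify_gene_context types intron/exon/junction/intron_exon", {
  models <- list(
    transcripts = data.frame(
      id = c("txI", "txE", "txJ", "txX"), gene_id = c("gI", "gE", "gJ", "gX"),
      seqid = "c1", start = c(0, 900, 2000, 0), end = c(800, 1500, 2800, 800),
      strand = "+"),
    exons = rbind(
      data.frame(transcript_id = "txI", start = c(0, 500), end = c(200, 800)),
      data.frame(transcript_id = "txE", start = 900, end = 1500),
      data.frame(transcript_id = "txJ", start = c(2000, 2500),
                 end = c(2300, 2800)),
      data.frame(transcript_id = "txX", start = 0, end = 800)))
  # precursor inside txI's intron [200,500)
  ctx <- classify_gene_context(list(seqid = "c1", pre_start = 250,
                                    pre_end = 350), models)
  expect_true(any(ctx$transcript_id == "txI" & ctx$context == "intron"))
  # txX has an exon covering [0,800): same locus gives exon -> merged AS case
  expect_true(any(ctx$transcript_id == "txX" & ctx$context == "exon"))
  expect_equal(unique(ctx$merged_context), "intron_exon")
  # fully inside txE's exon
  ctx2 <- classify_gene_context(list(seqid = "c1", pre_start = 1000,
                                     pre_end = 1100), models)
  expect_equal(ctx2$context[ctx2$transcript_id == "txE"], "exon")
  expect_equal(unique(ctx2$merged_context), "exon")
  # straddling txJ's exon-intron boundary at 2300
  ctx3 <- classify_gene_context(list(seqid = "c1", pre_start = 2250,
                                     pre_end = 2350), models)
  expect_equal(ctx3$context[ctx3$transcript_id == "txJ"], "junction")
  # outside every span: no context
  ctx4 <- classify_gene_context(list(seqid = "c1", pre_start = 5000,
                                     pre_end = 5100), models)
  expect_equal(nrow(ctx4), 0)
})

test_that("origin_sharing cells partition the families", {
  fs <- data.frame(
    family = c("f1", "f1", "f2", "f2", "f2", "f3", "f4"),
    conservation = c(rep("conserved", 5), "lineage_specific",
                     "lineage_specific"),
    source = c("A2", "D5", "A2", "D5", "transcript", "A2", "transcript"))
  out <- origin_sharing(fs)
  cons <- out[out$conservation == "conserved", ]
  expect_equal(cons$families[cons$subset == "A2&D5"], 1)
  expect_equal(cons$families[cons$subset == "A2&D5&transcript"], 1)
  expect_equal(sum(cons$families), 2)      # partition property
  ls <- out[out$conservation == "lineage_specific", ]
  expect_equal(ls$families[ls$subset == "A2"], 1)
  expect_equal(ls$families[ls$subset == "transcript"], 1)
  expect_equal(sum(ls$families), 2)
})
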
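# The small config keeps the per-test runtime low; the full default world
# is exercised once in test-acceptance.R.
small_cfg <- function(seed = 42L) {
  sim_config(seed = seed, ref_length = 30000L, n_hairpins = 6L,
             n_tx_hairpins = 1L, n_conserved = 3L, n_repeats = 10L,
             n_phased = 3L, n_decoy_tx = 5L, n_cis = 4L, n_trans = 2L,
             n_trans_decoys = 1L, background_reads = 40L)
}

test_that("generate_reference implants what the manifest declares", {
  ref <- generate_reference(small_cfg())
  truth <- ref$truth
  # one cis pair per orientation
  oris <- vapply(truth$cis, `[[`, character(1), "orientation")
  expect_setequal(oris, c("convergent", "divergent", "enclosed", "coincided"))
  # hairpin arms are where the manifest says they are
  for (t in truth$mirna) {
    src <- if (t$source == "transcript") ref$tx_seqs else ref$genome
    s <- as.character(src[[t$seqid]])
    expect_equal(substr(s, t$mature_start + 1, t$mature_end), t$mature)
    expect_equal(substr(s, t$star_start + 1, t$star_end), t$star)
  }
  # phased transcripts carry the complementary trigger site
  for (p in truth$phased) {
    s <- as.character(ref$tx_seqs[[p$id]])
    mat <- p$trigger_mature
    site <- substr(s, p$site_start + 1, p$site_end)
    expect_equal(site, rc(mat))
  }
  # trans pairs share a complementary block at >= 90% pairing
  for (tp in truth$trans) {
    a <- substr(as.character(ref$tx_seqs[[tp$a]]), tp$a_block_start + 1,
                tp$a_block_end)
    b <- substr(as.character(ref$tx_seqs[[tp$b]]), tp$b_block_start + 1,
                tp$b_block_end)
    agree <- mean(strsplit(rc(a), "")[[1]] == strsplit(b, "")[[1]])
    expect_gte(agree, 0.9)
  }
})

test_that("simulate_reads respects the configured depths", {
  cfg <- small_cfg()
  ref <- generate_reference(cfg)
  libs <- simulate_reads(ref, cfg)
  origin <- attr(libs, "origin")
  # mature:star = 20:1 at 100 mature reads
  for (t in ref$truth$mirna) {
    expect_equal(origin$count[origin$sequence == t$mature][1], 100)
    expect_equal(origin$count[origin$sequence == t$star][1], 5)
  }
  # every phased locus has its full set of in-register positions and at
  # least one pha-siRNA with >= 5 reads
  for (p in ref$truth$phased) {
    s <- as.character(ref$tx_seqs[[p$id]])
    regs <- vapply(0:(p$cycles - 1), function(j) {
      substr(s, p$anchor + 21 * j + 1, p$anchor + 21 * j + 21)
    }, character(1))
    cnt <- origin$count[match(regs, origin$sequence)]
    expect_true(all(!is.na(cnt)))
    expect_gte(max(cnt), 5)
  }
  # library counts sum to the origin totals
  tot_lib <- sum(vapply(libs, function(l) sum(l$count), numeric(1)))
  expect_equal(tot_lib, sum(origin$count))
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- small_cfg(seed = 7L)
  r1 <- generate_reference(cfg); r2 <- generate_reference(cfg)
  expect_identical(as.character(r1$genome), as.character(r2$genome))
  expect_identical(as.character(r1$tx_seqs), as.character(r2$tx_seqs))
  expect_identical(r1$truth, r2$truth)
  l1 <- simulate_reads(r1, cfg); l2 <- simulate_reads(r2, cfg)
  expect_identical(l1, l2)
  # a different seed changes the world
  r3 <- generate_reference(small_cfg(seed = 8L))
  expect_false(identical(as.character(r1$genome), as.character(r3$genome)))
})

test_that("write_synthetic_dataset round-trips through the file formats", {
  cfg <- small_cfg()
  ref <- generate_reference(cfg)
  libs <- simulate_reads(ref, cfg)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_dataset(ref, libs, dir)
  g <- read_genome(paths$genome)
  expect_identical(as.character(g), as.character(ref$genome))
  reps <- read_repeats(paths$repeat_gff)
  expect_equal(nrow(reps), nrow(ref$repeats))
  expect_setequal(unique(reps$class), unique(ref$repeats$class))
  models <- read_transcripts(paths$transcript_gff)
  expect_setequal(models$transcripts$id, ref$tx_models$transcripts$id)
  km <- read_known_mirnas(paths$known_mirnas)
  expect_setequal(km$family, ref$known$family)
  lib1 <- read_srna_library(paths$libraries[[1]])
  expect_equal(sum(lib1$count), sum(libs[[1]]$count))
})

test_that("evaluate_recovery scores simple call sets correctly", {
  cfg <- small_cfg()
  ref <- generate_reference(cfg)
  truth <- ref$truth
  # perfect calls constructed from the manifest
  loci <- do.call(rbind, lapply(truth$mirna, function(t) {
    data.frame(seqid = t$seqid, pre_start = t$pre_start,
               pre_end = t$pre_end, mature_seq = t$mature,
               star_seq = t$star, stringsAsFactors = FALSE)
  }))
  calls <- list(
    mirna_loci = loci,
    pyts = data.frame(transcript = vapply(truth$phased, `[[`,
                                          character(1), "id")),
    cis_pairs = do.call(rbind, lapply(truth$cis, function(x) {
      data.frame(pair_id = x$pair_id, orientation = x$orientation)
    })),
    trans_pairs = data.frame(pair_id = vapply(truth$trans, `[[`,
                                              character(1), "pair_id")))
  ev <- evaluate_recovery(calls, truth)
  expect_true(all(ev$precision[ev$class %in%
    c("mirna_locus", "pyt", "cis_pair", "trans_pair")] == 1))
  expect_true(all(ev$recall[ev$class %in%
    c("mirna_locus", "pyt", "cis_pair", "trans_pair")] == 1))
  expect_equal(attr(ev, "orientation_accuracy"), 1)
  # no calls at all: recall 0, precision NA
  none <- list(mirna_loci = loci[0, ], pyts = calls$pyts[0, , drop = FALSE],
               cis_pairs = calls$cis_pairs[0, ],
               trans_pairs = calls$trans_pairs[0, , drop = FALSE])
  ev0 <- evaluate_recovery(none, truth)
  expect_true(all(is.na(ev0$precision)))
  expect_true(all(ev0$recall == 0))
  # one mis-oriented cis pair drops orientation accuracy to 0.75
  mis <- calls
  mis$cis_pairs$orientation[1] <- setdiff(
    c("convergent", "divergent", "enclosed", "coincided"),
    mis$cis_pairs$orientation[1])[1]
  evm <- evaluate_recovery(mis, truth)
  expect_equal(attr(evm, "orientation_accuracy"), 0.75)
})
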
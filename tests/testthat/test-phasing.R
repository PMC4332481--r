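test_that("phase_register_counts counts window occupancy and register", {
  out <- phase_register_counts(c(0, 21, 42), anchor = 0, m = 3)
  expect_equal(out, list(N = 63L, n = 3L, k = 3L))
  out <- phase_register_counts(c(0, 5, 21), anchor = 0, m = 3)
  expect_equal(out$n, 3L)
  expect_equal(out$k, 2L)
  out <- phase_register_counts(integer(0), anchor = 0, m = 3)
  expect_equal(out$n, 0L)
  expect_equal(out$k, 0L)
  expect_error(phase_register_counts(c(0, 21), 0, m = 1), "m must be")
})

test_that("phasing_pvalue matches the derived combinatorial values", {
  expect_equal(phasing_pvalue(63, 4, 0), 1)
  # frozen values computed from the exhaustive tail sum
  expect_equal(phasing_pvalue(63, 4, 3),
               choose(3, 3) * choose(60, 1) / choose(63, 4),
               tolerance = 1e-12)
  expect_equal(phasing_pvalue(63, 3, 3), 1 / choose(63, 3),
               tolerance = 1e-12)
  expect_error(phasing_pvalue(63, 3, 4), "k_obs")
  expect_error(phasing_pvalue(64, 3, 2), "multiple")
})

test_that("phasing pmf sums to 1 and the tail is monotone in k", {
  for (m in 2:5) {
    N <- 21L * m
    for (n in c(3L, 7L, 12L)) {
      pm <- vapply(0:min(n, m), function(j) {
        choose(m, j) * choose(N - m, n - j) / choose(N, n)
      }, numeric(1))
      expect_equal(sum(pm), 1, tolerance = 1e-9)
      pv <- vapply(0:min(n, m), function(k) phasing_pvalue(N, n, k),
                   numeric(1))
      expect_true(all(diff(pv) < 0))
      # tail equals cumulated pmf
      for (k in 0:min(n, m)) {
        expect_equal(pv[k + 1], sum(pm[(k + 1):length(pm)]),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("register_positions shifts minus-strand hits by +2", {
  h <- data.frame(sequence = c("a", "b"), seqid = "t1", start = c(10, 30),
                  end = c(31, 51), strand = c("+", "-"))
  out <- register_positions(h)
  expect_equal(out$pos, c(10, 32))
})

mk_phased_tx <- function(cycles = 8, anchor = 60, pad = 40) {
  L <- anchor + 21 * cycles + pad
  tx <- rand_dna(L)
  reads <- data.frame(sequence = character(), count = numeric())
  for (j in 0:(cycles - 1)) {
    s <- anchor + 21 * j
    reads <- rbind(reads, data.frame(
      sequence = substr(tx, s + 1, s + 21), count = 8))
  }
  list(tx = tx, reads = reads, anchor = anchor, L = L)
}

test_that("call_pyts recovers a perfectly phased transcript", {
  set.seed(61)
  ph <- mk_phased_tx()
  srnas <- srna_fixture(ph$reads$sequence, ph$reads$count)
  txs <- Biostrings::DNAStringSet(c(t1 = ph$tx))
  hits <- map_exact(srnas, txs)
  out <- call_pyts(hits, srnas, c(t1 = ph$L))
  expect_equal(nrow(out), 1)
  expect_equal(out$anchor, ph$anchor)
  expect_lt(out$p_value, 1e-3)
  expect_equal(out$phased_ratio, 1)
  expect_gte(out$n_pha, 2)
})

test_that("post-filters reject loci with one pha-siRNA or low ratio", {
  set.seed(67)
  ph <- mk_phased_tx()
  txs <- Biostrings::DNAStringSet(c(t1 = ph$tx))
  # single distinct in-register sRNA cannot satisfy min_pha = 2
  srnas1 <- srna_fixture(ph$reads$sequence[1], 50)
  out1 <- call_pyts(map_exact(srnas1, txs), srnas1, c(t1 = ph$L))
  expect_equal(nrow(out1), 0)
  # heavy aperiodic off-register reads push the ratio below 0.6 (offsets
  # chosen so the noise itself is not 21-periodic)
  off <- vapply(c(3, 10, 16, 25, 33, 40, 51, 59), function(d) {
    substr(ph$tx, ph$anchor + d + 1, ph$anchor + d + 21)
  }, character(1))
  srnas2 <- srna_fixture(c(ph$reads$sequence, off),
                         c(ph$reads$count, rep(20, length(off))))
  out2 <- call_pyts(map_exact(srnas2, txs), srnas2, c(t1 = ph$L))
  expect_equal(nrow(out2), 0)
  # read-count filter: every pha-siRNA below 5 reads fails filter 2
  srnas3 <- srna_fixture(ph$reads$sequence, rep(4, nrow(ph$reads)))
  out3 <- call_pyts(map_exact(srnas3, txs), srnas3, c(t1 = ph$L))
  expect_equal(nrow(out3), 0)
})

test_that("target_penalty_score implements the penalty arithmetic", {
  mir <- "TGACAGAAGAGAGTGAGCACA"           # 21 nt, scored over first 18
  site18 <- rc(substr(mir, 1, 18))         # perfect complement
  expect_equal(target_penalty_score(mir, site18), 0)
  # one G:U wobble outside the doubled 2-13 region scores 0.5: miRNA
  # position 14 is U (T), wobble partner on the site is G
  ch <- strsplit(site18, "")[[1]]
  stopifnot(substr(mir, 14, 14) == "T")
  ch[18 - 14 + 1] <- "G"
  expect_equal(target_penalty_score(mir, paste(ch, collapse = "")), 0.5)
  # one mismatch at position 5 (seed region): doubled to 2.0
  ch2 <- strsplit(site18, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  m5 <- substr(mir, 5, 5)
  bad <- setdiff(c("A", "C", "G", "T"), c(comp[[m5]],
                                          if (m5 == "G") "T",
                                          if (m5 == "T") "G"))
  ch2[18 - 5 + 1] <- bad[1]
  expect_equal(target_penalty_score(mir, paste(ch2, collapse = "")), 2.0)
  # too-short site: no call
  expect_true(is.na(target_penalty_score(mir, "ACGT")))
})

test_that("predict_initiators calls triggers at the register boundary", {
  set.seed(71)
  mir <- paste0("T", rand_dna(20))
  ph <- mk_phased_tx(anchor = 60)
  tx <- ph$tx
  # implant a perfect site whose cleavage (e - 10) equals the anchor
  e <- ph$anchor + 10
  site <- rc(mir)                           # 21-nt site, last 18 scored
  substr(tx, e - 21 + 1, e) <- site
  txs <- Biostrings::DNAStringSet(c(t1 = tx))
  loci <- data.frame(transcript = "t1", start = ph$anchor,
                     end = ph$anchor + 21 * 8, anchor = ph$anchor,
                     N = 168, n = 8, k = 8, p_value = 1e-9, n_pha = 8,
                     max_pha_reads = 8, phased_ratio = 1, pha_seqs = "x")
  mirnas <- data.frame(id = "m1", sequence = mir)
  out <- predict_initiators(mirnas, loci, txs)
  expect_equal(nrow(out), 1)
  expect_equal(out$cleavage, ph$anchor)
  expect_equal(out$shift, 0L)
  expect_equal(out$expectation, 0)
  # a site 200 nt upstream of the locus is out of the 148-nt flank
  tx2 <- paste0(rand_dna(400), ph$tx)
  substr(tx2, 60 - 21 + 1, 60) <- site     # cleavage at 50, locus at 460
  txs2 <- Biostrings::DNAStringSet(c(t1 = tx2))
  loci2 <- loci; loci2$start <- 460; loci2$anchor <- 460
  loci2$end <- 460 + 21 * 8
  out2 <- predict_initiators(mirnas, loci2, txs2)
  expect_true(nrow(out2) == 0 || all(out2$site_end >= 460 - 148))
})
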
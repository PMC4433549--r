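make_locus_reads <- function(motif, units, n_reads, flank_left, flank_right,
                             prefix) {
  seqs <- vapply(seq_len(n_reads), function(i) {
    paste0(flank_left, strrep(motif, units), flank_right)
  }, character(1))
  data.frame(id = paste0(prefix, seq_len(n_reads)), seq = seqs,
             stringsAsFactors = FALSE)
}

test_that("PAL finding excludes dinucleotides and reports the design rate", {
  set.seed(51)
  # loci with no flanks: rate 0
  bare <- data.frame(id = "b1", seq = strrep("TTC", 10),
                     stringsAsFactors = FALSE)
  loci_b <- scan_reads(bare$seq, bare$id)
  res_b <- find_pals(loci_b, bare)
  expect_equal(nrow(res_b$pals), 0L)
  expect_equal(res_b$rate, 0)

  # clean 60-nt flanks: every locus designable
  cons <- primer_constraints(product_min = 60, product_max = 160)
  reads <- do.call(rbind, lapply(1:6, function(i) {
    data.frame(id = paste0("r", i),
               seq = paste0(random_seq(60), strrep("AATC", 6), random_seq(60)),
               stringsAsFactors = FALSE)
  }))
  loci <- scan_reads(reads$seq, reads$id)
  loci <- loci[loci$canonical == "AATC", ]
  res <- find_pals(loci, reads, cons)
  expect_equal(res$rate, 1)
  expect_equal(nrow(res$pals), nrow(loci))   # conservation

  # dinucleotide loci are not eligible
  di <- data.frame(id = "d1",
                   seq = paste0(random_seq(60), strrep("AC", 8),
                                random_seq(60)),
                   stringsAsFactors = FALSE)
  res_d <- find_pals(scan_reads(di$seq, di$id), di, cons)
  expect_equal(res_d$n_loci, 0L)
})

test_that("a primer shared between different loci rejects both PALs", {
  set.seed(52)
  shared <- random_seq(20)
  while (primer_tm(shared) < 57 || primer_tm(shared) > 63) {
    shared <- random_seq(20)
  }
  fake_pal <- function(id, canonical, forward, reverse) {
    data.frame(pal_id = id, read_id = id, start = 0L, end = 0L,
               motif = canonical, canonical = canonical,
               units = 6L, forward = forward, reverse = reverse,
               forward_start = 0L, reverse_end = 0L, tm_forward = 60,
               tm_reverse = 60, product_size = 100L, single_copy = NA,
               stringsAsFactors = FALSE)
  }
  other1 <- random_seq(20); other2 <- random_seq(20)
  pals <- rbind(fake_pal("P1", "AAG", shared, other1),
                fake_pal("P2", "AATC", shared, other2))
  reads <- data.frame(id = "r1", seq = random_seq(100),
                      stringsAsFactors = FALSE)
  out <- screen_single_copy(pals, reads)
  expect_equal(nrow(out), 0L)
})

test_that("single-copy screening retains planted loci and is idempotent", {
  set.seed(53)
  cons <- primer_constraints(product_min = 60, product_max = 160)
  fl <- replicate(4, random_seq(60)); fr <- replicate(4, random_seq(60))
  motifs <- c("AAG", "AATC", "ACT", "AATG")
  reads <- do.call(rbind, lapply(1:4, function(i) {
    make_locus_reads(motifs[i], 6, 30, fl[i], fr[i], paste0("L", i, "_"))
  }))
  loci <- scan_reads(reads$seq, reads$id)
  reps <- loci[!duplicated(loci$canonical), ]
  res <- find_pals(reps, reads, cons)
  expect_equal(nrow(res$pals), 4L)
  kept <- screen_single_copy(res$pals, reads, loci)
  expect_equal(nrow(kept), 4L)
  expect_true(all(kept$single_copy))
  expect_true(attr(kept, "screened"))
  again <- screen_single_copy(kept, reads, loci)
  expect_equal(again$pal_id, kept$pal_id)   # idempotent
  # empty read set: vacuous retention, flagged unscreened
  unscreened <- screen_single_copy(res$pals, reads[0, ])
  expect_equal(nrow(unscreened), 4L)
  expect_false(attr(unscreened, "screened"))
})

test_that("e-PCR product length arithmetic is exact", {
  set.seed(54)
  f <- random_seq(20); r <- random_seq(20)
  pair <- list(forward = f, reverse = r)
  read <- data.frame(id = "x",
                     seq = paste0(f, strrep("AAG", 6), oracle_revcomp(r)),
                     stringsAsFactors = FALSE)
  obs <- epcr_amplicons(pair, read)
  expect_equal(obs$product_length, 20L + 18L + 20L)
  # reverse-complemented read gives the same product on the minus strand
  rc_read <- data.frame(id = "y", seq = oracle_revcomp(read$seq),
                        stringsAsFactors = FALSE)
  obs_rc <- epcr_amplicons(pair, rc_read)
  expect_equal(obs_rc$product_length, 58L)
  expect_equal(obs_rc$strand, "-")
  # a read lacking either primer yields nothing
  expect_equal(nrow(epcr_amplicons(pair, data.frame(id = "z",
                                                    seq = random_seq(100)))),
               0L)
})

test_that("heterozygous planted alleles produce two length bins one unit apart", {
  set.seed(55)
  fl <- random_seq(40); fr <- random_seq(40)
  a1 <- make_locus_reads("TTC", 8, 15, fl, fr, "a")
  a2 <- make_locus_reads("TTC", 10, 15, fl, fr, "b")
  reads <- rbind(a1, a2)
  loci <- scan_reads(reads$seq, reads$id)
  cons <- primer_constraints(product_min = 50, product_max = 160)
  pal <- find_pals(loci[which.max(loci$units), , drop = FALSE], reads, cons)
  obs <- epcr_amplicons(pal$pals[1, ], reads)
  tab <- table(obs$product_length)
  expect_equal(length(tab), 2L)
  expect_equal(diff(as.integer(names(tab))), 6L)   # 2 units x 3 bp
  call <- flag_potentially_polymorphic(obs, min_support = 2, min_diff = 3)
  expect_true(call$flagged)
  expect_equal(sum(call$histogram), nrow(obs))     # histogram conservation
})

test_that("flagging requires two supported bins separated by a unit", {
  obs1 <- data.frame(read_id = paste0("r", 1:5), product_length = rep(230L, 5))
  expect_false(flag_potentially_polymorphic(obs1)$flagged)

  obs2 <- data.frame(read_id = paste0("r", 1:9),
                     product_length = c(rep(230L, 5), rep(233L, 4)))
  expect_true(flag_potentially_polymorphic(obs2, min_diff = 3)$flagged)

  obs3 <- data.frame(read_id = paste0("r", 1:6),
                     product_length = c(rep(230L, 5), 231L))
  expect_false(flag_potentially_polymorphic(obs3, min_diff = 3)$flagged)

  empty <- flag_potentially_polymorphic(obs1[0, ])
  expect_false(empty$flagged)
  expect_equal(length(empty$histogram), 0L)
})

test_that("candidate ranking puts flagged loci first, stably", {
  pals <- data.frame(pal_id = paste0("P", 1:4), canonical = c("A", "B", "C", "D"),
                     stringsAsFactors = FALSE)
  call <- function(flagged, lens, n) {
    structure(list(histogram = stats::setNames(rep(2L, length(lens)),
                                               lens),
                   supported_lengths = lens, flagged = flagged,
                   n_observations = n),
              class = "polymorphism_call")
  }
  # all unflagged: input order preserved
  calls <- list(call(FALSE, 100L, 5L), call(FALSE, 100L, 9L),
                call(FALSE, 100L, 2L), call(FALSE, 100L, 7L))
  expect_equal(prioritize_candidates(pals, calls)$pal_id, pals$pal_id)
  # one flagged ranks first
  calls[[3]] <- call(TRUE, c(100L, 106L), 8L)
  expect_equal(prioritize_candidates(pals, calls)$pal_id[1], "P3")
  # larger spread outranks larger support among flagged
  calls[[2]] <- call(TRUE, c(100L, 112L), 4L)
  expect_equal(prioritize_candidates(pals, calls)$pal_id[1:2], c("P2", "P3"))
})
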
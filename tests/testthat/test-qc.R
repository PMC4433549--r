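make_read <- function(seq, q = 30, id = "r") {
  data.frame(id = id, seq = seq,
             qual = strrep(intToUtf8(q + 33L), nchar(seq)),
             stringsAsFactors = FALSE)
}

test_that("quality filter applies length, ambiguity and quality rules in order", {
  set.seed(21)
  r_short <- make_read(random_seq(49))
  r_n2 <- make_read(paste0(random_seq(49), "N", random_seq(25), "N",
                           random_seq(24)))
  r_ok <- make_read(random_seq(100))
  r_lowq <- make_read(random_seq(100), q = 20)
  reads <- rbind(r_short, r_n2, r_ok, r_lowq)
  res <- quality_filter(reads)
  expect_equal(res$reason, c("length", "ambiguity", "pass", "quality"))
  expect_equal(res$pass, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("reason counts partition the input", {
  set.seed(22)
  reads <- do.call(rbind, lapply(1:60, function(i) {
    type <- i %% 5
    if (type == 0) make_read(random_seq(30), id = i)
    else if (type == 1) make_read(gsub("G", "N", random_seq(80)), id = i)
    else if (type == 2) make_read(random_seq(80), q = 10, id = i)
    else if (type == 3) make_read(strrep("AT", 40), id = i)
    else make_read(random_seq(80), id = i)
  }))
  s <- quality_filter(reads)$summary
  expect_equal(s[["input"]],
               s[["passed"]] + s[["length"]] + s[["ambiguity"]] +
                 s[["quality"]] + s[["dust"]])
  expect_true(all(s[c("length", "quality", "dust")] > 0))
})

test_that("quality rules on FASTA input are a configuration error", {
  r <- data.frame(id = "a", seq = "ACGT", qual = NA_character_)
  expect_error(quality_filter(r), "qualit")
  expect_silent(quality_filter(r, qc_params(min_length = 2), use_quality = FALSE))
})

test_that("DUST score matches the direct triplet-count oracle", {
  expect_equal(dust_score("ACGTTGCA"), 0)         # all triplets distinct
  expect_equal(dust_score(strrep("A", 100)), 100) # maximal repetitiveness
  at50 <- strrep("AT", 50)
  expect_gte(dust_score(at50), 7)                 # filtered at default 7
  expect_equal(dust_score(at50), oracle_dust(at50))
  set.seed(23)
  for (i in 1:20) {
    s <- random_seq(sample(10:120, 1), gc = runif(1, 0.2, 0.8))
    expect_equal(dust_score(s), oracle_dust(s), tolerance = 1e-12)
  }
  # N breaks triplets
  sn <- "ACGNACGNACGN"
  expect_equal(dust_score(sn), oracle_dust(sn))
  expect_error(dust_score("AC"), "length")
})

test_that("deduplication keeps first occurrences in order", {
  r1 <- make_read("ACGTACGTAC", id = "a")
  r2 <- make_read("ACGTACGTAC", id = "b")
  r3 <- make_read("TTTTGGGGCC", id = "c")
  dd <- deduplicate(rbind(r1, r2, r3))
  expect_equal(dd$reads$id, c("a", "c"))
  expect_equal(dd$removed, 1L)

  distinct <- rbind(r1, r3)
  expect_equal(deduplicate(distinct)$reads, distinct)

  many <- do.call(rbind, lapply(1:10, function(i) make_read("ACACACGTGT", id = i)))
  dd10 <- deduplicate(many)
  expect_equal(nrow(dd10$reads), 1L)
  expect_equal(dd10$removed, 9L)

  # paired duplicates defined on the ordered pair
  p <- deduplicate(rbind(r1, r1), rbind(r3, make_read("AAAACCCCGG")))
  expect_equal(nrow(p$reads), 2L)
})

test_that("pair merging reconstructs fragments from exact overlaps", {
  set.seed(24)
  for (i in 1:10) {
    frag <- random_seq(sample(150:190, 1))  # overlap stays >= 10 nt
    L <- 100L
    r1 <- make_read(substr(frag, 1, L), id = "x/1")
    r2 <- make_read(oracle_revcomp(substring(frag, nchar(frag) - L + 1)),
                    id = "x/2")
    m <- merge_pair(r1, r2)
    expect_false(is.null(m))
    expect_equal(m$seq, frag)
    expect_equal(nchar(m$seq), nchar(frag))
  }
  # the canonical arithmetic case: 100 + 100 - 20 = 180
  frag <- random_seq(180)
  m <- merge_pair(make_read(substr(frag, 1, 100)),
                  make_read(oracle_revcomp(substring(frag, 81))))
  expect_equal(m$overlap, 20L)
  expect_equal(nchar(m$seq), 180L)
})

test_that("disjoint or too-noisy pairs do not merge", {
  set.seed(25)
  r1 <- make_read(random_seq(100))
  r2 <- make_read(random_seq(100))
  expect_null(merge_pair(r1, r2))

  # 20-nt overlap carrying 5 mismatches: rate 0.25 > cap 0.1
  frag <- random_seq(180)
  s2 <- substring(frag, 81)
  pos <- c(3, 7, 11, 15, 19)
  for (p in pos) {
    b <- substr(s2, p, p)
    substr(s2, p, p) <- setdiff(c("A", "C", "G", "T"), b)[1]
  }
  expect_null(merge_pair(make_read(substr(frag, 1, 100)),
                         make_read(oracle_revcomp(s2))))
})

test_that("overlap disagreements take the higher-quality base", {
  set.seed(27)
  frag <- random_seq(180)
  s1 <- substr(frag, 1, 100)
  s2 <- substring(frag, 81)
  substr(s1, 90, 90) <- "T"   # error in read 1 inside the overlap
  r1 <- data.frame(id = "x/1", seq = s1, qual = strrep("$", 100))  # Q3
  r2 <- data.frame(id = "x/2", seq = oracle_revcomp(s2),
                   qual = strrep("I", 100))                        # Q40
  m <- merge_pair(r1, r2)
  expect_equal(m$seq, frag)   # high-quality mate wins the disagreement
})

test_that("FASTQ round-trips through the Biostrings-backed readers", {
  set.seed(26)
  reads <- do.call(rbind, lapply(1:5, function(i) {
    make_read(random_seq(60), q = sample(2:40, 1), id = paste0("read", i))
  }))
  f <- tempfile(fileext = ".fastq.gz")
  write_reads(reads, f)
  expect_equal(read_fastq(f), reads)
  fa <- tempfile(fileext = ".fasta")
  write_reads(reads, fa, format = "fasta")
  back <- read_fasta(fa)
  expect_equal(back$seq, reads$seq)
  expect_true(all(is.na(back$qual)))
})
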
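# Independent oracles and shared fixtures, kept deliberately separate from
# the package's own algorithms.

# reverse complement without Biostrings
oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# canonical class representative by explicit member enumeration
oracle_canonical <- function(m) {
  k <- nchar(m)
  rots <- function(s) {
    vapply(seq_len(k), function(i) paste0(substring(s, i), substring(s, 1, i - 1)),
           character(1))
  }
  min(c(rots(m), rots(oracle_revcomp(m))))
}

# number of motif classes for length k, via graph components over
# rotation/revcomp edges (requires igraph)
oracle_class_count <- function(k) {
  mers <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                      stringsAsFactors = FALSE))
  prim <- vapply(mers, function(s) {
    for (d in seq_len(k - 1)) {
      if (k %% d == 0 && s == strrep(substr(s, 1, d), k / d)) return(FALSE)
    }
    TRUE
  }, logical(1))
  mers <- mers[prim]
  rot1 <- vapply(mers, function(s) paste0(substring(s, 2), substring(s, 1, 1)),
                 character(1))
  rc <- vapply(mers, oracle_revcomp, character(1))
  g <- igraph::graph_from_data_frame(
    rbind(data.frame(from = mers, to = rot1),
          data.frame(from = mers, to = rc)),
    directed = FALSE)
  igraph::components(g)$no
}

# DUST score recomputed naively from triplet substrings
oracle_dust <- function(s) {
  n <- nchar(s)
  tri <- substring(s, 1:(n - 2), 3:n)
  tri <- tri[!grepl("N", tri)]
  w <- length(tri)
  if (w < 2) return(0)
  cnt <- table(tri)
  100 * sum(cnt * (cnt - 1)) / (w * (w - 1))
}

# closed-form Pearson chi-square for a 2x2 table
oracle_chisq <- function(a, b, c, d) {
  n <- a + b + c + d
  rs <- c(a + b, c + d); cs <- c(a + c, b + d)
  e <- outer(rs, cs) / n
  o <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  sum((o - e)^2 / e)
}

# brute-force canonical k-mer counting via substrings
oracle_kmer_counts <- function(seqs, k) {
  km <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1), k:n)
  }))
  km <- km[!grepl("N", km)]
  canon <- vapply(km, function(x) min(x, oracle_revcomp(x)), character(1))
  table(canon)
}

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# the planted-panel study design: 10 heterozygous + 10 homozygous loci with
# distinct canonical motifs on a 100 kb diploid, sequenced error-free at 30x
# as 2 x 100 nt pairs (fragments 180 +/- 8). Products are screened against
# (merged) reads, so the design product window is 50-120 bp, optimum 60.
marker_sim_constraints <- function() {
  primer_constraints(product_min = 50, product_max = 120, product_opt = 60)
}

make_marker_simulation <- function(seed = 101, genome_kb = 100,
                                   coverage = 30, error_rate = 0) {
  tri <- enumerate_motif_classes(3)$canonical
  tet <- enumerate_motif_classes(4)$canonical[1:10]
  specs <- c(
    lapply(tri[1:5],  function(m) plant_spec(m, c(5, 7))),
    lapply(tet[1:5],  function(m) plant_spec(m, c(4, 6))),
    lapply(tri[6:10], function(m) plant_spec(m, c(6, 6))),
    lapply(tet[6:10], function(m) plant_spec(m, c(5, 5)))
  )
  cons <- marker_sim_constraints()
  g <- simulate_genome(genome_kb * 1000, 0.38, seed = seed)
  pl <- plant_ssrs(g, specs, seed = seed + 1, flank_length = 120,
                   constraints = cons)
  sim <- simulate_reads(pl$hap1, pl$hap2, coverage = coverage,
                        read_length = 100, fragment_mean = 180,
                        fragment_sd = 8, error_rate = error_rate,
                        seed = seed + 2)
  list(specs = specs, planted = pl, sim = sim, constraints = cons)
}

decode_kmers_for_test <- function(sp) {
  ssrkit:::decode_kmer(sp$kmer_codes, sp$k)
}
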
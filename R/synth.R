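#' Simulate a random haploid genome sequence
#'
#' I.i.d. bases at a target GC content. Deterministic for a fixed seed.
#'
#' @param length genome length in bp (>= 1000).
#' @param gc_content target GC fraction. The default 0.38 is typical of
#'   dicot nuclear genomes.
#' @param seed RNG seed.
#' @return a single character string.
#' @export
simulate_genome <- function(length, gc_content = 0.38, seed = 1L) {
  if (length < 1000) stop("genome_length must be >= 1 kb")
  stopifnot(gc_content >= 0, gc_content <= 1)
  set.seed(seed)
  random_dna(length, gc_content)
}

random_dna <- function(n, gc) {
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Specification of one SSR locus to plant
#'
#' @param motif repeat unit (primitive, 2-6 bp).
#' @param units length-2 integer vector: repeat units on haplotype 1 and 2
#'   (unequal values create a heterozygous locus).
#' @param structure `"single"`, `"compound"` (a second tract of a different
#'   motif follows) or `"broken"` (a second tract of the same motif follows
#'   after a short interruption).
#' @param second_motif,second_units the trailing tract for compound loci.
#' @param broken_units units of the continuation tract for broken loci.
#' @return list of class `plant_spec`.
#' @export
plant_spec <- function(motif, units, structure = c("single", "compound",
                                                   "broken"),
                       second_motif = NULL, second_units = 5L,
                       broken_units = NULL) {
  structure <- match.arg(structure)
  stopifnot(is_primitive(motif), length(units) == 2L, all(units >= 2L))
  if (structure == "compound" && is.null(second_motif)) {
    stop("compound loci need a second_motif")
  }
  if (structure == "broken" && is.null(broken_units)) broken_units <- 4L
  base::structure(list(motif = motif, units = as.integer(units),
                       structure = structure, second_motif = second_motif,
                       second_units = as.integer(second_units),
                       broken_units = as.integer(broken_units)),
                  class = "plant_spec")
}

tract_seq <- function(spec, hap) {
  main <- strrep(spec$motif, spec$units[hap])
  if (spec$structure == "single") return(main)
  if (spec$structure == "compound") {
    return(paste0(main, strrep(spec$second_motif, spec$second_units)))
  }
  # broken: 1-nt interruption that cannot extend either neighbouring tract
  gap <- setdiff(DNA_BASES, c(substr(spec$motif, 1L, 1L),
                              substr(spec$motif, nchar(spec$motif),
                                     nchar(spec$motif))))[1L]
  paste0(main, gap, strrep(spec$motif, spec$broken_units))
}

spec_truth_rows <- function(spec) {
  # expected scan output rows (relative 0-based offsets within the tract)
  rows <- function(hap) {
    main_len <- spec$units[hap] * nchar(spec$motif)
    if (spec$structure == "single") {
      data.frame(motif = spec$motif, units = spec$units[hap],
                 offset = 0L, stringsAsFactors = FALSE)
    } else if (spec$structure == "compound") {
      data.frame(motif = c(spec$motif, spec$second_motif),
                 units = c(spec$units[hap], spec$second_units),
                 offset = c(0L, main_len), stringsAsFactors = FALSE)
    } else {
      data.frame(motif = c(spec$motif, spec$motif),
                 units = c(spec$units[hap], spec$broken_units),
                 offset = c(0L, main_len + 1L), stringsAsFactors = FALSE)
    }
  }
  list(rows(1L), rows(2L))
}

#' Plant SSR loci into a haploid background, producing a diploid pair
#'
#' Loci are spaced evenly along the genome, each wrapped in freshly drawn
#' flanks that are rejection-sampled to contain no SSR signal of their own
#' and not to extend the planted tract, so planted loci are exactly the
#' tracts a scanner should find. Haplotype 2 differs from haplotype 1 only
#' at loci with unequal allele unit counts. Flanks are drawn at a separate
#' (default balanced) GC so that planted loci are primer-compatible.
#'
#' @param genome haploid background from [simulate_genome()].
#' @param specs list of [plant_spec()]s.
#' @param seed RNG seed.
#' @param flank_length clean flank planted on each side of every tract (nt).
#' @param flank_gc GC fraction of the planted flanks.
#' @param thresholds [scan_thresholds()] used for the cleanliness check.
#' @param constraints optional [primer_constraints()]; when given, flanks are
#'   additionally rejection-sampled until a primer pair satisfying them
#'   exists within `compat_flank` nt of the tract on both haplotypes, so
#'   every planted locus is potentially amplifiable by construction.
#' @param compat_flank flank window (nt per side) for the compatibility
#'   check; keep it no larger than the usable flank on a typical read.
#' @return list with `hap1`, `hap2` (strings) and `truth`, a data.frame with
#'   one row per planted tract component and haplotype: `locus`, `hap`,
#'   `motif`, `canonical`, `units`, `start`, `end` (0-based half-open
#'   haplotype coordinates), `structure`, `het` (were the allele unit counts
#'   unequal).
#' @export
plant_ssrs <- function(genome, specs, seed = 1L, flank_length = 120L,
                       flank_gc = 0.5, thresholds = scan_thresholds(),
                       constraints = NULL, compat_flank = 50L) {
  set.seed(seed)
  G <- nchar(genome)
  n <- length(specs)
  slot <- G %/% (n + 1L)
  max_tract <- max(vapply(specs, function(sp) nchar(tract_seq(sp, 1L)) +
                            nchar(tract_seq(sp, 2L)), numeric(1)))
  if (slot < 2L * flank_length + max_tract + 10L) {
    stop("genome too small to place ", n, " loci with ", flank_length,
         "-nt flanks")
  }
  anchors <- slot * seq_len(n)   # insertion points in background coords
  parts1 <- character(2L * n + 1L)
  parts2 <- character(2L * n + 1L)
  truth <- list()
  pos1 <- 0L; pos2 <- 0L        # 0-based cursor per haplotype
  prev_anchor <- 0L
  for (i in seq_len(n)) {
    sp <- specs[[i]]
    t1 <- tract_seq(sp, 1L); t2 <- tract_seq(sp, 2L)
    expect <- spec_truth_rows(sp)
    flanks <- sample_clean_flanks(sp, t1, t2, expect, flank_length, flank_gc,
                                  thresholds, constraints, compat_flank)
    bg <- substr(genome, prev_anchor + 1L, anchors[i])
    parts1[2L * i - 1L] <- bg
    parts2[2L * i - 1L] <- bg
    ins1 <- paste0(flanks$left, t1, flanks$right)
    ins2 <- paste0(flanks$left, t2, flanks$right)
    parts1[2L * i] <- ins1
    parts2[2L * i] <- ins2
    base1 <- pos1 + nchar(bg) + flank_length
    base2 <- pos2 + nchar(bg) + flank_length
    for (h in 1:2) {
      ex <- expect[[h]]
      base <- if (h == 1L) base1 else base2
      truth[[length(truth) + 1L]] <- data.frame(
        locus = paste0("L", sprintf("%02d", i)), hap = h,
        motif = ex$motif, canonical = canonical_motif(ex$motif),
        units = ex$units,
        start = base + ex$offset,
        end = base + ex$offset + ex$units * nchar(ex$motif),
        structure = sp$structure, het = sp$units[1L] != sp$units[2L],
        stringsAsFactors = FALSE)
    }
    pos1 <- pos1 + nchar(bg) + nchar(ins1)
    pos2 <- pos2 + nchar(bg) + nchar(ins2)
    prev_anchor <- anchors[i]
  }
  tail_bg <- substr(genome, prev_anchor + 1L, G)
  parts1[2L * n + 1L] <- tail_bg
  parts2[2L * n + 1L] <- tail_bg
  list(hap1 = paste(parts1, collapse = ""),
       hap2 = paste(parts2, collapse = ""),
       truth = do.call(rbind, truth))
}

sample_clean_flanks <- function(sp, t1, t2, expect, flank_length, flank_gc,
                                thresholds, constraints = NULL,
                                compat_flank = 50L, max_tries = 200L) {
  for (try in seq_len(max_tries)) {
    left <- random_dna(flank_length, flank_gc)
    right <- random_dna(flank_length, flank_gc)
    ok <- TRUE
    for (h in 1:2) {
      tract <- if (h == 1L) t1 else t2
      ctx <- paste0(left, tract, right)
      found <- scan_reads(ctx, ids = "ctx", thresholds = thresholds)
      ex <- expect[[h]]
      if (nrow(found) != nrow(ex) ||
          !all(found$motif == ex$motif) ||
          !all(found$units == ex$units) ||
          !all(found$start == flank_length + ex$offset)) {
        ok <- FALSE
        break
      }
      if (!is.null(constraints)) {
        # primer pair must exist in the near flanks (a typical read window)
        trim <- paste0(substr(left, flank_length - compat_flank + 1L,
                              flank_length),
                       tract,
                       substr(right, 1L, compat_flank))
        loc <- data.frame(start = compat_flank,
                          end = compat_flank + nchar(tract))
        if (is.null(design_primer_pair(trim, loc, constraints))) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) return(list(left = left, right = right))
  }
  stop("could not sample clean flanks after ", max_tries, " tries")
}

#' Simulate paired-end reads from a diploid genome
#'
#' Uniformly placed fragments, drawn 50/50 from the two haplotypes, are
#' sequenced from both ends (the reverse mate in sequencing orientation,
#' i.e. reverse-complemented). Substitution errors are i.i.d. at the
#' configured rate; indels are not modelled, matching the substitution-
#' dominated error profile of short-read sequencers. Base qualities encode
#' the error rate. Deterministic for a fixed seed.
#'
#' @param hap1,hap2 haplotype sequences (use the same string twice for a
#'   homozygous/haploid simulation).
#' @param coverage total fold coverage in read bases over the mean
#'   haplotype length.
#' @param read_length read length (nt).
#' @param fragment_mean,fragment_sd fragment-length distribution (bp);
#'   `fragment_mean` must exceed `read_length`.
#' @param error_rate per-base substitution probability, in `[0, 0.1]`.
#' @param seed RNG seed.
#' @return list with read tables `r1`, `r2` and `provenance`
#'   (`fragment`, `hap`, `start` 0-based, `length`).
#' @export
simulate_reads <- function(hap1, hap2, coverage = 30, read_length = 100L,
                           fragment_mean = 180, fragment_sd = 15,
                           error_rate = 0, seed = 1L) {
  stopifnot(coverage > 0, fragment_mean > read_length,
            error_rate >= 0, error_rate <= 0.1)
  set.seed(seed)
  haps <- c(hap1, hap2)
  hlen <- nchar(haps)
  G <- mean(hlen)
  n <- round(G * coverage / (2 * read_length))
  hap <- sample(1:2, n, replace = TRUE)
  frag <- pmin(pmax(round(stats::rnorm(n, fragment_mean, fragment_sd)),
                    read_length), hlen[hap])
  start <- floor(stats::runif(n, 0, hlen[hap] - frag + 1))  # 0-based
  src <- haps[hap]
  r1 <- substring(src, start + 1L, start + read_length)
  r2 <- revcomp(substring(src, start + frag - read_length + 1L,
                          start + frag))
  if (error_rate > 0) {
    r1 <- add_substitutions(r1, error_rate)
    r2 <- add_substitutions(r2, error_rate)
  }
  q <- if (error_rate > 0) {
    max(2L, min(40L, round(-10 * log10(error_rate))))
  } else 40L
  qual <- strrep(intToUtf8(q + 33L), read_length)
  ids <- paste0("frag", seq_len(n))
  list(
    r1 = data.frame(id = paste0(ids, "/1"), seq = r1, qual = qual,
                    stringsAsFactors = FALSE),
    r2 = data.frame(id = paste0(ids, "/2"), seq = r2, qual = qual,
                    stringsAsFactors = FALSE),
    provenance = data.frame(fragment = ids, hap = hap, start = start,
                            length = frag, stringsAsFactors = FALSE)
  )
}

add_substitutions <- function(seqs, rate) {
  L <- nchar(seqs[1L])
  n_err <- stats::rbinom(length(seqs), L, rate)
  for (i in which(n_err > 0L)) {
    pos <- sample.int(L, n_err[i])
    for (p in pos) {
      old <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(DNA_BASES, old), 1L)
    }
  }
  seqs
}
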
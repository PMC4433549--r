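#' Read a FASTQ file into a read table
#'
#' Phred+33 FASTQ, gzip-transparent (delegated to Biostrings). Returns the
#' plain-table read representation used throughout the package.
#'
#' @param path FASTQ file (optionally gzipped).
#' @return data.frame with columns `id`, `seq`, `qual` (Phred+33 strings).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(
    id = names(x),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Read a FASTA file into a read table
#'
#' @param path FASTA file (optionally gzipped).
#' @return data.frame with columns `id`, `seq` and `qual` set to `NA`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  data.frame(id = names(x), seq = as.character(x), qual = NA_character_,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a read table to FASTQ or FASTA
#'
#' @param reads data.frame with `id`, `seq` and (for FASTQ) `qual`.
#' @param path output file; a `.gz` suffix triggers compression.
#' @param format "fastq" or "fasta".
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  compress <- grepl("\\.gz$", path)
  if (format == "fastq") {
    if (any(is.na(reads$qual))) stop("FASTQ output requires qualities")
    Biostrings::writeXStringSet(
      x, path, format = "fastq", compress = compress,
      qualities = Biostrings::BStringSet(reads$qual))
  } else {
    Biostrings::writeXStringSet(x, path, format = "fasta", compress = compress)
  }
  invisible(path)
}

#' Read-filtering parameters
#'
#' Defaults follow common survey-sequencing QC practice: minimum length
#' 50 nt, minimum mean Phred quality 25, at most one ambiguous base, DUST
#' low-complexity score threshold 7, and paired-end merging with a minimum
#' 10 nt overlap at <= 10 % mismatches.
#'
#' @param min_length minimum read length (nt).
#' @param min_mean_quality minimum arithmetic mean Phred score.
#' @param max_n maximum number of `N` bases.
#' @param dust_threshold reads with DUST score >= this are removed.
#' @param merge_min_overlap minimum 3' overlap (nt) for pair merging.
#' @param merge_max_mismatch_rate maximum mismatch fraction in the overlap.
#' @return list of class `qc_params`.
#' @export
qc_params <- function(min_length = 50L, min_mean_quality = 25,
                      max_n = 1L, dust_threshold = 7,
                      merge_min_overlap = 10L,
                      merge_max_mismatch_rate = 0.1) {
  stopifnot(min_length >= 0, min_mean_quality >= 0, max_n >= 0,
            dust_threshold >= 0, merge_min_overlap >= 1,
            merge_max_mismatch_rate >= 0, merge_max_mismatch_rate <= 1)
  structure(list(min_length = as.integer(min_length),
                 min_mean_quality = min_mean_quality,
                 max_n = as.integer(max_n),
                 dust_threshold = dust_threshold,
                 merge_min_overlap = as.integer(merge_min_overlap),
                 merge_max_mismatch_rate = merge_max_mismatch_rate),
            class = "qc_params")
}

mean_phred <- function(qual) {
  vapply(qual, function(q) mean(utf8ToInt(q)) - 33, numeric(1),
         USE.NAMES = FALSE)
}

count_n <- function(seq) {
  nchar(seq) - nchar(gsub("N", "", seq, fixed = TRUE))
}

#' DUST low-complexity score
#'
#' Whole-read triplet-overrepresentation score scaled to 0-100 (the scale on
#' which a removal threshold of 7 is conventional). With `c_t` the count of
#' overlapping triplet `t` among the `w` valid (N-free) triplet windows, the
#' score is `100 * sum(c_t * (c_t - 1)) / (w * (w - 1))`: 0 when every
#' triplet is distinct, 100 for a homopolymer. `N` breaks triplets; windows
#' containing `N` are excluded from both counts and normalization.
#'
#' @param seq character vector of sequences, each of length >= 3.
#' @return numeric vector of scores in `[0, 100]`.
#' @examples
#' dust_score(strrep("A", 100))  # 100
#' dust_score("ACGTTGCA")        # 0, all triplets distinct
#' @export
dust_score <- function(seq) {
  if (length(seq) == 0L) return(numeric(0))
  check_alphabet(seq, allow_n = TRUE)
  if (any(nchar(seq) < 3L)) stop("dust_score requires length >= 3")
  n <- nchar(seq)
  concat <- paste(seq, collapse = "")
  v <- utf8ToInt(concat)
  code <- rep(NA_integer_, length(v))
  code[v == 65L] <- 0L; code[v == 67L] <- 1L
  code[v == 71L] <- 2L; code[v == 84L] <- 3L
  read_of <- rep.int(seq_along(seq), n)
  np <- length(v)
  # triplet windows fully inside one read, N-free
  i <- seq_len(np - 2L)
  ok <- read_of[i] == read_of[i + 2L] &
    !is.na(code[i]) & !is.na(code[i + 1L]) & !is.na(code[i + 2L])
  tri <- code[i] * 16L + code[i + 1L] * 4L + code[i + 2L]
  key <- (read_of[i] - 1L) * 64 + tri
  key <- key[ok]
  rid <- read_of[i][ok]
  w <- tabulate(rid, nbins = length(seq))          # valid windows per read
  srt <- sort(key, method = "quick")
  r <- rle(srt)
  cnt <- r$lengths
  grp <- r$values %/% 64 + 1
  num <- rep(0, length(seq))
  agg <- rowsum(cnt * (cnt - 1), grp)
  num[as.integer(rownames(agg))] <- agg[, 1L]
  score <- ifelse(w >= 2L, 100 * num / (w * (w - 1)), 0)
  score
}

#' Per-read quality filter
#'
#' Applies the length, ambiguity, mean-quality and DUST rules in that order
#' (cheap checks first) and reports the first violated rule per read, so the
#' reason counts partition the input.
#'
#' @param reads read table (`id`, `seq`, `qual`); `qual` may be `NA` only if
#'   `use_quality = FALSE`.
#' @param params a [qc_params()] object.
#' @param use_quality apply the mean-quality rule (must be `FALSE` for FASTA
#'   input, which has no qualities).
#' @return list with `pass` (logical), `reason` (character: `"pass"`,
#'   `"length"`, `"ambiguity"`, `"quality"`, `"dust"`), and `summary`
#'   (named counts).
#' @export
quality_filter <- function(reads, params = qc_params(), use_quality = TRUE) {
  if (use_quality && any(is.na(reads$qual))) {
    stop("quality rules enabled but reads carry no qualities (FASTA input?); ",
         "set use_quality = FALSE")
  }
  n <- nrow(reads)
  reason <- rep("pass", n)
  len_ok <- nchar(reads$seq) >= params$min_length
  reason[!len_ok] <- "length"
  amb_ok <- count_n(reads$seq) <= params$max_n
  reason[reason == "pass" & !amb_ok] <- "ambiguity"
  if (use_quality) {
    q_ok <- mean_phred(reads$qual) >= params$min_mean_quality
    reason[reason == "pass" & !q_ok] <- "quality"
  }
  idx <- reason == "pass" & nchar(reads$seq) >= 3L
  dust <- rep(0, n)
  dust[idx] <- dust_score(reads$seq[idx])
  reason[reason == "pass" & dust >= params$dust_threshold] <- "dust"
  pass <- reason == "pass"
  summary <- c(input = n, passed = sum(pass),
               length = sum(reason == "length"),
               ambiguity = sum(reason == "ambiguity"),
               quality = sum(reason == "quality"),
               dust = sum(reason == "dust"))
  list(pass = pass, reason = reason, summary = summary)
}

#' Remove exact duplicate reads
#'
#' Keeps the first occurrence of each exact full-length sequence (for pairs,
#' the ordered concatenation of both mates), preserving input order.
#'
#' @param reads read table.
#' @param mates optional second-mate table of the same length; duplicates are
#'   then defined on the ordered pair.
#' @return list with `reads` (and `mates` if given) deduplicated, and
#'   `removed`, the number of reads (pairs) dropped.
#' @export
deduplicate <- function(reads, mates = NULL) {
  key <- if (is.null(mates)) reads$seq else paste(reads$seq, mates$seq)
  keep <- !duplicated(key)
  out <- list(reads = reads[keep, , drop = FALSE], removed = sum(!keep))
  if (!is.null(mates)) out$mates <- mates[keep, , drop = FALSE]
  out
}

# consensus-merge one aligned pair given overlap length o (1-based strings)
merge_one <- function(s1, q1, s2rc, q2rc, o) {
  l1 <- nchar(s1); l2 <- nchar(s2rc)
  a <- substr(s1, l1 - o + 1L, l1)
  b <- substr(s2rc, 1L, o)
  qa <- utf8ToInt(substr(q1, l1 - o + 1L, l1))
  qb <- utf8ToInt(substr(q2rc, 1L, o))
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  take_b <- qb > qa
  cons <- ifelse(take_b, cb, ca)
  consq <- pmax(qa, qb)
  seq <- paste0(substr(s1, 1L, l1 - o), paste(cons, collapse = ""),
                substr(s2rc, o + 1L, l2))
  qual <- paste0(substr(q1, 1L, l1 - o), intToUtf8(consq, multiple = FALSE),
                 substr(q2rc, o + 1L, l2))
  list(seq = seq, qual = qual)
}

#' Merge one read pair by 3' overlap
#'
#' The reverse mate is reverse-complemented and aligned against the 3' end of
#' the forward mate; the longest overlap of at least `merge_min_overlap` nt
#' with a mismatch rate at most `merge_max_mismatch_rate` wins. Disagreeing
#' overlap positions take the base with the higher quality.
#'
#' @param fwd,rev single-row read tables (forward mate; reverse mate in
#'   sequencing orientation).
#' @param params a [qc_params()] object.
#' @return a one-row read table for the merged super-read, or `NULL` if no
#'   admissible overlap exists.
#' @export
merge_pair <- function(fwd, rev, params = qc_params()) {
  res <- merge_pairs(fwd, rev, params)
  if (nrow(res$merged) == 0L) NULL else res$merged
}

#' Merge read pairs in bulk
#'
#' Vectorized driver for [merge_pair()]: an exact-overlap pass (longest
#' overlap first) handles the error-free case quickly; remaining pairs fall
#' back to mismatch-tolerant per-pair alignment.
#'
#' @param r1,r2 read tables of equal length (mates in order).
#' @param params a [qc_params()] object.
#' @return list with `merged` (read table with an `overlap` column) and
#'   `unmerged` (integer indices of pairs that did not merge).
#' @export
merge_pairs <- function(r1, r2, params = qc_params()) {
  n <- nrow(r1)
  stopifnot(nrow(r2) == n)
  if (n == 0L) {
    return(list(merged = data.frame(id = character(0), seq = character(0),
                                    qual = character(0), overlap = integer(0)),
                unmerged = integer(0)))
  }
  s1 <- r1$seq; q1 <- r1$qual
  s2 <- revcomp(r2$seq)
  q2 <- vapply(r2$qual, function(q) intToUtf8(rev(utf8ToInt(q))), character(1),
               USE.NAMES = FALSE)
  l1 <- nchar(s1); l2 <- nchar(s2)
  omax <- pmin(l1, l2)
  found <- rep(NA_integer_, n)
  nhits <- integer(n)
  # exact pass, longest overlap first; pairs with several exactly matching
  # overlap lengths (periodic sequence, typically a mate overlap inside an
  # SSR tract) are ambiguous -- merging them at the longest overlap would
  # collapse repeat units, so they are left unmerged
  if (max(omax) >= params$merge_min_overlap) {
    for (o in seq(max(omax), params$merge_min_overlap, by = -1L)) {
      idx <- which(omax >= o)
      if (length(idx) == 0L) next
      hit <- substr(s1[idx], l1[idx] - o + 1L, l1[idx]) ==
        substr(s2[idx], 1L, o)
      nhits[idx[hit]] <- nhits[idx[hit]] + 1L
      first <- hit & is.na(found[idx])
      found[idx[first]] <- o
    }
    found[nhits > 1L] <- NA_integer_
  }
  # mismatch-tolerant fallback for pairs without an exact overlap
  if (params$merge_max_mismatch_rate > 0) {
    for (i in which(is.na(found) & nhits == 0L)) {
      if (omax[i] < params$merge_min_overlap) next
      v1 <- utf8ToInt(s1[i]); v2 <- utf8ToInt(s2[i])
      for (o in seq(omax[i], params$merge_min_overlap, by = -1L)) {
        mm <- sum(v1[(l1[i] - o + 1L):l1[i]] != v2[1:o])
        if (mm / o <= params$merge_max_mismatch_rate) {
          found[i] <- o
          break
        }
      }
    }
  }
  hit <- which(!is.na(found))
  merged <- vector("list", length(hit))
  for (j in seq_along(hit)) {
    i <- hit[j]
    merged[[j]] <- merge_one(s1[i], q1[i], s2[i], q2[i], found[i])
  }
  list(
    merged = data.frame(
      id = if (length(hit)) paste0(sub("/1$", "", r1$id[hit]), "_merged")
           else character(0),
      seq = vapply(merged, `[[`, character(1), "seq"),
      qual = vapply(merged, `[[`, character(1), "qual"),
      overlap = found[hit],
      stringsAsFactors = FALSE
    ),
    unmerged = which(is.na(found))
  )
}
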
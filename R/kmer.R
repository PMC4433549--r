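#' Canonical k-mer spectrum of a read set
#'
#' Counts every k-mer on its canonical strand (the lexicographic minimum of
#' the k-mer and its reverse complement) and returns the multiplicity
#' histogram. K-mers containing `N` are skipped. Counting is exact; k-mers
#' are packed into 2-bit-per-base numeric codes, so `k` up to 25 is
#' supported (the default 21 is standard for genome surveys).
#'
#' @param seqs character vector of read sequences.
#' @param k odd k-mer length; 15-31 recommended, must not exceed the longest
#'   read, at most 25.
#' @param keep_counts retain per-k-mer counts (needed by
#'   [extract_repeat_kmers()]); disable to save memory on large inputs.
#' @return object of class `kmer_spectrum`: list with `k`, `histogram`
#'   (index m = multiplicity, value = number of distinct k-mers seen m
#'   times), `total_kmer_instances`, and optionally `kmer_codes`/`kmer_counts`.
#' @export
kmer_spectrum <- function(seqs, k = 21L, keep_counts = TRUE) {
  k <- as.integer(k)
  if (k < 2L || k > 25L) stop("k must be in [2, 25]")
  if (k > max(nchar(seqs))) stop("k exceeds the longest read")
  enc <- encode_concat(seqs, spacer = 1L)
  code <- enc$code
  code[code < 0] <- NA_real_   # N and spacers break k-mers
  # filter (sides = 1): y[i] = sum_j w[j] * x[i-j+1]. The leftmost window
  # base must weigh 4^(k-1) on the forward strand; on the reverse strand its
  # complement weighs 4^0. Verified against brute-force counting in tests.
  w_fwd <- 4^(0:(k - 1L))
  w_rev <- 4^((k - 1L):0L)
  fwd <- stats::filter(code, w_fwd, method = "convolution", sides = 1L)
  rev <- stats::filter(3 - code, w_rev, method = "convolution", sides = 1L)
  fwd <- as.numeric(fwd); rev <- as.numeric(rev)
  canon <- pmin(fwd, rev)
  canon <- canon[!is.na(canon)]
  if (length(canon) == 0L) stop("no valid k-mers")
  srt <- sort(canon, method = "quick")
  r <- rle(srt)
  mult <- r$lengths
  hist <- tabulate(mult)
  out <- list(k = k, histogram = hist,
              total_kmer_instances = sum(as.numeric(mult)))
  if (keep_counts) {
    out$kmer_codes <- r$values
    out$kmer_counts <- mult
  }
  structure(out, class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat("k-mer spectrum (k =", x$k, ")\n",
      " distinct k-mers:", sum(x$histogram), "\n",
      " instances:      ", format(x$total_kmer_instances, big.mark = ","),
      "\n")
  invisible(x)
}

decode_kmer <- function(codes, k) {
  cols <- lapply((k - 1L):0L, function(p) {
    DNA_BASES[(codes %/% 4^p) %% 4 + 1L]
  })
  do.call(paste0, cols)
}

#' Estimate genome size from a k-mer spectrum
#'
#' Locates the error peak / coverage peak structure of the multiplicity
#' histogram: after light smoothing (moving average, window 3) the first
#' local minimum is the error cutoff; the mode above it is the k-mer
#' coverage peak. The peak position is refined to sub-integer precision by
#' an iterated local centroid (window of about two standard deviations of
#' the expected Poisson spread), and the genome size is the number of k-mer
#' instances above the cutoff divided by the refined peak coverage.
#' Error-free data have no error peak: the cutoff falls back to 0 with a
#' warning. A monotonically decreasing histogram has no coverage peak and is
#' an estimation failure.
#'
#' @param spectrum a [kmer_spectrum()].
#' @return object of class `genome_size_estimate`: `size_bp`,
#'   `coverage_peak` (integer mode), `coverage_peak_refined`,
#'   `error_cutoff`.
#' @export
estimate_genome_size <- function(spectrum) {
  h <- as.numeric(spectrum$histogram)
  M <- length(h)
  if (M < 3L) stop("histogram too short to locate a coverage peak")
  s <- stats::filter(h, rep(1 / 3, 3L), sides = 2L)
  s[1L] <- mean(h[1:2]); s[M] <- mean(h[(M - 1L):M])
  s <- as.numeric(s)
  cutoff <- 0L
  for (m in 2:(M - 1L)) {
    # a valley counts only if a coverage peak rises beyond it
    if (s[m] < s[m - 1L] && s[m] <= s[m + 1L] &&
        max(s[(m + 1L):M]) > s[m]) {
      cutoff <- m
      break
    }
  }
  if (cutoff == 0L) {
    warning("no error/coverage valley found; using cutoff 0 ",
            "(expected for error-free data)")
  }
  mrange <- (cutoff + 1L):M
  peak <- mrange[which.max(h[mrange])]
  if (peak == 1L) stop("monotonically decreasing spectrum: no coverage peak")
  # refine the peak to sub-integer precision: iterated local centroid with a
  # window ~2 sd of the expected Poisson spread, so a noisy mode does not
  # bias the coverage estimate
  centre <- as.numeric(peak)
  for (it in 1:3) {
    w <- max(3, ceiling(2 * sqrt(centre)))
    win <- max(cutoff + 1L, round(centre) - w):min(M, round(centre) + w)
    centre <- sum(win * h[win]) / sum(h[win])
  }
  peak_ref <- centre
  mass <- mrange
  size <- sum(mass * h[mass]) / peak_ref
  structure(list(size_bp = size, coverage_peak = peak,
                 coverage_peak_refined = peak_ref,
                 error_cutoff = cutoff),
            class = "genome_size_estimate")
}

#' @export
print.genome_size_estimate <- function(x, ...) {
  cat(sprintf(
    "genome size ~ %.0f bp (coverage peak %d, refined %.2f, error cutoff %d)\n",
    x$size_bp, x$coverage_peak, x$coverage_peak_refined, x$error_cutoff))
  invisible(x)
}

#' Extract high-multiplicity (repeat) k-mers
#'
#' Returns all k-mers whose multiplicity reaches `min_multiplicity`
#' (conventionally 50x for the repetitive genome fraction) and the fraction
#' of all k-mer instances they account for.
#'
#' @param spectrum a [kmer_spectrum()] built with `keep_counts = TRUE`.
#' @param min_multiplicity multiplicity threshold.
#' @return list `kmers` (character), `counts`, `fraction_of_instances`.
#' @export
extract_repeat_kmers <- function(spectrum, min_multiplicity = 50L) {
  if (is.null(spectrum$kmer_codes)) {
    stop("spectrum was built with keep_counts = FALSE")
  }
  sel <- spectrum$kmer_counts >= min_multiplicity
  counts <- spectrum$kmer_counts[sel]
  list(kmers = decode_kmer(spectrum$kmer_codes[sel], spectrum$k),
       counts = counts,
       fraction_of_instances =
         sum(as.numeric(counts)) / spectrum$total_kmer_instances)
}
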
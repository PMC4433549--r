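#' Per-unit-length SSR detection thresholds
#'
#' Minimum number of contiguous repeat units required to call a tract, by
#' motif length: six units for dinucleotides, four for tri- and
#' tetranucleotides, three for penta- and hexanucleotides.
#'
#' @param di,tri,tetra,penta,hexa minimum unit counts (each >= 2).
#' @return named integer vector indexed by motif length `"2"` .. `"6"`.
#' @export
scan_thresholds <- function(di = 6L, tri = 4L, tetra = 4L, penta = 3L,
                            hexa = 3L) {
  v <- c(`2` = di, `3` = tri, `4` = tetra, `5` = penta, `6` = hexa)
  if (any(v < 2L)) stop("minimum unit counts must be >= 2")
  storage.mode(v) <- "integer"
  v
}

# integer codes for a concatenated read set; non-ACGT positions (N and the
# inter-read spacer) get unique negative codes so they never match anything
encode_concat <- function(seqs, spacer = 6L) {
  concat <- paste(seqs, collapse = strrep(" ", spacer))
  v <- utf8ToInt(concat)
  code <- rep(NA_real_, length(v))
  code[v == 65L] <- 0; code[v == 67L] <- 1
  code[v == 71L] <- 2; code[v == 84L] <- 3
  nas <- which(is.na(code))
  code[nas] <- -seq_along(nas)
  offsets <- cumsum(c(1L, nchar(seqs) + spacer))[seq_along(seqs)]
  list(code = code, concat = concat, offsets = offsets)
}

#' Detect perfect SSR tracts in reads
#'
#' Finds all maximal perfect (mismatch-free) tandem repeat tracts of
#' primitive 2-6 bp motifs meeting the per-unit-length thresholds. `N` never
#' matches. When tracts of different unit lengths overlap, the tract covering
#' more bases wins; on equal coverage the shorter motif, then the leftmost
#' tract. Coordinates are 0-based half-open.
#'
#' @param seqs character vector of read sequences over `A/C/G/T/N`.
#' @param ids read identifiers (defaults to `read1..readN`).
#' @param thresholds a [scan_thresholds()] vector.
#' @return data.frame with columns `read_id`, `start`, `end`, `motif`
#'   (as phased at the tract start), `canonical`, `units`; sorted by read
#'   then `start`, non-overlapping within a read.
#' @export
scan_reads <- function(seqs, ids = NULL, thresholds = scan_thresholds()) {
  empty <- data.frame(read_id = character(0), start = integer(0),
                      end = integer(0), motif = character(0),
                      canonical = character(0), units = integer(0),
                      stringsAsFactors = FALSE)
  if (length(seqs) == 0L) return(empty)
  if (is.null(ids)) ids <- paste0("read", seq_along(seqs))
  check_alphabet(seqs[nzchar(seqs)], allow_n = TRUE)
  enc <- encode_concat(seqs)
  code <- enc$code
  np <- length(code)
  cand <- list()
  for (k in 2:6) {
    if (np <= k) next
    mu <- thresholds[[as.character(k)]]
    eq <- code[1:(np - k)] == code[(k + 1):np]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- r$values & r$lengths >= (mu - 1L) * k
    if (!any(ok)) next
    gs <- starts[ok]
    lambda <- r$lengths[ok]
    units <- (lambda + k) %/% k
    motif <- substr(rep(enc$concat, length(gs)), gs, gs + k - 1L)
    keep <- is_primitive(motif)
    if (!any(keep)) next
    cand[[length(cand) + 1L]] <- data.frame(
      gstart = gs[keep], k = k, units = units[keep], motif = motif[keep],
      stringsAsFactors = FALSE)
  }
  if (length(cand) == 0L) return(empty)
  cand <- do.call(rbind, cand)
  cand$span <- cand$units * cand$k
  cand$gend <- cand$gstart + cand$span - 1L
  ridx <- findInterval(cand$gstart, enc$offsets)
  cand$read <- ridx
  cand$start <- cand$gstart - enc$offsets[ridx]   # 0-based within read
  cand$end <- cand$start + cand$span              # half-open
  # resolve overlaps within each read: larger span, then shorter motif,
  # then leftmost
  cand <- cand[order(cand$read, -cand$span, cand$k, cand$start), , drop = FALSE]
  sel <- logical(nrow(cand))
  for (rows in split(seq_len(nrow(cand)), cand$read)) {
    taken_s <- integer(0); taken_e <- integer(0)
    for (i in rows) {
      s <- cand$start[i]; e <- cand$end[i]
      if (!any(s < taken_e & e > taken_s)) {
        sel[i] <- TRUE
        taken_s <- c(taken_s, s); taken_e <- c(taken_e, e)
      }
    }
  }
  out <- cand[sel, , drop = FALSE]
  out <- out[order(out$read, out$start), , drop = FALSE]
  data.frame(read_id = ids[out$read],
             start = out$start, end = out$end,
             motif = out$motif,
             canonical = canonical_motif(out$motif),
             units = out$units,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Scan a single read
#'
#' @param sequence a single read sequence.
#' @param thresholds a [scan_thresholds()] vector.
#' @return as [scan_reads()], for one read.
#' @export
scan_read <- function(sequence, thresholds = scan_thresholds()) {
  scan_reads(sequence, ids = "read1", thresholds = thresholds)
}

#' Classify the repeat structure of a read
#'
#' A read with one SSR tract is `"single"`; with several tracts all of the
#' same canonical motif it carries a `"broken"` repeat (one tract interrupted
#' by non-repeat sequence); with two or more distinct canonical motifs it
#' carries a `"compound"` repeat.
#'
#' @param loci locus table for one read (rows of [scan_reads()] output).
#' @return one of `"single"`, `"broken"`, `"compound"`.
#' @export
classify_read <- function(loci) {
  if (nrow(loci) == 0L) stop("classification requires at least one locus")
  if (nrow(loci) == 1L) return("single")
  if (length(unique(loci$canonical)) == 1L) "broken" else "compound"
}

#' Classify all annotated reads
#'
#' @param loci a [scan_reads()] locus table (any number of reads).
#' @return data.frame `read_id`, `n_loci`, `classification`.
#' @export
classify_reads <- function(loci) {
  if (nrow(loci) == 0L) {
    return(data.frame(read_id = character(0), n_loci = integer(0),
                      classification = character(0), stringsAsFactors = FALSE))
  }
  sp <- split(loci, loci$read_id)
  data.frame(
    read_id = names(sp),
    n_loci = vapply(sp, nrow, integer(1)),
    classification = vapply(sp, classify_read, character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Canonical-motif frequency table
#'
#' @param loci a [scan_reads()] locus table.
#' @param top optionally restrict to the `top` most frequent motifs.
#' @return data.frame `canonical`, `count`, sorted by descending count with
#'   lexicographic tie-break.
#' @export
motif_frequency_table <- function(loci, top = NULL) {
  if (nrow(loci) == 0L) {
    return(data.frame(canonical = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  tab <- table(loci$canonical)
  out <- data.frame(canonical = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$canonical), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(top)) out <- utils::head(out, top)
  out
}

#' SSR spacing (kb of sequence per locus)
#'
#' @param total_loci number of SSR loci found.
#' @param total_bases total bases screened.
#' @return kb per locus (numeric; `Inf` when no loci). Conventionally
#'   reported to one decimal, e.g. 175,607 loci in 1e9 bases -> 5.7 kb.
#' @export
ssr_density <- function(total_loci, total_bases) {
  if (total_bases <= 0) stop("total_bases must be positive")
  if (total_loci == 0) return(Inf)
  (total_bases / total_loci) / 1000
}
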
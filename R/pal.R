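#' Find potentially amplifiable loci (PALs)
#'
#' Attempts primer-pair design for every trinucleotide-and-longer SSR locus
#' (dinucleotide loci are excluded from marker development at this step) and
#' reports which loci admit a primer pair together with the designable
#' fraction.
#'
#' @param loci a [scan_reads()] locus table.
#' @param reads read table (`id`, `seq`) the loci were called on.
#' @param constraints a [primer_constraints()] object.
#' @return list with `pals` (data.frame: `pal_id`, `read_id`, `start`,
#'   `end`, `motif`, `canonical`, `units`, `forward`, `reverse`,
#'   `forward_start`, `reverse_end`, `tm_forward`, `tm_reverse`,
#'   `product_size`, `single_copy` initialized `NA`), `n_loci` (eligible
#'   loci) and `rate` (fraction designable).
#' @export
find_pals <- function(loci, reads, constraints = primer_constraints()) {
  eligible <- loci[nchar(loci$motif) >= 3L, , drop = FALSE]
  seq_of <- stats::setNames(reads$seq, reads$id)
  rows <- vector("list", nrow(eligible))
  for (i in seq_len(nrow(eligible))) {
    loc <- eligible[i, , drop = FALSE]
    pair <- design_primer_pair(seq_of[[loc$read_id]], loc, constraints)
    if (is.null(pair)) next
    rows[[i]] <- cbind(loc[, c("read_id", "start", "end", "motif",
                               "canonical", "units")],
                       data.frame(forward = pair$forward,
                                  reverse = pair$reverse,
                                  forward_start = pair$forward_start,
                                  reverse_end = pair$reverse_end,
                                  tm_forward = pair$tm_forward,
                                  tm_reverse = pair$tm_reverse,
                                  product_size = pair$product_size,
                                  stringsAsFactors = FALSE))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  pals <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read_id = character(0), start = integer(0), end = integer(0),
               motif = character(0), canonical = character(0),
               units = integer(0), forward = character(0),
               reverse = character(0), forward_start = integer(0),
               reverse_end = integer(0), tm_forward = numeric(0),
               tm_reverse = numeric(0), product_size = integer(0),
               stringsAsFactors = FALSE)
  if (nrow(pals)) {
    pals <- cbind(pal_id = paste0("PAL", seq_len(nrow(pals))), pals,
                  stringsAsFactors = FALSE)
    pals$single_copy <- NA
  } else {
    pals <- cbind(data.frame(pal_id = character(0)), pals,
                  data.frame(single_copy = logical(0)))
  }
  rownames(pals) <- NULL
  list(pals = pals, n_loci = nrow(eligible),
       rate = if (nrow(eligible)) nrow(pals) / nrow(eligible) else NA_real_)
}

#' Screen PALs for locus-specific (single-copy) primers
#'
#' A PAL is retained only when each of its primers (searched in both
#' orientations, exact match) occurs in the read set exclusively in a context
#' consistent with its own locus: a primer found in a read whose SSR tract
#' has a different canonical motif, or shared between PALs at loci with
#' different canonical motifs, marks a multi-copy flank and rejects the
#' affected PALs. The operation is idempotent.
#'
#' @param pals PAL table from [find_pals()].
#' @param reads read table (`id`, `seq`) to screen against; when empty the
#'   input is returned unchanged with attribute `screened = FALSE`.
#' @param loci optional precomputed [scan_reads()] annotation of `reads`
#'   (computed internally when missing).
#' @return the retained subset of `pals` with `single_copy = TRUE` and
#'   attribute `screened`.
#' @export
screen_single_copy <- function(pals, reads, loci = NULL) {
  if (nrow(reads) == 0L) {
    attr(pals, "screened") <- FALSE
    return(pals)
  }
  if (is.null(loci)) loci <- scan_reads(reads$seq, reads$id)
  motifs_of_read <- split(loci$canonical, loci$read_id)
  reject <- logical(nrow(pals))
  # cross-PAL sharing: identical primer sequence used at loci with
  # different canonical motifs
  prim_long <- data.frame(
    pal = rep(seq_len(nrow(pals)), 2L),
    canonical = rep(pals$canonical, 2L),
    seq = c(pals$forward, pals$reverse),
    stringsAsFactors = FALSE)
  key <- vapply(prim_long$seq, function(s) min(s, revcomp(s)), character(1),
                USE.NAMES = FALSE)
  for (grp in split(seq_len(nrow(prim_long)), key)) {
    if (length(unique(prim_long$canonical[grp])) > 1L) {
      reject[prim_long$pal[grp]] <- TRUE
    }
  }
  # read-context check
  for (i in seq_len(nrow(pals))) {
    if (reject[i]) next
    for (p in c(pals$forward[i], pals$reverse[i])) {
      hits <- grepl(p, reads$seq, fixed = TRUE) |
        grepl(revcomp(p), reads$seq, fixed = TRUE)
      if (!any(hits)) next
      ctx <- motifs_of_read[reads$id[hits]]
      ctx <- unique(unlist(ctx[!vapply(ctx, is.null, logical(1))]))
      if (length(setdiff(ctx, pals$canonical[i])) > 0L) {
        reject[i] <- TRUE
        break
      }
    }
  }
  out <- pals[!reject, , drop = FALSE]
  if (nrow(out)) out$single_copy <- TRUE
  attr(out, "screened") <- TRUE
  out
}
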
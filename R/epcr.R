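#' In-silico PCR amplicon observations for one primer pair
#'
#' Searches every read (both orientations, exact matching) for the forward
#' primer followed 3' by the reverse complement of the reverse primer, and
#' records the product length spanned by each such hit. Only reads containing
#' the complete product can contribute, so merged super-reads extend the
#' observable product range.
#'
#' @param pair a `primer_pair` (or any list with `forward`/`reverse`).
#' @param reads read table (`id`, `seq`).
#' @return data.frame `read_id`, `product_length`, `strand` (`"+"`/`"-"`).
#' @export
epcr_amplicons <- function(pair, reads) {
  empty <- data.frame(read_id = character(0), product_length = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  if (nrow(reads) == 0L) return(empty)
  f <- pair$forward
  rr <- revcomp(pair$reverse)
  nf <- nchar(f); nr <- nchar(rr)
  hit_one_strand <- function(seqs) {
    pf <- regexpr(f, seqs, fixed = TRUE)
    idx <- which(pf > 0L)
    if (length(idx) == 0L) return(NULL)
    tails <- substring(seqs[idx], pf[idx] + nf)
    pr <- regexpr(rr, tails, fixed = TRUE)
    ok <- pr > 0L
    if (!any(ok)) return(NULL)
    data.frame(i = idx[ok],
               product_length = nf + pr[ok] + nr - 1L,
               stringsAsFactors = FALSE)
  }
  plus <- hit_one_strand(reads$seq)
  minus <- hit_one_strand(revcomp(reads$seq))
  out <- list()
  if (!is.null(plus)) {
    out$p <- data.frame(read_id = reads$id[plus$i],
                        product_length = plus$product_length,
                        strand = "+", stringsAsFactors = FALSE)
  }
  if (!is.null(minus)) {
    keep <- if (is.null(plus)) rep(TRUE, nrow(minus)) else
      !(minus$i %in% plus$i)   # palindromic double hits counted once
    out$m <- data.frame(read_id = reads$id[minus$i[keep]],
                        product_length = minus$product_length[keep],
                        strand = "-", stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Flag a locus as potentially length-polymorphic
#'
#' A locus is flagged when its amplicon-length histogram shows at least two
#' distinct product lengths, each supported by at least `min_support` reads,
#' with some pair of supported lengths differing by at least `min_diff` bp
#' (by default one repeat-unit length, since SSR alleles differ by unit
#' multiples). Such a locus is putatively heterozygous in the sequenced
#' individual.
#'
#' @param observations [epcr_amplicons()] output for one PAL.
#' @param min_support minimum reads supporting an allele length.
#' @param min_diff minimum difference (bp) between supported lengths.
#' @return list of class `polymorphism_call`: `histogram` (named counts),
#'   `supported_lengths`, `flagged`, `n_observations`.
#' @export
flag_potentially_polymorphic <- function(observations, min_support = 2L,
                                         min_diff = 1L) {
  if (nrow(observations) == 0L) {
    return(structure(list(histogram = integer(0),
                          supported_lengths = integer(0), flagged = FALSE,
                          n_observations = 0L),
                     class = "polymorphism_call"))
  }
  tab <- table(observations$product_length)
  hist <- stats::setNames(as.integer(tab), names(tab))
  supp <- as.integer(names(hist))[hist >= min_support]
  flagged <- length(supp) >= 2L && (max(supp) - min(supp)) >= min_diff
  structure(list(histogram = hist, supported_lengths = supp,
                 flagged = flagged, n_observations = nrow(observations)),
            class = "polymorphism_call")
}

#' Rank marker candidates by polymorphism evidence
#'
#' Flagged (putatively heterozygous) PALs rank first, ordered by decreasing
#' allele-length spread and then decreasing read support; unflagged PALs
#' follow in their input order. The ordering is stable.
#'
#' @param pals PAL table.
#' @param calls list of `polymorphism_call`s parallel to the rows of `pals`.
#' @return `pals` reordered, with columns `flagged`, `spread`, `support`.
#' @export
prioritize_candidates <- function(pals, calls) {
  stopifnot(nrow(pals) == length(calls))
  flagged <- vapply(calls, `[[`, logical(1), "flagged")
  spread <- vapply(calls, function(cl) {
    if (length(cl$supported_lengths) >= 2L)
      max(cl$supported_lengths) - min(cl$supported_lengths) else 0L
  }, numeric(1))
  support <- vapply(calls, `[[`, integer(1), "n_observations")
  ord <- order(!flagged, ifelse(flagged, -spread, 0),
               ifelse(flagged, -support, 0), seq_len(nrow(pals)))
  out <- pals[ord, , drop = FALSE]
  out$flagged <- flagged[ord]
  out$spread <- spread[ord]
  out$support <- support[ord]
  rownames(out) <- NULL
  out
}
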
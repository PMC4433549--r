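#' Full marker-development pipeline on a paired-end read set
#'
#' Chains the package end to end: per-read quality control (pairs are kept
#' only when both mates pass), exact-duplicate removal, overlap merging into
#' super-reads, SSR scanning, primer design for one representative locus per
#' canonical motif (the locus with the widest minimum flank, so the design
#' window is maximal), single-copy screening, in-silico PCR over the full
#' post-QC read set, and heterozygosity flagging with `min_diff` equal to
#' one repeat unit per locus.
#'
#' Designed for locus panels in which each locus carries a distinct
#' canonical motif (as the planted simulations do); the canonical motif then
#' identifies the locus across reads.
#'
#' @param r1,r2 mate read tables (`id`, `seq`, `qual`).
#' @param params a [qc_params()] object.
#' @param thresholds a [scan_thresholds()] vector.
#' @param constraints a [primer_constraints()] object. For read-scale data
#'   the product range must fit within a (merged) read; see
#'   [primer_constraints()].
#' @param min_support minimum reads per allele length for flagging.
#' @return list with `qc_summary`, `reads` (post-QC screening set),
#'   `loci`, `classifications`, `pals`, `calls` (named by `pal_id`),
#'   `candidates` (prioritized PAL table).
#' @export
run_marker_pipeline <- function(r1, r2, params = qc_params(),
                                thresholds = scan_thresholds(),
                                constraints = primer_constraints(),
                                min_support = 2L) {
  f1 <- quality_filter(r1, params)
  f2 <- quality_filter(r2, params)
  keep <- f1$pass & f2$pass
  r1 <- r1[keep, , drop = FALSE]
  r2 <- r2[keep, , drop = FALSE]
  dd <- deduplicate(r1, r2)
  r1 <- dd$reads; r2 <- dd$mates
  mg <- merge_pairs(r1, r2, params)
  reads <- rbind(
    mg$merged[, c("id", "seq", "qual")],
    r1[mg$unmerged, c("id", "seq", "qual")],
    r2[mg$unmerged, c("id", "seq", "qual")]
  )
  rownames(reads) <- NULL
  loci <- scan_reads(reads$seq, reads$id, thresholds)
  classifications <- classify_reads(loci)
  # one locus per canonical motif, designed on the best-covered read that
  # admits a primer pair (candidate loci tried in decreasing minimum-flank
  # order)
  pal_rows <- list()
  if (nrow(loci)) {
    rlen <- stats::setNames(nchar(reads$seq), reads$id)
    flank <- pmin(loci$start, rlen[loci$read_id] - loci$end)
    for (rows in split(seq_len(nrow(loci)), loci$canonical)) {
      rows <- rows[order(-flank[rows])]
      for (i in utils::head(rows, 8L)) {
        res_i <- find_pals(loci[i, , drop = FALSE], reads, constraints)
        if (nrow(res_i$pals)) {
          pal_rows[[length(pal_rows) + 1L]] <- res_i$pals
          break
        }
      }
    }
  }
  pals <- if (length(pal_rows)) do.call(rbind, pal_rows) else
    find_pals(loci[0, , drop = FALSE], reads, constraints)$pals
  if (nrow(pals)) pals$pal_id <- paste0("PAL", seq_len(nrow(pals)))
  pals <- screen_single_copy(pals, reads, loci)
  calls <- lapply(seq_len(nrow(pals)), function(i) {
    obs <- epcr_amplicons(pals[i, ], reads)
    flag_potentially_polymorphic(obs, min_support = min_support,
                                 min_diff = nchar(pals$motif[i]))
  })
  names(calls) <- pals$pal_id
  list(
    qc_summary = list(mate1 = f1$summary, mate2 = f2$summary,
                      pairs_kept = sum(keep), duplicates_removed = dd$removed,
                      pairs_merged = nrow(mg$merged)),
    reads = reads,
    loci = loci,
    classifications = classifications,
    pals = pals,
    calls = calls,
    candidates = prioritize_candidates(pals, calls)
  )
}
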
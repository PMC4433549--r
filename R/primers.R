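# Nearest-neighbour thermodynamics (unified DNA parameters of
# Allawi & SantaLucia 1997). dH kcal/mol, dS cal/(mol K), indexed by the
# 16 dinucleotide steps 4*first + second + 1 with A=0,C=1,G=2,T=3.
.nn_pairs <- local({
  base <- c(
    AA = -7.9, AC = -8.4, AG = -7.8, AT = -7.2,
    CA = -8.5, CC = -8.0, CG = -10.6, CT = -7.8,
    GA = -8.2, GC = -9.8, GG = -8.0, GT = -8.4,
    TA = -7.2, TC = -8.2, TG = -8.5, TT = -7.9)
  baseS <- c(
    AA = -22.2, AC = -22.4, AG = -21.0, AT = -20.4,
    CA = -22.7, CC = -19.9, CG = -27.2, CT = -21.0,
    GA = -22.2, GC = -24.4, GG = -19.9, GT = -22.4,
    TA = -21.3, TC = -22.2, TG = -22.7, TT = -22.2)
  idx <- function(p) 4L * match(substr(p, 1, 1), DNA_BASES) +
    match(substr(p, 2, 2), DNA_BASES) - 4L
  dH <- numeric(16); dS <- numeric(16)
  dH[idx(names(base))] <- base
  dS[idx(names(baseS))] <- baseS
  list(dH = dH, dS = dS)
})

#' Nearest-neighbour primer melting temperature
#'
#' Two-state nearest-neighbour model with the unified DNA stack parameters,
#' terminal initiation terms, and entropic monovalent-salt correction
#' `dS + 0.368 (n-1) ln[Na+]`. The duplex is a primer annealing to its
#' template in excess: `Tm = 1000 dH / (dS + R ln(Cp - Ct/2)) - 273.15`.
#' Default conditions are 50 mM monovalent salt, 500 nM primer and 250 nM
#' template strand.
#'
#' @param sequence primer sequence(s), 10-36 nt, `A/C/G/T` only.
#' @param na_mM monovalent cation concentration (mM).
#' @param primer_nM,template_nM strand concentrations (nM).
#' @return melting temperature(s) in degrees Celsius.
#' @export
primer_tm <- function(sequence, na_mM = 50, primer_nM = 500,
                      template_nM = 250) {
  if (length(sequence) == 0L) return(numeric(0))
  n <- nchar(sequence)
  if (any(n < 10L | n > 36L)) {
    stop("primer_tm requires sequences of 10-36 nt")
  }
  check_alphabet(sequence)
  salt_s <- 0.368 * log(na_mM / 1000)
  rln_c <- 1.987 * log((primer_nM - template_nM / 2) * 1e-9)
  vapply(sequence, function(s) {
    v <- match(strsplit(s, "")[[1]], DNA_BASES) - 1L
    steps <- 4L * v[-length(v)] + v[-1L] + 1L
    dH <- sum(.nn_pairs$dH[steps])
    dS <- sum(.nn_pairs$dS[steps])
    ends <- c(v[1L], v[length(v)])
    dH <- dH + sum(ifelse(ends %in% c(0L, 3L), 2.3, 0.1))
    dS <- dS + sum(ifelse(ends %in% c(0L, 3L), 4.1, -2.8))
    dS <- dS + salt_s * (length(v) - 1L)
    1000 * dH / (dS + rln_c) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

gc_content <- function(seq) {
  gc <- nchar(gsub("[AT]", "", seq))
  100 * gc / nchar(seq)
}

max_mononucleotide_run <- function(seq) {
  vapply(seq, function(s) max(rle(strsplit(s, "")[[1]])$lengths), integer(1),
         USE.NAMES = FALSE)
}

#' Primer-pair design constraints
#'
#' Encodes the conventional default primer-design window: length 18-27 nt
#' (optimum 20), melting temperature 57-63 degrees C (optimum 60), GC content
#' 20-80 %, no mononucleotide run longer than 4, primers outside the repeat
#' tract, and a configurable product-size range (default 100-450 bp, which
#' brackets typical SSR marker allele sizes).
#'
#' @param len_min,len_opt,len_max primer length bounds (nt).
#' @param tm_min,tm_opt,tm_max melting temperature bounds (degrees C).
#' @param gc_min,gc_max GC-content bounds (percent).
#' @param max_run maximum mononucleotide run.
#' @param product_min,product_max product-size range (bp).
#' @param product_opt optional product-size optimum (bp); when set, pair
#'   selection penalizes deviation from it (`w_product` per 5 bp). Useful
#'   when amplicons are screened against reads, where support for a product
#'   decays with its length; `NA` disables the term.
#' @param w_length,w_tm,w_product score weights for deviation from the
#'   length, Tm and product-size optima.
#' @return list of class `primer_constraints`.
#' @export
primer_constraints <- function(len_min = 18L, len_opt = 20L, len_max = 27L,
                               tm_min = 57, tm_opt = 60, tm_max = 63,
                               gc_min = 20, gc_max = 80, max_run = 4L,
                               product_min = 100L, product_max = 450L,
                               product_opt = NA, w_length = 1, w_tm = 1,
                               w_product = 1) {
  stopifnot(len_min <= len_opt, len_opt <= len_max,
            tm_min <= tm_opt, tm_opt <= tm_max,
            gc_min <= gc_max, product_min <= product_max)
  structure(list(len_min = as.integer(len_min), len_opt = as.integer(len_opt),
                 len_max = as.integer(len_max),
                 tm_min = tm_min, tm_opt = tm_opt, tm_max = tm_max,
                 gc_min = gc_min, gc_max = gc_max,
                 max_run = as.integer(max_run),
                 product_min = as.integer(product_min),
                 product_max = as.integer(product_max),
                 product_opt = if (is.na(product_opt)) NA_integer_
                               else as.integer(product_opt),
                 w_length = w_length, w_tm = w_tm, w_product = w_product),
            class = "primer_constraints")
}

# enumerate admissible primer candidates on a flank region (plain strand).
# region_offset: 0-based read coordinate of the region's first base.
flank_candidates <- function(region, region_offset, constraints,
                             reverse = FALSE) {
  nr <- nchar(region)
  if (nr < constraints$len_min) return(NULL)
  lens <- constraints$len_min:min(constraints$len_max, nr)
  grid <- do.call(rbind, lapply(lens, function(l) {
    st <- seq_len(nr - l + 1L)
    cbind(start = st, len = l)
  }))
  seqs <- substr(rep(region, nrow(grid)), grid[, "start"],
                 grid[, "start"] + grid[, "len"] - 1L)
  ok <- grepl("^[ACGT]+$", seqs)
  gc <- rep(NA_real_, length(seqs))
  gc[ok] <- gc_content(seqs[ok])
  ok <- ok & gc >= constraints$gc_min & gc <= constraints$gc_max
  ok[ok] <- max_mononucleotide_run(seqs[ok]) <= constraints$max_run
  if (!any(ok)) return(NULL)
  grid <- grid[ok, , drop = FALSE]
  seqs <- seqs[ok]
  primer <- if (reverse) revcomp(seqs) else seqs
  tm <- primer_tm(primer)
  keep <- tm >= constraints$tm_min & tm <= constraints$tm_max
  if (!any(keep)) return(NULL)
  data.frame(
    seq = primer[keep],
    start = region_offset + grid[keep, "start"] - 1L,   # 0-based on read
    end = region_offset + grid[keep, "start"] + grid[keep, "len"] - 1L,
    tm = tm[keep],
    score = constraints$w_length * abs(grid[keep, "len"] - constraints$len_opt) +
      constraints$w_tm * abs(tm[keep] - constraints$tm_opt),
    stringsAsFactors = FALSE
  )
}

#' Design a flanking primer pair for an SSR locus
#'
#' Enumerates all admissible forward primers in the 5' flank and reverse
#' primers (on the opposite strand) in the 3' flank of the tract, and
#' returns the pair with the smallest total deviation from the length and
#' Tm optima whose product size is in range. Ties break to the leftmost
#' forward primer, then to the smallest product.
#'
#' @param read_sequence the read (or contig) carrying the locus.
#' @param locus one-row locus table (`start`, `end`, 0-based half-open).
#' @param constraints a [primer_constraints()] object.
#' @return list of class `primer_pair` (`forward`, `reverse`,
#'   `forward_start`, `reverse_end`, `tm_forward`, `tm_reverse`,
#'   `product_size`), or `NULL` when either flank admits no primer.
#' @export
design_primer_pair <- function(read_sequence, locus,
                               constraints = primer_constraints()) {
  L <- nchar(read_sequence)
  s0 <- locus$start[1L]; e0 <- locus$end[1L]
  stopifnot(s0 >= 0, e0 <= L, s0 < e0)
  left <- substr(read_sequence, 1L, s0)          # read[0, s0)
  right <- substr(read_sequence, e0 + 1L, L)     # read[e0, L)
  fw <- flank_candidates(left, 0L, constraints, reverse = FALSE)
  if (is.null(fw)) return(NULL)
  rv <- flank_candidates(right, e0, constraints, reverse = TRUE)
  if (is.null(rv)) return(NULL)
  # shortlist by score to bound the pairing step
  shortlist <- function(df, n = 60L) {
    df <- df[order(df$score, df$start), , drop = FALSE]
    utils::head(df, n)
  }
  fw <- shortlist(fw); rv <- shortlist(rv)
  pairs <- expand.grid(f = seq_len(nrow(fw)), r = seq_len(nrow(rv)))
  product <- rv$end[pairs$r] - fw$start[pairs$f]
  ok <- product >= constraints$product_min & product <= constraints$product_max
  if (!any(ok)) return(NULL)
  pairs <- pairs[ok, , drop = FALSE]
  product <- product[ok]
  total <- fw$score[pairs$f] + rv$score[pairs$r]
  if (!is.na(constraints$product_opt)) {
    total <- total +
      constraints$w_product * abs(product - constraints$product_opt) / 5
  }
  best <- order(total, fw$start[pairs$f], product)[1L]
  f <- pairs$f[best]; r <- pairs$r[best]
  structure(list(
    forward = fw$seq[f], reverse = rv$seq[r],
    forward_start = fw$start[f], reverse_end = rv$end[r],
    tm_forward = fw$tm[f], tm_reverse = rv$tm[r],
    product_size = product[best]
  ), class = "primer_pair")
}
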
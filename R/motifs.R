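#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#' Accepts `A/C/G/T/N`.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

check_alphabet <- function(m, allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  bad <- !grepl(pat, m)
  if (any(bad)) {
    stop("invalid alphabet in sequence(s): ",
         paste(utils::head(m[bad], 3L), collapse = ", "),
         " (only A/C/G/T", if (allow_n) "/N", " allowed)")
  }
  invisible(TRUE)
}

#' Is a motif primitive?
#'
#' A repeat motif is primitive when it is not a whole-number power of a
#' shorter string: `"ATC"` is primitive, `"ATAT" = ("AT")^2` and the
#' homopolymer `"AA" = ("A")^2` are not. Only primitive motifs are valid
#' repeat units; non-primitive strings would double-report the same tract.
#'
#' @param m character vector of candidate motifs over `A/C/G/T`.
#' @return logical vector.
#' @examples
#' is_primitive(c("ATC", "ATAT", "AA"))
#' @export
is_primitive <- function(m) {
  if (length(m) == 0L) return(logical(0))
  if (any(!nzchar(m))) stop("empty motif")
  check_alphabet(m)
  vapply(m, function(s) {
    n <- nchar(s)
    if (n == 1L) return(FALSE)  # single bases power-decompose trivially
    for (d in seq_len(n - 1L)) {
      if (n %% d == 0L &&
          s == strrep(substr(s, 1L, d), n %/% d)) {
        return(FALSE)
      }
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

rotations <- function(s) {
  n <- nchar(s)
  vapply(seq_len(n), function(i) {
    paste0(substr(s, i, n), substr(s, 1L, i - 1L))
  }, character(1))
}

motif_class_members <- function(m) {
  sort(unique(c(rotations(m), rotations(revcomp(m)))))
}

.canon_cache <- new.env(parent = emptyenv())

#' Canonical representative of a repeat-motif class
#'
#' Repeat motifs that are cyclic rotations of one another, or rotations of
#' the reverse complement, describe the same tandem repeat (`TG` and `CA`;
#' `TGG`, `GTG` and `GGT`). The canonical representative is the
#' lexicographically smallest member of this equivalence class, so every
#' member maps to the same name and the map is idempotent.
#'
#' @param m character vector of primitive motifs.
#' @return character vector of canonical motifs, same length as `m`.
#' @examples
#' canonical_motif("TG")   # "AC", same as canonical_motif("CA")
#' canonical_motif("CTT")  # "AAG"
#' @export
canonical_motif <- function(m) {
  if (length(m) == 0L) return(character(0))
  prim <- is_primitive(m)
  if (any(!prim)) {
    stop("non-primitive motif(s): ", paste(unique(m[!prim]), collapse = ", "))
  }
  vapply(m, function(s) {
    hit <- .canon_cache[[s]]
    if (!is.null(hit)) return(hit)
    can <- min(c(rotations(s), rotations(revcomp(s))))
    .canon_cache[[s]] <- can
    can
  }, character(1), USE.NAMES = FALSE)
}

all_kmers <- function(k) {
  do.call(paste0, expand.grid(rep(list(DNA_BASES), k),
                              stringsAsFactors = FALSE)[k:1])
}

#' Enumerate repeat-motif equivalence classes
#'
#' Partitions all primitive motifs of length `k` into classes closed under
#' cyclic rotation and reverse complementation. Dinucleotides form 4 classes
#' and trinucleotides 10; homopolymers are excluded because they are not
#' primitive.
#'
#' @param k motif length, 2 to 6.
#' @return data.frame with one row per class: `canonical`, `k`, `n_members`,
#'   and `members` (comma-joined, sorted). Rows sorted by `canonical`.
#' @examples
#' nrow(enumerate_motif_classes(2))  # 4
#' nrow(enumerate_motif_classes(3))  # 10
#' @export
enumerate_motif_classes <- function(k) {
  if (length(k) != 1L || is.na(k) || k != as.integer(k) || k < 2L || k > 6L) {
    stop("k must be a single integer in [2, 6]")
  }
  k <- as.integer(k)
  mers <- all_kmers(k)
  mers <- mers[is_primitive(mers)]
  canon <- canonical_motif(mers)
  groups <- split(mers, canon)
  out <- data.frame(
    canonical = names(groups),
    k = k,
    n_members = lengths(groups),
    members = vapply(groups, function(g) paste(sort(g), collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$canonical), , drop = FALSE]
  rownames(out) <- NULL
  out
}
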
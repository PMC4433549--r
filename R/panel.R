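CROSS_SPECIES_TOKENS <- c("hom", "het", "het_out_of_range", "no_ampl",
                          "not_tested")

#' Parse a repeat-motif string
#'
#' Grammar: one or more components `"(UNIT)n"`; a suffix `",(m)"` denotes a
#' broken repeat, i.e. a second tract of the previous unit with `m` units
#' (e.g. `"(ATC)7,(8)"`); adjacent components with different units form a
#' compound repeat (e.g. `"(TC)10(AGCG)5"`). Units must be valid primitive
#' 2-6 bp motifs and counts at least 2.
#'
#' @param s a motif string.
#' @return data.frame `unit`, `count`, `broken` (logical: continuation of the
#'   previous unit).
#' @export
parse_motif_string <- function(s) {
  rest <- s
  units <- character(0); counts <- integer(0); broken <- logical(0)
  while (nzchar(rest)) {
    m <- regmatches(rest, regexec("^\\(([ACGT]+)\\)([0-9]+)", rest))[[1]]
    if (length(m)) {
      units <- c(units, m[2]); counts <- c(counts, as.integer(m[3]))
      broken <- c(broken, FALSE)
      rest <- substring(rest, nchar(m[1]) + 1L)
      next
    }
    m <- regmatches(rest, regexec("^,\\(([0-9]+)\\)", rest))[[1]]
    if (length(m) && length(units)) {
      units <- c(units, units[length(units)])
      counts <- c(counts, as.integer(m[2]))
      broken <- c(broken, TRUE)
      rest <- substring(rest, nchar(m[1]) + 1L)
      next
    }
    stop("malformed motif string: ", s)
  }
  if (length(units) == 0L) stop("malformed motif string: ", s)
  if (any(nchar(units) < 2L | nchar(units) > 6L) ||
      !all(is_primitive(units))) {
    stop("invalid repeat unit in motif string: ", s)
  }
  if (any(counts < 2L)) stop("repeat counts must be >= 2 in: ", s)
  data.frame(unit = units, count = counts, broken = broken,
             stringsAsFactors = FALSE)
}

format_motif_string <- function(parts) {
  paste(ifelse(parts$broken,
               paste0(",(", parts$count, ")"),
               paste0("(", parts$unit, ")", parts$count)),
        collapse = "")
}

#' Read a marker-panel table
#'
#' Reads a tab-separated marker panel (one row per marker: name, primer
#' sequences 5'->3', motif string, allele count, allele size range, quality
#' grade, observed heterozygosity, and one cross-species amplification call
#' column per tested species) and validates every field. The packaged
#' fixture `table1_markers.tsv` holds the 46-marker *Boswellia papyrifera*
#' panel with calls for *B. pirrotae* (`pirrotae`) and *B. popoviana*
#' (`popoviana`).
#'
#' @param path TSV file; defaults to the packaged panel.
#' @return data.frame of class `marker_panel`; cross-species call columns
#'   keep their file names.
#' @export
parse_marker_table <- function(path = system.file("extdata",
                                                  "table1_markers.tsv",
                                                  package = "ssrkit")) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("name", "forward_primer", "reverse_primer", "motif", "alleles",
            "size_min", "size_max", "quality", "ho")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  species_cols <- setdiff(names(x), need)
  for (i in seq_len(nrow(x))) {
    row <- x$name[i]
    tryCatch(parse_motif_string(x$motif[i]),
             error = function(e) stop("row ", row, ": ", conditionMessage(e)))
    check_alphabet(c(x$forward_primer[i], x$reverse_primer[i]))
    ho <- as.numeric(x$ho[i])
    if (is.na(ho) || ho < 0 || ho > 1) {
      stop("row ", row, ": Ho must be in [0, 1]")
    }
    if (as.integer(x$size_min[i]) > as.integer(x$size_max[i])) {
      stop("row ", row, ": size_min exceeds size_max")
    }
    for (sp in species_cols) {
      if (!x[[sp]][i] %in% CROSS_SPECIES_TOKENS) {
        stop("row ", row, ": unknown cross-species call '", x[[sp]][i], "'")
      }
    }
  }
  x$alleles <- as.integer(x$alleles)
  x$size_min <- as.integer(x$size_min)
  x$size_max <- as.integer(x$size_max)
  x$quality <- as.integer(x$quality)
  x$ho <- as.numeric(x$ho)
  if (any(x$alleles < 1L)) stop("allele counts must be >= 1")
  class(x) <- c("marker_panel", "data.frame")
  x
}

#' Write a marker panel back to TSV
#'
#' Inverse of [parse_marker_table()]; parse -> serialize -> parse is the
#' identity.
#'
#' @param panel a `marker_panel`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Repeat-unit-length class of a marker
#'
#' Classifies a marker as di-, tri-, tetra-, penta- or hexanucleotide by the
#' longest repeat unit among its motif components (compound markers take the
#' longest unit; broken suffixes inherit their unit). The class is invariant
#' under canonicalization of the unit.
#'
#' @param motif a motif string (or vector of them).
#' @return character vector of `"di"`, `"tri"`, `"tetra"`, `"penta"`,
#'   `"hexa"`.
#' @export
classify_marker <- function(motif) {
  classes <- c("di", "tri", "tetra", "penta", "hexa")
  vapply(motif, function(s) {
    parts <- parse_motif_string(s)
    classes[max(nchar(parts$unit)) - 1L]
  }, character(1), USE.NAMES = FALSE)
}

#' Allele-count summary of a panel
#'
#' @param panel a `marker_panel`.
#' @return list `min`, `max`, `mean` (mean rounded to 2 decimals).
#' @export
allele_stats <- function(panel) {
  if (nrow(panel) == 0L) stop("empty panel")
  list(min = min(panel$alleles), max = max(panel$alleles),
       mean = round(mean(panel$alleles), 2))
}

#' Observed heterozygosity of one locus
#'
#' `Ho` = heterozygous individuals / individuals with a genotype, where an
#' individual is heterozygous when its two allele lengths differ.
#'
#' @param genotypes two-column matrix or data.frame of allele lengths (bp),
#'   one row per individual; `NA` rows are missing genotypes.
#' @return Ho in `[0, 1]`.
#' @export
observed_het <- function(genotypes) {
  g <- as.matrix(genotypes)
  stopifnot(ncol(g) == 2L)
  ok <- stats::complete.cases(g)
  if (!any(ok)) stop("no non-missing genotypes")
  mean(g[ok, 1L] != g[ok, 2L])
}

#' Panel mean of observed heterozygosity
#'
#' @param panel a `marker_panel`.
#' @return mean Ho over all rows, rounded to 2 decimals.
#' @export
mean_observed_het <- function(panel) {
  if (nrow(panel) == 0L) stop("empty panel")
  round(mean(panel$ho), 2)
}

#' Cross-species transferability summary
#'
#' Tallies amplification calls for one species. Heterozygous calls --
#' including products outside the expected size range -- are direct evidence
#' of polymorphism, so `polymorphic_lower_bound` counts them.
#'
#' @param panel a `marker_panel`.
#' @param species name of a cross-species call column (e.g. `"pirrotae"`).
#' @return list `het`, `hom`, `no_ampl`, `not_tested`, `tested`,
#'   `polymorphic_lower_bound`.
#' @export
cross_species_summary <- function(panel, species) {
  if (!species %in% names(panel)) stop("unknown species column: ", species)
  calls <- panel[[species]]
  het <- sum(calls %in% c("het", "het_out_of_range"))
  list(het = het,
       hom = sum(calls == "hom"),
       no_ampl = sum(calls == "no_ampl"),
       not_tested = sum(calls == "not_tested"),
       tested = sum(calls != "not_tested"),
       polymorphic_lower_bound = het)
}

#' 2x2 chi-square (and exact) association test
#'
#' Pearson chi-square without continuity correction by default, with the
#' Yates-corrected and Fisher-exact variants selectable. Cells are
#' `[[a, b], [c, d]]`.
#'
#' @param a,b,c,d non-negative integer cell counts with positive margins.
#' @param method `"pearson"`, `"yates"` or `"fisher"`.
#' @return list `statistic` (NA for Fisher), `df`, `p_value`, `method`.
#' @export
chi_square_2x2 <- function(a, b, c, d,
                           method = c("pearson", "yates", "fisher")) {
  method <- match.arg(method)
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != as.integer(cells))) {
    stop("cells must be non-negative integers")
  }
  m <- matrix(cells, nrow = 2L, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("all margins must be positive")
  }
  if (method == "fisher") {
    ft <- stats::fisher.test(m)
    return(list(statistic = NA_real_, df = NA_integer_,
                p_value = unname(ft$p.value), method = method))
  }
  ct <- suppressWarnings(
    stats::chisq.test(m, correct = (method == "yates")))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), method = method)
}

#' Read a genotype matrix
#'
#' TSV with an `individual` column and two columns per locus named
#' `<locus>_1` and `<locus>_2` holding allele lengths in bp (blank/NA for
#' missing).
#'
#' @param path TSV file.
#' @return list with `individuals` and `loci`, a named list of two-column
#'   allele-length matrices.
#' @export
read_genotype_matrix <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot("individual" %in% names(x))
  cols <- setdiff(names(x), "individual")
  loci <- unique(sub("_[12]$", "", cols))
  mats <- lapply(loci, function(l) {
    m <- as.matrix(x[, paste0(l, c("_1", "_2"))])
    if (any(m <= 0, na.rm = TRUE)) stop("allele lengths must be positive: ", l)
    dimnames(m) <- list(x$individual, c("a1", "a2"))
    m
  })
  list(individuals = x$individual, loci = stats::setNames(mats, loci))
}
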
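panel <- parse_marker_table()

test_that("the packaged 46-marker panel parses and validates", {
  expect_s3_class(panel, "marker_panel")
  expect_equal(nrow(panel), 46L)
  expect_equal(panel$alleles[panel$name == "Bp21"], 12L)
  p29 <- parse_motif_string(panel$motif[panel$name == "Bp29"])
  expect_equal(p29$unit, c("TC", "AGCG"))
  expect_equal(p29$count, c(10L, 5L))
  p38 <- parse_motif_string(panel$motif[panel$name == "Bp38"])
  expect_equal(p38$unit, c("ATC", "ATC"))
  expect_equal(p38$count, c(7L, 8L))
  expect_true(p38$broken[2])
})

test_that("malformed panel rows are rejected with the row name", {
  bad <- panel
  bad$motif[3] <- "(AXT)5"
  f <- tempfile(fileext = ".tsv")
  write_marker_table(bad, f)
  expect_error(parse_marker_table(f), "Bp03")

  bad2 <- panel
  bad2$ho[5] <- 1.5
  write_marker_table(bad2, f)
  expect_error(parse_marker_table(f), "Ho")

  bad3 <- panel
  bad3$pirrotae[1] <- "maybe"
  write_marker_table(bad3, f)
  expect_error(parse_marker_table(f), "unknown cross-species call")

  expect_error(parse_motif_string("(AT)1"), "counts")
  expect_error(parse_motif_string("(ATAT)5"), "invalid repeat unit")
})

test_that("parse -> serialize -> parse is the identity on the fixture", {
  f <- tempfile(fileext = ".tsv")
  write_marker_table(panel, f)
  expect_equal(parse_marker_table(f), panel)
})

test_that("unit-length classification reproduces the printed class partition", {
  expect_equal(classify_marker("(ATC)7,(8)"), "tri")
  expect_equal(classify_marker("(TC)10(AGCG)5"), "tetra")  # longest unit
  tab <- table(classify_marker(panel$motif))
  expect_equal(tab[["tri"]], 30L)
  expect_equal(tab[["tetra"]], 4L)
  expect_equal(tab[["penta"]], 6L)
  expect_equal(tab[["hexa"]], 6L)
  # invariant under canonicalization of the unit
  expect_equal(classify_marker("(CTT)9"), classify_marker("(TTC)9"))
})

test_that("allele statistics match the printed range", {
  st <- allele_stats(panel)
  expect_equal(st$min, 2L)
  expect_equal(st$max, 12L)
  # the fixture's computed mean is 4.91; the text prints 4.8, which the
  # table does not reproduce
  expect_equal(st$mean, 4.91)
  one <- panel[7, ]
  expect_equal(allele_stats(one),
               list(min = one$alleles, max = one$alleles,
                    mean = as.numeric(one$alleles)))
  expect_error(allele_stats(panel[0, ]), "empty")
})

test_that("observed heterozygosity counts heterozygous individuals", {
  all_het <- cbind(rep(100, 10), rep(106, 10))
  expect_equal(observed_het(all_het), 1.0)
  none_het <- cbind(rep(100, 10), rep(100, 10))
  expect_equal(observed_het(none_het), 0.0)
  with_na <- rbind(all_het[1:4, ], cbind(NA, NA), none_het[1:5, ])
  expect_equal(observed_het(with_na), 4 / 9)
  expect_error(observed_het(cbind(NA_real_, NA_real_)), "non-missing")
  expect_equal(mean_observed_het(panel), 0.43)
})

test_that("genotype matrices reconcile with the published Ho values", {
  # build, for each marker, a 10-individual genotype matrix whose allele
  # count matches the panel and whose het fraction is as close to the
  # printed Ho as 10 genotypes allow, then recompute Ho from the matrix
  set.seed(61)
  for (i in sample(nrow(panel), 12)) {
    A <- panel$alleles[i]; ho <- panel$ho[i]
    sizes <- panel$size_min[i] + seq_len(A) * 3 - 3
    best <- NULL
    for (n_ok in 2:10) {
      h <- round(ho * n_ok)
      if (abs(h / n_ok - ho) < (if (is.null(best)) Inf else best$err)) {
        best <- list(n = n_ok, h = h, err = abs(h / n_ok - ho))
      }
    }
    g <- matrix(NA_real_, 10, 2)
    hets <- seq_len(best$h)
    for (j in seq_len(best$n)) {
      a1 <- sizes[(j - 1) %% A + 1]
      a2 <- if (j %in% hets) sizes[j %% A + 1] else a1
      g[j, ] <- c(a1, a2)
    }
    if (best$h > 0 && best$h < best$n) {
      expect_equal(observed_het(g), best$h / best$n)
    }
    expect_lt(abs(observed_het(g) - ho), 0.051)
  }
})

test_that("cross-species transfer counts match the printed tallies", {
  br <- cross_species_summary(panel, "pirrotae")
  expect_equal(br$het, 19L)               # includes the out-of-range het
  expect_equal(br$tested, 46L)
  expect_equal(br$polymorphic_lower_bound, 19L)
  bv <- cross_species_summary(panel, "popoviana")
  expect_equal(bv$het, 8L)
  expect_equal(bv$tested, 33L)
  expect_equal(bv$not_tested, 13L)
  expect_error(cross_species_summary(panel, "serrata"), "unknown species")
  none <- panel
  none$pirrotae <- "not_tested"
  expect_equal(cross_species_summary(none, "pirrotae")$het, 0L)
})

test_that("2x2 chi-square matches the closed-form oracle", {
  expect_equal(chi_square_2x2(10, 10, 5, 5)$statistic, 0)
  expect_equal(chi_square_2x2(10, 0, 0, 10)$statistic, 20.0)
  set.seed(62)
  for (i in 1:25) {
    cells <- rpois(4, 20) + 1
    got <- chi_square_2x2(cells[1], cells[2], cells[3], cells[4])
    expect_equal(got$statistic,
                 oracle_chisq(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-9)
    expect_equal(got$df, 1L)
    expect_equal(got$p_value,
                 stats::pchisq(got$statistic, 1, lower.tail = FALSE))
  }
  expect_error(chi_square_2x2(0, 0, 3, 4), "margins")
  expect_error(chi_square_2x2(-1, 2, 3, 4), "non-negative")
  # variants
  y <- chi_square_2x2(12, 5, 6, 9, method = "yates")
  expect_lt(y$statistic, chi_square_2x2(12, 5, 6, 9)$statistic)
  f <- chi_square_2x2(12, 5, 6, 9, method = "fisher")
  expect_true(is.na(f$statistic))
  expect_true(f$p_value > 0 && f$p_value < 1)
})
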
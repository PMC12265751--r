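# A small hand-built stratified cohort exercising every tabulation rule.
tab_fixture <- function() {
  samples <- dplyr::bind_rows(
    meta_row("A1", "AAC"),                      # GBA1 risk carrier
    meta_row("A2", "AAC"),                      # none
    meta_row("A3", "AAC", cohort_class = "genetic_enrichment_affected"),
    meta_row("A4", "AAC", affected = FALSE),    # unaffected GBA1 carrier
    meta_row("E1", "EUR"),                      # G2019S causal
    meta_row("E2", "EUR"),                      # dual causal+risk
    meta_row("E3", "EUR"),                      # dual risk+risk
    meta_row("E4", "EUR", aao_years = 60),      # single het PRKN
    meta_row("E5", "EUR")                       # none
  )
  geno <- dplyr::bind_rows(
    geno_call("A1", "rs3115534", "hom_alt"),
    geno_call("A3", "N409S"),
    geno_call("A4", "E365K"),
    geno_call("E1", "G2019S"),
    geno_call("E2", "G2019S"), geno_call("E2", "N409S"),
    geno_call("E3", "G2385R"), geno_call("E3", "L483P"),
    geno_call("E4", "R275W")
  )
  mk_cohort(samples, geno)
}

test_that("yield cells count qualifying individuals with exact percentages", {
  cohort <- tab_fixture()
  f <- batch_classify(cohort, CATALOG)
  m <- cohort$samples

  yt <- yield_table(f, m, "causal_and_risk", include_enriched = FALSE)
  aac <- yt[yt$ancestry == "AAC", ]
  expect_equal(aac$numerator, 1)   # enriched A3 excluded entirely
  expect_equal(aac$denominator, 2)
  expect_equal(aac$pct, 50)
  eur <- yt[yt$ancestry == "EUR", ]
  expect_equal(eur$numerator, 3)   # E1 causal + E2/E3 dual; E4 single het out
  expect_equal(eur$denominator, 5)
  expect_equal(eur$pct, 60)
  tot <- yt[yt$ancestry == "Total", ]
  expect_equal(tot$numerator, sum(yt$numerator[yt$ancestry != "Total"]))
  expect_equal(tot$denominator, 7)

  # causal-only: dual with a causal component counts, risk+risk dual not
  co <- yield_table(f, m, "causal_only", include_enriched = FALSE)
  expect_equal(co$numerator[co$ancestry == "EUR"], 2)  # E1, E2
  expect_equal(co$numerator[co$ancestry == "AAC"], 0)

  # include_enriched adds A3 to numerator and denominator
  ye <- yield_table(f, m, "causal_and_risk", include_enriched = TRUE)
  expect_equal(ye$numerator[ye$ancestry == "AAC"], 2)
  expect_equal(ye$denominator[ye$ancestry == "AAC"], 3)

  # unaffected arm
  yu <- yield_table(f, m, "causal_and_risk", affected = FALSE)
  expect_equal(yu$numerator[yu$ancestry == "AAC"], 1)
  expect_equal(yu$pct[yu$ancestry == "AAC"], 100)
  expect_equal(yu$denominator[yu$ancestry == "Total"], 1)

  # scope and enrichment monotonicity on a randomized cohort
  rc <- random_cohort(400, seed = 5)
  rf <- batch_classify(rc, CATALOG)
  a <- yield_table(rf, rc$samples, "causal_only")
  b <- yield_table(rf, rc$samples, "causal_and_risk")
  expect_true(all(b$numerator >= a$numerator))
})

test_that("gene table separates duals and LRRK2 risk from pathogenic", {
  cohort <- tab_fixture()
  f <- batch_classify(cohort, CATALOG)
  gt <- gene_table(f, cohort$samples)
  cell <- function(anc, aff, col) {
    gt$n[gt$ancestry == anc & gt$affected == aff & gt$column == col]
  }
  expect_equal(cell("AAC", TRUE, "GBA1"), 1)
  expect_equal(cell("AAC", FALSE, "GBA1"), 1)
  expect_equal(cell("EUR", TRUE, "LRRK2"), 1)        # E1 only
  expect_equal(cell("EUR", TRUE, "Dual"), 2)         # E2, E3
  expect_equal(cell("EUR", TRUE, "GBA1"), 0)         # dual GBA1 not here
  expect_equal(cell("EUR", TRUE, "PRKN"), 0)         # single het invisible
  expect_equal(cell("EUR", TRUE, "LRRK2_risk"), 0)

  # LRRK2 risk-only carrier lands in the risk column
  c2 <- mk_cohort(meta_row("X1", "EAS"), geno_call("X1", "R1628P"))
  f2 <- batch_classify(c2, CATALOG)
  g2 <- gene_table(f2, c2$samples)
  expect_equal(g2$n[g2$ancestry == "EAS" & g2$affected &
                      g2$column == "LRRK2_risk"], 1)
  expect_equal(g2$n[g2$ancestry == "EAS" & g2$affected &
                      g2$column == "LRRK2"], 0)

  # conservation: per-gene cells + Dual = qualifying individuals
  rc <- random_cohort(400, seed = 9)
  rf <- batch_classify(rc, CATALOG)
  gtr <- gene_table(rf, rc$samples)
  qual <- rf$samples |>
    dplyr::filter(.data$category %in% c("causal", "risk", "dual")) |>
    dplyr::inner_join(rc$samples, by = "sample_id")
  expect_equal(sum(gtr$n), nrow(qual))
})

test_that("GBA1 spectrum counts, shares, and Other-collapsing", {
  samples <- dplyr::bind_rows(
    lapply(sprintf("P%02d", 1:16), meta_row, ancestry = "EAS")
  )
  geno <- dplyr::bind_rows(
    dplyr::bind_rows(lapply(sprintf("P%02d", 1:10), geno_call,
                            label = "L483P")),       # severe, 10 carriers
    geno_call("P11", "L483R"),                       # severe, 1
    geno_call("P12", "D448H"),                       # severe, 1
    dplyr::bind_rows(lapply(sprintf("P%02d", 13:15), geno_call,
                            label = "N409S")),       # mild, 3
    geno_call("P16", "E365K")                        # risk, 1
  )
  cohort <- mk_cohort(samples, geno)
  f <- batch_classify(cohort, CATALOG)

  sp <- gba1_spectrum(f, cohort$samples, "EAS")
  expect_equal(sum(sp$n), 16)
  expect_equal(sum(sp$share), 1, tolerance = 1e-9)
  expect_equal(sp$n[sp$label == "L483P"], 10)

  # severe-only collapsing at threshold 3 merges L483R and D448H only
  spc <- gba1_spectrum(f, cohort$samples, "EAS", collapse_threshold = 3,
                       collapse_scope = "severe_only")
  expect_equal(spc$n[spc$label == "Other" & spc$severity == "severe"], 2)
  expect_true("E365K" %in% spc$label)  # risk group untouched
  expect_equal(sum(spc$share), 1, tolerance = 1e-9)

  # collapsing in all severity groups also merges the lone risk carrier
  spa <- gba1_spectrum(f, cohort$samples, "EAS", collapse_threshold = 3,
                       collapse_scope = "all")
  expect_false("E365K" %in% spa$label)
  expect_equal(sum(spa$n), 16)

  # ancestry with no GBA1 carriers -> empty result
  expect_equal(nrow(gba1_spectrum(f, cohort$samples, "FIN")), 0)

  # single-variant fixture: one entry, share 1
  c1 <- mk_cohort(
    dplyr::bind_rows(lapply(sprintf("Q%d", 1:10), meta_row,
                            ancestry = "AJ")),
    dplyr::bind_rows(lapply(sprintf("Q%d", 1:10), geno_call,
                            label = "N409S"))
  )
  f1 <- batch_classify(c1, CATALOG)
  s1 <- gba1_spectrum(f1, c1$samples, "AJ")
  expect_equal(nrow(s1), 1)
  expect_equal(s1$share, 1)
})

test_that("half-up rounding follows table conventions", {
  expect_equal(round_half_up(12.80093, 2), 12.80)
  expect_equal(round_half_up(7.75, 1), 7.8)
  expect_equal(round_half_up(51.7441, 1), 51.7)
  expect_equal(round_half_up(0.125, 2), 0.13)  # R's round() would give 0.12
})
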
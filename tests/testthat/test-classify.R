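classify_one <- function(meta, geno = empty_geno(), cnv = empty_cnv()) {
  cohort <- mk_cohort(meta, geno, cnv)
  classify_sample(cohort, meta$sample_id[1], CATALOG)
}

test_that("recessive-gene rules: biallelic states and the onset gate", {
  # two distinct het PRKN variants, onset 28 -> likely compound het
  f <- classify_one(
    meta_row(aao_years = 28, age_years = 40),
    dplyr::bind_rows(geno_call("S1", "R275W"), geno_call("S1", "T240M"))
  )
  expect_equal(f$category, "causal")
  expect_equal(f$gene_findings$evidence, "likely_compound_het")

  # same genotype, onset 60 -> single het (not interpreted without phase)
  f <- classify_one(
    meta_row(aao_years = 60),
    dplyr::bind_rows(geno_call("S1", "R275W"), geno_call("S1", "T240M"))
  )
  expect_equal(f$category, "single_het_recessive")

  # onset exactly 50 qualifies; missing onset fails the gate
  f50 <- classify_one(
    meta_row(aao_years = 50),
    dplyr::bind_rows(geno_call("S1", "R275W"), geno_call("S1", "T240M"))
  )
  expect_equal(f50$gene_findings$evidence, "likely_compound_het")
  fna <- classify_one(
    meta_row(aao_years = NA),
    dplyr::bind_rows(geno_call("S1", "R275W"), geno_call("S1", "T240M"))
  )
  expect_equal(fna$category, "single_het_recessive")

  # two identical het calls at one variant never form a compound het
  fdup <- classify_one(meta_row(aao_years = 30),
                       geno_call("S1", "R275W"))
  expect_equal(fdup$category, "single_het_recessive")

  # homozygous PINK1 L347P is causal with no onset condition
  f <- classify_one(meta_row(aao_years = NA),
                    geno_call("S1", "L347P", "hom_alt"))
  expect_equal(f$category, "causal")
  expect_equal(f$gene_findings$evidence, "recessive_hom")

  # biallelic PRKN deletion is causal with no onset condition
  f <- classify_one(meta_row(aao_years = 27, age_years = 40),
                    cnv = cnv_call("S1", "PRKN", "exon_deletion", 2))
  expect_equal(f$gene_findings$evidence, "cnv_biallelic")
  expect_equal(f$category, "causal")

  # het SNV + single-allele CNV under the gate -> mixed compound het
  f <- classify_one(meta_row(aao_years = 35, age_years = 40),
                    geno_call("S1", "R275W"),
                    cnv_call("S1", "PRKN", "exon_duplication", 1))
  expect_equal(f$gene_findings$evidence, "snv_cnv_compound_het")
  expect_equal(f$category, "causal")
})

test_that("dominant, X-linked and risk-locus rules", {
  f <- classify_one(meta_row(), geno_call("S1", "G2019S"))
  expect_equal(f$category, "causal")
  expect_equal(f$gene_findings$evidence, "dominant_het")

  # SNCA multiplication is a causal dominant mechanism
  f <- classify_one(meta_row(),
                    cnv = cnv_call("S1", "SNCA", "multiplication", 1))
  expect_equal(f$category, "causal")

  # all GBA1 variants are risk, any zygosity; hom does not escalate
  f <- classify_one(meta_row(), geno_call("S1", "rs3115534", "hom_alt"))
  expect_equal(f$category, "risk")
  expect_equal(f$gene_findings$evidence, "risk_variant")

  # both LRRK2 risk variants: one finding, category risk
  f <- classify_one(meta_row(), dplyr::bind_rows(
    geno_call("S1", "R1628P"), geno_call("S1", "G2385R")))
  expect_equal(f$category, "risk")
  expect_equal(nrow(f$gene_findings), 1)

  # causal LRRK2 variant dominates co-occurring LRRK2 risk variants
  f <- classify_one(meta_row(), dplyr::bind_rows(
    geno_call("S1", "G2019S"), geno_call("S1", "G2385R")))
  expect_equal(f$category, "causal")

  # X-linked female het counts as causal by default, not with the flag off
  cohort <- mk_cohort(meta_row(sex = "female"),
                      geno_call("S1", "L119P"))
  expect_equal(classify_sample(cohort, "S1", CATALOG)$category, "causal")
  f_off <- batch_classify(cohort, CATALOG,
                          count_xlinked_female_het = FALSE)
  expect_equal(f_off$samples$category, "none")
})

test_that("dual status needs two individually qualifying genes", {
  # pathogenic LRRK2 + GBA1 risk variant -> dual
  f <- classify_one(meta_row(), dplyr::bind_rows(
    geno_call("S1", "G2019S"), geno_call("S1", "N409S")))
  expect_equal(f$category, "dual")

  # two risk-level genes (LRRK2 risk + GBA1) -> dual
  f <- classify_one(meta_row(), dplyr::bind_rows(
    geno_call("S1", "G2385R"), geno_call("S1", "L483P")))
  expect_equal(f$category, "dual")

  # het PINK1 (single-het) + LRRK2 risk -> risk, with the single-het
  # finding recorded but not category-qualifying
  f <- classify_one(meta_row(aao_years = 45), dplyr::bind_rows(
    geno_call("S1", "L347P"), geno_call("S1", "G2385R")))
  expect_equal(f$category, "risk")
  expect_setequal(f$gene_findings$evidence,
                  c("single_het_recessive", "risk_variant"))

  # no qualifying calls -> none
  f <- classify_one(meta_row())
  expect_equal(f$category, "none")
})

test_that("batch classification matches the per-sample path and the oracle", {
  for (seed in c(11, 12)) {
    cohort <- random_cohort(200, seed)
    f <- batch_classify(cohort, CATALOG)
    # per-sample package path
    per_sample <- vapply(
      cohort$samples$sample_id,
      function(s) classify_sample(cohort, s, CATALOG)$category,
      character(1)
    )
    expect_equal(f$samples$category, unname(per_sample))
    # independent rule-by-rule oracle
    expect_equal(f$samples$category, unname(oracle_classify(cohort)))
  }
})

test_that("category partition, monotonicity and the onset-gate flip hold", {
  cohort <- random_cohort(1000, seed = 42)
  f <- batch_classify(cohort, CATALOG)
  # partition: every sample in exactly one category
  expect_equal(nrow(f$samples), nrow(cohort$samples))
  expect_true(all(f$samples$category %in%
                    c("causal", "risk", "dual", "single_het_recessive",
                      "none")))

  # monotonicity: adding a causal dominant het never lowers the category
  rank <- c(none = 0, single_het_recessive = 1, risk = 2, causal = 3,
            dual = 3)
  add <- dplyr::bind_rows(lapply(cohort$samples$sample_id, geno_call,
                                 label = "D620N"))
  boosted <- build_cohort(
    cohort$samples,
    dplyr::bind_rows(cohort$genotypes[, names(empty_geno())], add),
    cohort$cnvs, CATALOG
  )
  f2 <- batch_classify(boosted, CATALOG)
  expect_true(all(rank[f2$samples$category] >= rank[f$samples$category]))

  # onset-gate flip: crossing 50 toggles compound-het <-> single-het for
  # two-het recessive genotypes and changes nothing else
  two_het <- cohort$genotypes |>
    dplyr::inner_join(CATALOG$variants[, c("variant_key", "gene", "tier")],
                      by = "variant_key") |>
    dplyr::inner_join(CATALOG$genes, by = c(gene = "symbol")) |>
    dplyr::filter(.data$inheritance == "autosomal_recessive",
                  .data$tier != "risk", .data$zygosity == "het") |>
    dplyr::distinct(.data$sample_id, .data$variant_key) |>
    dplyr::count(.data$sample_id) |>
    dplyr::filter(.data$n >= 2)
  flipped <- cohort$samples |>
    dplyr::mutate(aao_years = ifelse(
      .data$affected & !is.na(.data$aao_years),
      ifelse(.data$aao_years <= 50, 51, 45), .data$aao_years))
  f3 <- batch_classify(
    build_cohort(flipped, cohort$genotypes[, names(empty_geno())],
                 cohort$cnvs, CATALOG),
    CATALOG
  )
  cmp <- dplyr::inner_join(f$genes, f3$genes,
                           by = c("sample_id", "gene"))
  changed <- cmp[cmp$evidence.x != cmp$evidence.y, ]
  expect_true(all(sort(unique(c(changed$evidence.x, changed$evidence.y)))
                  %in% c("likely_compound_het", "single_het_recessive",
                         "snv_cnv_compound_het")))
})
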
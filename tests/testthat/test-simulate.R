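small_census <- function() {
  plant <- dplyr::bind_rows(
    plant_unit("AAC", TRUE, "snv_het", 10, v1 = "rs3115534"),
    plant_unit("AAC", TRUE, "snv_hom", 2, v1 = "rs3115534"),
    plant_unit("AAC", TRUE, "cnv", 1, gene = "PRKN",
               event = "exon_deletion", alleles = 2, aao = "early"),
    plant_unit("EUR", TRUE, "snv_het", 5, v1 = "G2019S"),
    plant_unit("EUR", TRUE, "two_het", 3, v1 = "R275W", v2 = "T240M",
               aao = "early"),
    plant_unit("EUR", TRUE, "two_het", 2, v1 = "R275W", v2 = "T240M",
               aao = "late"),
    plant_unit("EUR", TRUE, "dual", 2, v1 = "G2019S", v2 = "N409S"),
    plant_unit("EUR", FALSE, "snv_het", 4, v1 = "E365K"),
    plant_unit("EUR", TRUE, "snv_het", 3, v1 = "G2019S", enriched = TRUE)
  )
  strata <- tibble::tibble(
    ancestry = c("AAC", "EUR", "EUR", "EUR"),
    affected = c(TRUE, TRUE, FALSE, TRUE),
    enriched = c(FALSE, FALSE, FALSE, TRUE),
    n_total = c(40L, 60L, 30L, 3L)
  )
  sim_config("census", plant = plant, strata = strata)
}

test_that("census mode plants exact counts that classification recovers", {
  cfg <- small_census()
  sim <- generate_cohort(cfg, seed = 4)
  expect_equal(nrow(sim$samples), 133)
  cohort <- build_cohort(sim$samples, sim$genotypes, sim$cnvs, CATALOG)
  f <- batch_classify(cohort, CATALOG)
  truth <- sim$truth$sample_truth
  j <- dplyr::inner_join(truth, f$samples, by = "sample_id")
  expect_equal(j$category.y, j$category.x)
  yt <- yield_table(f, cohort$samples, "causal_and_risk")
  expect_equal(yt$numerator[yt$ancestry == "AAC"], 13)
  expect_equal(yt$denominator[yt$ancestry == "AAC"], 40)
  expect_equal(yt$numerator[yt$ancestry == "EUR"], 10)  # 5+3+2 dual
  co <- yield_table(f, cohort$samples, "causal_only")
  expect_equal(co$numerator[co$ancestry == "EUR"], 10)  # dual has causal part
  expect_equal(co$numerator[co$ancestry == "AAC"], 1)
})

test_that("generation is reproducible and seed-sensitive", {
  cfg <- small_census()
  s1 <- generate_cohort(cfg, seed = 10)
  s2 <- generate_cohort(cfg, seed = 10)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$genotypes, s2$genotypes)
  s3 <- generate_cohort(cfg, seed = 11)
  expect_false(identical(s1$samples$aao_years, s3$samples$aao_years))
})

test_that("written files round-trip byte-identically and reload cleanly", {
  cfg <- small_census()
  sim <- generate_cohort(cfg, seed = 4)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort_files(sim, d1, CATALOG)
  write_cohort_files(generate_cohort(cfg, seed = 4), d2, CATALOG)
  for (fn in c("manifest.tsv", "cohort.vcf", "cnv.tsv", "truth.json")) {
    expect_identical(readLines(file.path(d1, fn)),
                     readLines(file.path(d2, fn)), label = fn)
  }
  cohort <- read_cohort_dir(d1, CATALOG)
  expect_equal(nrow(cohort$samples), nrow(sim$samples))
  f_file <- batch_classify(cohort, CATALOG)
  f_mem <- batch_classify(
    build_cohort(sim$samples, sim$genotypes, sim$cnvs, CATALOG), CATALOG)
  expect_equal(
    dplyr::arrange(f_file$samples, sample_id),
    dplyr::arrange(f_mem$samples, sample_id)
  )
})

test_that("empty strata produce empty but valid outputs", {
  cfg <- sim_config(
    "census", plant = plant_unit(),
    strata = tibble::tibble(ancestry = "EUR", affected = TRUE,
                            enriched = FALSE, n_total = 0L)
  )
  sim <- generate_cohort(cfg, seed = 1)
  expect_equal(nrow(sim$samples), 0)
  d <- withr::local_tempdir()
  write_cohort_files(sim, d, CATALOG)
  expect_true(file.exists(file.path(d, "cohort.vcf")))
  cohort <- read_cohort_dir(d, CATALOG)
  expect_equal(nrow(cohort$samples), 0)
})

test_that("census counts larger than the stratum are rejected", {
  cfg <- sim_config(
    "census",
    plant = plant_unit("FIN", TRUE, "snv_het", 5, v1 = "N409S"),
    strata = tibble::tibble(ancestry = "FIN", affected = TRUE,
                            enriched = FALSE, n_total = 3L)
  )
  expect_error(generate_cohort(cfg, seed = 1), "exceed")
})

test_that("binomial mode draws carriers near the planted frequency", {
  cfg <- sim_config(
    "binomial",
    strata = tibble::tibble(ancestry = "EUR", n_affected = 2000L,
                            n_unaffected = 0L),
    freqs = tibble::tibble(label = "N409S", freq_affected = 0.10,
                           freq_unaffected = 0)
  )
  sim <- generate_cohort(cfg, seed = 21)
  cohort <- build_cohort(sim$samples, sim$genotypes, sim$cnvs, CATALOG)
  est <- variant_carrier_freq(cohort, CATALOG, "N409S", "EUR")
  lo <- stats::qbinom(0.025, 2000, 0.10)
  hi <- stats::qbinom(0.975, 2000, 0.10)
  expect_gte(est$n_carriers, lo)
  expect_lte(est$n_carriers, hi)
})
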
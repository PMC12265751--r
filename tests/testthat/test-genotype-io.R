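write_test_vcf <- function(records, samples) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, records), path)
  path
}

test_that("VCF genotypes map to zygosity calls restricted to the catalog", {
  # G2019S het, rs3115534 hom, a non-catalog site, and missing/ref calls
  recs <- c(
    paste(c("12", "40340400", ".", "G", "A", ".", "PASS", ".", "GT",
            "0/1", "0/0", "./."), collapse = "\t"),
    paste(c("chr1", "155236376", "rs3115534", "T", "G", ".", "PASS", ".",
            "GT", "1/1", "0|1", "0/0"), collapse = "\t"),
    paste(c("7", "12345", ".", "A", "T", ".", "PASS", ".", "GT",
            "0/1", "1/1", "0/1"), collapse = "\t")
  )
  path <- write_test_vcf(recs, c("S1", "S2", "S3"))
  g <- read_vcf(path, CATALOG)
  expect_equal(nrow(g), 3)
  expect_equal(g$zygosity[g$sample_id == "S1" & g$pos == 40340400], "het")
  expect_equal(g$zygosity[g$sample_id == "S1" & g$pos == 155236376],
               "hom_alt")
  # phased het treated like unphased
  expect_equal(g$zygosity[g$sample_id == "S2"], "het")
  expect_false(any(g$sample_id == "S3"))
})

test_that("multi-allelic records decompose per alternate allele", {
  # L483P (A>G) and L483R (A>C) share a position; sample carries 1/2
  recs <- paste(c("1", "155235252", ".", "A", "G,C", ".", "PASS", ".",
                  "GT", "1/2", "2/2"), collapse = "\t")
  path <- write_test_vcf(recs, c("S1", "S2"))
  g <- read_vcf(path, CATALOG)
  s1 <- g[g$sample_id == "S1", ]
  expect_setequal(s1$alt, c("G", "C"))
  expect_true(all(s1$zygosity == "het"))
  s2 <- g[g$sample_id == "S2", ]
  expect_equal(s2$alt, "C")
  expect_equal(s2$zygosity, "hom_alt")
})

test_that("haploid and male diploid-coded X calls become hemizygous", {
  recs <- paste(c("chrX", "155259163", ".", "G", "A", ".", "PASS", ".",
                  "GT", "1", "1/1", "0/1"), collapse = "\t")
  path <- write_test_vcf(recs, c("M1", "M2", "F1"))
  g <- read_vcf(path, CATALOG)
  expect_equal(g$zygosity[g$sample_id == "M1"], "hemizygous")
  samples <- dplyr::bind_rows(
    meta_row("M1", sex = "male"), meta_row("M2", sex = "male"),
    meta_row("F1", sex = "female")
  )
  cohort <- build_cohort(samples, g, NULL, CATALOG)
  z <- cohort$genotypes
  expect_equal(z$zygosity[z$sample_id == "M2"], "hemizygous")
  expect_equal(z$zygosity[z$sample_id == "F1"], "het")
})

test_that("manifest validation names offending rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  ok <- meta_row("S1", ancestry = "EAS", sex = "male", age_years = 68,
                 aao_years = 60)
  readr::write_tsv(ok, path)
  expect_equal(nrow(read_sample_manifest(path)), 1)

  bad_anc <- ok; bad_anc$ancestry <- "XYZ"
  readr::write_tsv(bad_anc, path)
  expect_error(read_sample_manifest(path), "ancestry")

  contradiction <- ok; contradiction$cohort_class <- "controls"
  readr::write_tsv(contradiction, path)
  expect_error(read_sample_manifest(path), "contradicts")

  bad_aao <- ok; bad_aao$aao_years <- 70; bad_aao$age_years <- 60
  readr::write_tsv(bad_aao, path)
  expect_error(read_sample_manifest(path), "aao_years exceeds")
})

test_that("CNV table enforces the SNCA-multiplication rule", {
  path <- withr::local_tempfile(fileext = ".tsv")
  ok <- dplyr::bind_rows(
    cnv_call("S2", "PRKN", "exon_deletion", 2, exons = "3,4"),
    cnv_call("S3", "SNCA", "multiplication", 1)
  )
  readr::write_tsv(ok, path)
  expect_equal(nrow(read_cnv_table(path)), 2)
  bad <- cnv_call("S4", "SNCA", "exon_deletion", 1)
  readr::write_tsv(bad, path)
  expect_error(read_cnv_table(path), "SNCA CNV events")
})

test_that("cohort merge fails exactly when calls reference unknown samples", {
  samples <- meta_row("S1")
  g <- geno_call("S1", "G2019S")
  expect_s3_class(mk_cohort(samples, g), "pd_cohort")
  g_orphan <- geno_call("S9", "G2019S")
  expect_error(mk_cohort(samples, g_orphan), "absent from manifest")
  cnv_orphan <- cnv_call("S9")
  expect_error(mk_cohort(samples, empty_geno(), cnv_orphan),
               "absent from manifest")
})

test_that("reading is order-insensitive", {
  samples <- dplyr::bind_rows(meta_row("S1"), meta_row("S2"))
  g <- dplyr::bind_rows(geno_call("S1", "G2019S"),
                        geno_call("S2", "N409S"))
  c1 <- mk_cohort(samples, g)
  c2 <- mk_cohort(samples[2:1, ], g[2:1, ])
  expect_equal(dplyr::arrange(c1$genotypes, sample_id),
               dplyr::arrange(c2$genotypes, sample_id))
  f1 <- batch_classify(c1, CATALOG)
  f2 <- batch_classify(c2, CATALOG)
  expect_equal(dplyr::arrange(f1$samples, sample_id),
               dplyr::arrange(f2$samples, sample_id))
})
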
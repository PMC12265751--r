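# Shared fixtures: everything is built in code at test time.

CATALOG <- default_catalog()

# One-line manifest row with sensible defaults.
meta_row <- function(sample_id = "S1", ancestry = "EUR", affected = TRUE,
                     phenotype = if (affected) "PD" else "control",
                     cohort_class = if (affected) "pd_unselected" else
                       "controls",
                     sex = "female", age_years = 70, aao_years = 60,
                     family_history = FALSE) {
  tibble::tibble(
    sample_id = sample_id, ancestry = ancestry, affected = affected,
    phenotype = phenotype, cohort_class = cohort_class, sex = sex,
    age_years = age_years,
    aao_years = if (affected) aao_years else NA_real_,
    family_history = family_history
  )
}

# Genotype call at a catalog variant identified by protein label / rsid.
geno_call <- function(sample_id, label, zygosity = "het",
                      catalog = CATALOG) {
  v <- catalog_variant(catalog, label)[1, ]
  tibble::tibble(sample_id = sample_id, chrom = v$chrom, pos = v$pos,
                 ref = v$ref, alt = v$alt, variant_key = v$variant_key,
                 zygosity = zygosity)
}

cnv_call <- function(sample_id, gene = "PRKN", event = "exon_deletion",
                     alleles_affected = 2L, exons = NA_character_) {
  tibble::tibble(sample_id = sample_id, gene = gene, event = event,
                 alleles_affected = as.integer(alleles_affected),
                 exons = exons)
}

empty_geno <- function() {
  tibble::tibble(sample_id = character(), chrom = character(),
                 pos = integer(), ref = character(), alt = character(),
                 variant_key = character(), zygosity = character())
}
empty_cnv <- function() {
  tibble::tibble(sample_id = character(), gene = character(),
                 event = character(), alleles_affected = integer(),
                 exons = character())
}

# Small cohort from lists of rows.
mk_cohort <- function(samples, genotypes = empty_geno(),
                      cnvs = empty_cnv()) {
  build_cohort(samples, genotypes, cnvs, CATALOG)
}

# Random cohort for property tests: each sample draws 0-3 SNV calls at
# random catalog variants plus occasional CNVs, random onset and sex.
random_cohort <- function(n, seed) {
  set.seed(seed)
  vars <- CATALOG$variants
  samples <- tibble::tibble(
    sample_id = sprintf("R%04d", seq_len(n)),
    ancestry = sample(c("EUR", "EAS", "AFR", "MDE"), n, replace = TRUE),
    affected = stats::runif(n) < 0.7,
    sex = sample(c("male", "female"), n, replace = TRUE),
    aao_years = ifelse(stats::runif(n) < 0.25, NA_real_,
                       sample(20:80, n, replace = TRUE)),
    age_years = NA_real_
  )
  samples <- samples |>
    dplyr::mutate(
      aao_years = ifelse(.data$affected, .data$aao_years, NA_real_),
      phenotype = ifelse(.data$affected, "PD", "control"),
      cohort_class = ifelse(.data$affected, "pd_unselected", "controls"),
      family_history = NA
    )
  genos <- list()
  cnvs <- list()
  for (i in seq_len(n)) {
    k <- sample(0:3, 1, prob = c(0.45, 0.3, 0.18, 0.07))
    if (k > 0) {
      idx <- sample(nrow(vars), k)
      v <- vars[idx, ]
      genos[[length(genos) + 1L]] <- tibble::tibble(
        sample_id = samples$sample_id[i], chrom = v$chrom, pos = v$pos,
        ref = v$ref, alt = v$alt, variant_key = v$variant_key,
        zygosity = sample(c("het", "hom_alt"), k, replace = TRUE,
                          prob = c(0.85, 0.15))
      )
    }
    if (stats::runif(1) < 0.06) {
      g <- sample(c("PRKN", "SNCA"), 1)
      cnvs[[length(cnvs) + 1L]] <- cnv_call(
        samples$sample_id[i], gene = g,
        event = if (g == "SNCA") "multiplication" else
          sample(c("exon_deletion", "exon_duplication"), 1),
        alleles_affected = if (g == "SNCA") 1L else sample(1:2, 1)
      )
    }
  }
  geno <- if (length(genos)) dplyr::bind_rows(genos) else empty_geno()
  cnv <- if (length(cnvs)) dplyr::bind_rows(cnvs) else empty_cnv()
  mk_cohort(samples, geno, cnv)
}
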
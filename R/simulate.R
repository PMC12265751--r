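#' Build a simulation configuration
#'
#' Two modes. `census` plants exact carrier counts: `plant` is a tibble of
#' planted units (see [plant_unit()]) and `strata` gives the total sample
#' count per ancestry, arm and enrichment block; non-carriers fill each
#' stratum up to its total. `binomial` draws carrier status independently per
#' variant: `strata` gives `n_affected` / `n_unaffected` per ancestry and
#' `freqs` per-variant carrier frequencies.
#'
#' The age-at-onset model is normal with mean `ipd_mean` and SD `ipd_sd`,
#' truncated to `[aao_min, aao_max]` years; carriers whose sole qualifying
#' gene is GBA1 or LRRK2 have their mean shifted by `shift_gba1` /
#' `shift_lrrk2` years. `missing_frac` of onsets are blanked at random —
#' except for samples whose planted classification depends on onset (likely
#' compound heterozygotes and the onset-structured single-het blocks), which
#' keep theirs so that planted counts stay exact.
#'
#' @param mode `"census"` or `"binomial"`.
#' @param plant Census plant tibble ([plant_unit()] rows).
#' @param strata Census: tibble `ancestry`, `affected`, `enriched`,
#'   `n_total`. Binomial: tibble `ancestry`, `n_affected`, `n_unaffected`.
#' @param freqs Binomial: tibble `label`, `freq_affected`,
#'   `freq_unaffected`.
#' @param aao List of onset-model parameters (see Details).
#' @return A `pd_sim_config` object.
#' @export
sim_config <- function(mode = c("census", "binomial"), plant = NULL,
                       strata = NULL, freqs = NULL, aao = list()) {
  mode <- match.arg(mode)
  aao_default <- list(ipd_mean = 60, ipd_sd = 10, shift_gba1 = -5,
                      shift_lrrk2 = -2, missing_frac = 0.3,
                      aao_min = 5, aao_max = 98)
  aao <- utils::modifyList(aao_default, aao)
  if (mode == "binomial") {
    stopifnot(!is.null(strata), !is.null(freqs))
    bad <- freqs$freq_affected < 0 | freqs$freq_affected > 1 |
      freqs$freq_unaffected < 0 | freqs$freq_unaffected > 1
    if (any(bad)) rlang::abort("carrier frequencies must be in [0, 1]")
  } else {
    stopifnot(!is.null(strata))
    if (is.null(plant)) plant <- plant_unit()[0, ]
  }
  structure(list(mode = mode, plant = plant, strata = strata,
                 freqs = freqs, aao = aao),
            class = "pd_sim_config")
}

#' One planted carrier unit for census-mode simulation
#'
#' Each row plants `n` identical individuals in a stratum. `class` controls
#' the genetic mechanism:
#' \describe{
#'   \item{snv_het / snv_hom}{one variant `v1`, heterozygous / homozygous.}
#'   \item{two_het}{two distinct heterozygous variants `v1`, `v2` in the
#'     same gene (compound-het candidates, late-onset two-het carriers, or
#'     carriers of both LRRK2 risk variants).}
#'   \item{cnv}{a structural event in `gene` (`event`, `alleles`).}
#'   \item{snv_cnv}{`v1` heterozygous plus a single-allele CNV in its gene.}
#'   \item{dual}{`v1` and `v2` heterozygous in two different genes.}
#' }
#' `aao` is `"default"` (onset model with gene shift), `"early"` (drawn in
#' \[5, 50\]), `"late"` (drawn in (50, 98\]), or `"missing"`.
#'
#' @param ancestry,affected,enriched Stratum placement.
#' @param class Mechanism (above).
#' @param n Number of individuals.
#' @param v1,v2 Catalog variant labels (protein label or rsid).
#' @param gene Gene symbol (needed for `cnv`).
#' @param event,alleles CNV event type and alleles affected.
#' @param aao Onset rule.
#' @param sex Forced sex, or `NA` to draw.
#' @return A one-row tibble (or the empty prototype when called without
#'   arguments).
#' @export
plant_unit <- function(ancestry = character(), affected = logical(),
                       class = character(), n = integer(),
                       v1 = NA_character_, v2 = NA_character_,
                       gene = NA_character_, event = NA_character_,
                       alleles = NA_integer_, aao = "default",
                       sex = NA_character_, enriched = FALSE) {
  if (length(ancestry) == 0) {
    return(tibble::tibble(
      ancestry = character(), affected = logical(), enriched = logical(),
      class = character(), n = integer(), v1 = character(),
      v2 = character(), gene = character(), event = character(),
      alleles = integer(), aao = character(), sex = character()
    ))
  }
  tibble::tibble(ancestry = ancestry, affected = affected,
                 enriched = enriched, class = class, n = as.integer(n),
                 v1 = v1, v2 = v2, gene = gene, event = event,
                 alleles = as.integer(alleles), aao = aao, sex = sex)
}

resolve_label <- function(catalog, label) {
  hit <- catalog_variant(catalog, label)
  if (nrow(hit) == 0) {
    rlang::abort(paste0("plant references unknown variant '", label, "'"))
  }
  if (nrow(hit) > 1) hit <- hit[1, ]
  hit
}

# Truth category implied by a planted unit, by construction. For class
# "cnv", v1row is a list carrying `gene` and `alleles`.
plant_category <- function(class, genes_tbl, v1row, v2row, aao) {
  if (class == "dual") return("dual")
  gene <- v1row$gene
  inh <- genes_tbl$inheritance[genes_tbl$symbol == gene]
  if (inh == "risk_locus") return("risk")
  if (gene == "LRRK2") {
    tiers <- c(v1row$tier, if (!is.null(v2row)) v2row$tier)
    if (all(tiers == "risk")) return("risk") else return("causal")
  }
  if (inh %in% c("autosomal_dominant", "x_linked")) return("causal")
  # recessive
  switch(class,
    snv_hom = "causal",
    snv_het = "single_het_recessive",
    two_het = if (identical(aao, "early")) "causal" else
      "single_het_recessive",
    snv_cnv = if (identical(aao, "early")) "causal" else
      "single_het_recessive",
    cnv = if (identical(v1row$alleles, 2L)) "causal" else
      "single_het_recessive"
  )
}

#' Generate a synthetic cohort
#'
#' Deterministic given `seed` and `config`. Census mode plants exact counts
#' (classification of the output recovers them exactly); binomial mode draws
#' heterozygous carrier status independently per variant at the configured
#' frequencies. Only catalog variant sites appear in the genotype data.
#'
#' @param config A `pd_sim_config`.
#' @param seed Integer seed for all randomness.
#' @param catalog A `pd_catalog` supplying variant definitions.
#' @return A `pd_sim` object: list with `samples` (manifest tibble),
#'   `genotypes`, `cnvs`, and `truth` (list of `sample_truth` and
#'   `stratum_counts` tibbles).
#' @seealso [write_cohort_files()] to emit `cohort.vcf`, `manifest.tsv`,
#'   `cnv.tsv` and `truth.json`.
#' @export
generate_cohort <- function(config, seed = 1L,
                            catalog = default_catalog()) {
  stopifnot(inherits(config, "pd_sim_config"))
  set.seed(as.integer(seed))
  if (config$mode == "census") {
    sim <- generate_census(config, catalog)
  } else {
    sim <- generate_binomial(config, catalog)
  }
  sim$samples <- draw_phenotype_fields(sim$samples, config$aao)
  manifest <- dplyr::select(
    sim$samples, "sample_id", "ancestry", "affected", "phenotype",
    "cohort_class", "sex", "age_years", "aao_years", "family_history"
  )
  structure(
    list(samples = validate_manifest(manifest),
         genotypes = sim$genotypes,
         cnvs = validate_cnv(sim$cnvs),
         truth = sim$truth),
    class = "pd_sim"
  )
}

generate_census <- function(config, catalog) {
  plant <- config$plant
  strata <- config$strata
  planted_totals <- plant |>
    dplyr::group_by(.data$ancestry, .data$affected, .data$enriched) |>
    dplyr::summarise(n_planted = sum(.data$n), .groups = "drop")
  strata <- dplyr::left_join(
    strata, planted_totals,
    by = c("ancestry", "affected", "enriched")
  ) |>
    dplyr::mutate(n_planted = tidyr::replace_na(.data$n_planted, 0L))
  over <- strata$n_planted > strata$n_total
  if (any(over)) {
    rlang::abort(paste0(
      "planted census counts exceed stratum size for ",
      paste(strata$ancestry[over], collapse = ", ")
    ))
  }
  counter <- 0L
  next_ids <- function(k, ancestry, affected) {
    ids <- sprintf("%s_%s_%06d", ancestry, ifelse(affected, "A", "U"),
                   counter + seq_len(k))
    counter <<- counter + k
    ids
  }
  sample_proto <- tibble::tibble(
    sample_id = character(), ancestry = character(), affected = logical(),
    enriched = logical(), aao_rule = character(),
    sex_force = character(), shift_gene = character()
  )
  truth_proto <- tibble::tibble(sample_id = character(),
                                category = character(),
                                genes = character())
  samples <- list(sample_proto); genos <- list()
  cnvs <- list(); truths <- list(truth_proto)
  for (i in seq_len(nrow(plant))) {
    p <- plant[i, ]
    if (p$n == 0) next
    ids <- next_ids(p$n, p$ancestry, p$affected)
    v1row <- if (!is.na(p$v1)) resolve_label(catalog, p$v1) else NULL
    v2row <- if (!is.na(p$v2)) resolve_label(catalog, p$v2) else NULL
    g <- list()
    cv <- NULL
    add_calls <- function(vrow, zyg) {
      tibble::tibble(sample_id = ids, chrom = vrow$chrom, pos = vrow$pos,
                     ref = vrow$ref, alt = vrow$alt,
                     variant_key = vrow$variant_key, zygosity = zyg)
    }
    if (p$class == "snv_het") {
      g <- list(add_calls(v1row, "het"))
    } else if (p$class == "snv_hom") {
      g <- list(add_calls(v1row, "hom_alt"))
    } else if (p$class == "two_het") {
      g <- list(add_calls(v1row, "het"), add_calls(v2row, "het"))
    } else if (p$class == "dual") {
      g <- list(add_calls(v1row, "het"), add_calls(v2row, "het"))
    } else if (p$class == "cnv") {
      cv <- tibble::tibble(sample_id = ids, gene = p$gene, event = p$event,
                           alleles_affected = p$alleles,
                           exons = if (p$gene == "PRKN") "3,4" else
                             NA_character_)
    } else if (p$class == "snv_cnv") {
      g <- list(add_calls(v1row, "het"))
      cv <- tibble::tibble(sample_id = ids, gene = v1row$gene,
                           event = p$event, alleles_affected = 1L,
                           exons = "2")
    } else {
      rlang::abort(paste0("unknown plant class '", p$class, "'"))
    }
    cat_genes <- unique(stats::na.omit(c(
      if (!is.null(v1row)) v1row$gene, if (!is.null(v2row)) v2row$gene,
      if (!is.na(p$gene)) p$gene
    )))
    category <- plant_category(
      p$class, catalog$genes,
      if (p$class == "cnv") list(alleles = p$alleles,
                                 gene = p$gene, tier = NA) else v1row,
      v2row, p$aao
    )
    shift_gene <- if (category %in% c("risk", "causal") &&
                        length(cat_genes) == 1) cat_genes else NA_character_
    samples[[length(samples) + 1L]] <- tibble::tibble(
      sample_id = ids, ancestry = p$ancestry, affected = p$affected,
      enriched = p$enriched, aao_rule = p$aao, sex_force = p$sex,
      shift_gene = shift_gene
    )
    truths[[length(truths) + 1L]] <- tibble::tibble(
      sample_id = ids, category = category,
      genes = paste(cat_genes, collapse = ",")
    )
    for (gg in g) genos[[length(genos) + 1L]] <- gg
    if (!is.null(cv)) cnvs[[length(cnvs) + 1L]] <- cv
  }
  # fill non-carriers
  for (j in seq_len(nrow(strata))) {
    s <- strata[j, ]
    k <- s$n_total - s$n_planted
    if (k <= 0) next
    ids <- next_ids(k, s$ancestry, s$affected)
    samples[[length(samples) + 1L]] <- tibble::tibble(
      sample_id = ids, ancestry = s$ancestry, affected = s$affected,
      enriched = s$enriched, aao_rule = "default",
      sex_force = NA_character_, shift_gene = NA_character_
    )
    truths[[length(truths) + 1L]] <- tibble::tibble(
      sample_id = ids, category = "none", genes = ""
    )
  }
  samples <- dplyr::bind_rows(samples)
  truth_samples <- dplyr::bind_rows(truths)
  stratum_counts <- plant |>
    dplyr::group_by(.data$ancestry, .data$affected, .data$enriched,
                    .data$class) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop")
  list(
    samples = samples,
    genotypes = if (length(genos)) dplyr::bind_rows(genos) else
      empty_genotypes()[, c("sample_id", "chrom", "pos", "ref", "alt",
                            "variant_key", "zygosity")],
    cnvs = if (length(cnvs)) dplyr::bind_rows(cnvs) else
      tibble::tibble(sample_id = character(), gene = character(),
                     event = character(), alleles_affected = integer(),
                     exons = character()),
    truth = list(sample_truth = truth_samples,
                 stratum_counts = stratum_counts)
  )
}

generate_binomial <- function(config, catalog) {
  strata <- config$strata
  freqs <- config$freqs
  samples <- list(); genos <- list()
  counter <- 0L
  for (j in seq_len(nrow(strata))) {
    s <- strata[j, ]
    for (arm in c(TRUE, FALSE)) {
      n <- if (arm) s$n_affected else s$n_unaffected
      if (n == 0) next
      ids <- sprintf("%s_%s_%06d", s$ancestry, ifelse(arm, "A", "U"),
                     counter + seq_len(n))
      counter <- counter + n
      carrier_genes <- vector("list", n)
      for (k in seq_len(nrow(freqs))) {
        vrow <- resolve_label(catalog, freqs$label[k])
        f <- if (arm) freqs$freq_affected[k] else freqs$freq_unaffected[k]
        hit <- stats::rbinom(n, 1, f) == 1
        if (any(hit)) {
          genos[[length(genos) + 1L]] <- tibble::tibble(
            sample_id = ids[hit], chrom = vrow$chrom, pos = vrow$pos,
            ref = vrow$ref, alt = vrow$alt,
            variant_key = vrow$variant_key, zygosity = "het"
          )
          for (w in which(hit)) {
            carrier_genes[[w]] <- c(carrier_genes[[w]], vrow$gene)
          }
        }
      }
      sole <- vapply(carrier_genes, function(gs) {
        gs <- unique(gs)
        if (length(gs) == 1) gs else NA_character_
      }, character(1))
      samples[[length(samples) + 1L]] <- tibble::tibble(
        sample_id = ids, ancestry = s$ancestry, affected = arm,
        enriched = FALSE, aao_rule = "default", sex_force = NA_character_,
        shift_gene = sole
      )
    }
  }
  samples <- dplyr::bind_rows(samples)
  geno <- if (length(genos)) dplyr::bind_rows(genos) else
    empty_genotypes()[, c("sample_id", "chrom", "pos", "ref", "alt",
                          "variant_key", "zygosity")]
  list(
    samples = samples, genotypes = geno,
    cnvs = tibble::tibble(sample_id = character(), gene = character(),
                          event = character(), alleles_affected = integer(),
                          exons = character()),
    truth = list(
      sample_truth = tibble::tibble(sample_id = samples$sample_id,
                                    category = NA_character_, genes = ""),
      planted_freqs = freqs
    )
  )
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd),
                    stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# Demographics, onset, cohort class assignment shared by both modes.
draw_phenotype_fields <- function(samples, aao) {
  n <- nrow(samples)
  sex <- ifelse(stats::runif(n) < ifelse(samples$affected, 0.60, 0.51),
                "male", "female")
  sex <- ifelse(is.na(samples$sex_force), sex, samples$sex_force)
  shift <- dplyr::case_when(
    samples$shift_gene == "GBA1" ~ aao$shift_gba1,
    samples$shift_gene == "LRRK2" ~ aao$shift_lrrk2,
    TRUE ~ 0
  )
  shift[is.na(shift)] <- 0
  aao_years <- rep(NA_real_, n)
  rule <- samples$aao_rule
  idx_def <- which(samples$affected & rule == "default")
  aao_years[idx_def] <- rtruncnorm(length(idx_def),
                                   aao$ipd_mean + shift[idx_def],
                                   aao$ipd_sd, aao$aao_min, aao$aao_max)
  idx_early <- which(samples$affected & rule == "early")
  aao_years[idx_early] <- rtruncnorm(length(idx_early), 38, 8,
                                     aao$aao_min, 50)
  idx_late <- which(samples$affected & rule == "late")
  aao_years[idx_late] <- rtruncnorm(length(idx_late), 62, 8, 50.5,
                                    aao$aao_max)
  aao_years <- round(aao_years)
  aao_years[aao_years > 50 & seq_len(n) %in% idx_early] <- 50
  # Missingness only where classification does not depend on onset.
  blank <- stats::runif(n) < aao$missing_frac & rule == "default"
  aao_years[blank] <- NA_real_
  delay <- pmax(0, round(stats::rnorm(n, 8, 4)))
  age <- ifelse(samples$affected & !is.na(aao_years),
                pmin(aao_years + delay, 110),
                round(rtruncnorm(n, 65, 12, 16, 104)))
  fh <- stats::runif(n) < ifelse(samples$affected, 0.20, 0.05)
  fh[stats::runif(n) < 0.25] <- NA
  cohort_class <- character(n)
  u <- stats::runif(n)
  aff <- samples$affected
  enr <- samples$enriched
  cohort_class[aff & enr] <- "genetic_enrichment_affected"
  cohort_class[!aff & enr] <- "genetic_enrichment_unaffected"
  planted_carrier <- samples$aao_rule != "default" |
    !is.na(samples$shift_gene)
  idx <- aff & !enr
  cohort_class[idx] <- ifelse(
    planted_carrier[idx] | u[idx] < 0.83, "pd_unselected",
    ifelse(u[idx] < 0.915, "monogenic_recruitment", "other_phenotypes")
  )
  idx <- !aff & !enr
  cohort_class[idx] <- ifelse(
    u[idx] < 0.65, "controls",
    ifelse(u[idx] < 0.98, "population_cohort", "unaffected_family")
  )
  phenotype <- ifelse(!aff, "control",
                      ifelse(cohort_class == "other_phenotypes",
                             ifelse(u < 0.87, "PSP", "DLB"), "PD"))
  samples$sex <- sex
  samples$aao_years <- ifelse(aff, aao_years, NA_real_)
  samples$age_years <- age
  samples$family_history <- fh
  samples$cohort_class <- cohort_class
  samples$phenotype <- phenotype
  samples
}

#' Write a simulated cohort to files
#'
#' Emits `manifest.tsv`, `cohort.vcf` (plain-text VCF v4.2 whose sites are
#' the catalog variants), `cnv.tsv` and `truth.json` into `dir`. Male
#' hemizygous X calls are written diploid-coded (`1/1`), as genotyping
#' arrays emit them; [build_cohort()] reinterprets them on read.
#'
#' @param sim A `pd_sim` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param catalog The catalog used to generate the cohort.
#' @return `dir`, invisibly.
#' @export
write_cohort_files <- function(sim, dir, catalog = default_catalog()) {
  stopifnot(inherits(sim, "pd_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(sim$samples, file.path(dir, "manifest.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$cnvs, file.path(dir, "cnv.tsv"), progress = FALSE)
  write_vcf(sim, file.path(dir, "cohort.vcf"), catalog)
  truth <- sim$truth
  jsonlite::write_json(
    list(sample_truth = truth$sample_truth,
         stratum_counts = truth$stratum_counts,
         planted_freqs = truth$planted_freqs),
    file.path(dir, "truth.json"),
    dataframe = "columns", na = "null"
  )
  invisible(dir)
}

write_vcf <- function(sim, path, catalog) {
  variants <- dplyr::arrange(catalog$variants, .data$chrom, .data$pos,
                             .data$alt)
  sample_ids <- sim$samples$sample_id
  gt <- matrix("0/0", nrow = nrow(variants), ncol = length(sample_ids))
  if (nrow(sim$genotypes) > 0) {
    ri <- match(sim$genotypes$variant_key, variants$variant_key)
    ci <- match(sim$genotypes$sample_id, sample_ids)
    code <- dplyr::case_when(
      sim$genotypes$zygosity == "het" ~ "0/1",
      sim$genotypes$zygosity %in% c("hom_alt", "hemizygous") ~ "1/1"
    )
    gt[cbind(ri, ci)] <- code
  }
  fix <- paste(sub("^chr", "", variants$chrom), variants$pos,
               ifelse(is.na(variants$rsid), ".", variants$rsid),
               variants$ref, variants$alt, ".", "PASS", ".", "GT",
               sep = "\t")
  body <- if (length(sample_ids) == 0) fix else
    paste(fix, apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pdcarrier-simulator",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' @export
print.pd_sim <- function(x, ...) {
  cat("<pd_sim> ", nrow(x$samples), " samples, ", nrow(x$genotypes),
      " genotype calls, ", nrow(x$cnvs), " CNV calls\n", sep = "")
  invisible(x)
}
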
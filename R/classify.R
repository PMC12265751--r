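causal_tiers <- c("pathogenic", "likely_pathogenic")
causal_level_evidence <- c("dominant_het", "recessive_hom",
                           "likely_compound_het", "cnv_biallelic",
                           "snv_cnv_compound_het")
finding_categories <- c("causal", "risk", "dual", "single_het_recessive",
                        "none")

#' Assess one gene in one individual
#'
#' Applies the per-gene decision rules to the calls of a single individual in
#' a single gene:
#'
#' 1. In `GBA1` every catalog variant counts as a PD risk variant (any
#'    zygosity); in `LRRK2` the risk variants R1628P and G2385R yield
#'    risk-level evidence — carrying both is still one finding. A
#'    causal-eligible (pathogenic / likely pathogenic) variant in the same
#'    gene takes precedence over its risk variants.
#' 2. Dominant gene: any causal-eligible het/hom variant, or an `SNCA`
#'    multiplication, is causal-level (`dominant_het`).
#' 3. X-linked gene: any causal-eligible het/hom/hemizygous variant is
#'    causal-level; female heterozygous carriers count by default
#'    (`count_xlinked_female_het`).
#' 4. Recessive gene: a homozygous causal-eligible variant
#'    (`recessive_hom`) or a biallelic CNV (`cnv_biallelic`) is causal-level
#'    with no age condition. Two distinct heterozygous causal-eligible
#'    variants with age at onset known and <= 50 years are a likely compound
#'    heterozygote (`likely_compound_het`); one het SNV plus a single-allele
#'    CNV under the same age gate is `snv_cnv_compound_het`. Any remaining
#'    heterozygous pathogenic allele is `single_het_recessive` — not causal.
#'
#' A missing age at onset fails the <= 50 gate (conservative: unphased
#' two-het carriers with unknown onset stay single-het). Age at onset exactly
#' 50 qualifies.
#'
#' @param gene One row of the gene panel (see [default_genes()]).
#' @param calls Genotype calls of one sample in that gene, joined to catalog
#'   columns `tier`, `protein_label`, `variant_key`, `zygosity`.
#' @param cnvs CNV calls of the same sample in that gene.
#' @param meta One-row sample metadata (needs `aao_years`, `sex`).
#' @param count_xlinked_female_het Count X-linked female het carriers as
#'   causal-level (default `TRUE`).
#' @return A one-row tibble (`gene`, `evidence`, `variants`, `zygosities`),
#'   or `NULL` when nothing in the gene qualifies at any level.
#' @export
assess_gene <- function(gene, calls, cnvs, meta,
                        count_xlinked_female_het = TRUE) {
  causal <- calls[calls$tier %in% causal_tiers, , drop = FALSE]
  risk <- calls[calls$tier == "risk", , drop = FALSE]
  n_het <- length(unique(causal$variant_key[causal$zygosity == "het"]))
  n_hom <- sum(causal$zygosity == "hom_alt")
  n_hemi <- sum(causal$zygosity == "hemizygous")
  cnv_biallelic <- nrow(cnvs) > 0 && any(cnvs$alleles_affected == 2)
  n_cnv_single <- if (nrow(cnvs) > 0) sum(cnvs$alleles_affected == 1) else 0
  aao_le50 <- !is.na(meta$aao_years) && meta$aao_years <= 50

  finding <- function(evidence, use_calls, use_cnvs = NULL) {
    labels <- use_calls$protein_label
    zygs <- use_calls$zygosity
    if (!is.null(use_cnvs) && nrow(use_cnvs) > 0) {
      labels <- c(labels, paste0("CNV:", use_cnvs$event))
      zygs <- c(zygs, ifelse(use_cnvs$alleles_affected == 2,
                             "biallelic", "single_allele"))
    }
    tibble::tibble(
      gene = gene$symbol,
      evidence = evidence,
      variants = paste(labels, collapse = ","),
      zygosities = paste(zygs, collapse = ",")
    )
  }

  if (gene$inheritance == "risk_locus") {
    if (nrow(risk) > 0) return(finding("risk_variant", risk))
    return(NULL)
  }
  if (gene$inheritance == "autosomal_dominant") {
    has_mult <- gene$symbol == "SNCA" && nrow(cnvs) > 0
    if (n_het + n_hom + n_hemi > 0 || has_mult) {
      return(finding("dominant_het", causal, if (has_mult) cnvs))
    }
    if (nrow(risk) > 0) return(finding("risk_variant", risk))
    return(NULL)
  }
  if (gene$inheritance == "x_linked") {
    qualifies <- n_hom + n_hemi > 0 ||
      (n_het > 0 && (count_xlinked_female_het || meta$sex != "female"))
    if (qualifies) return(finding("dominant_het", causal))
    return(NULL)
  }
  # autosomal recessive
  if (n_hom > 0) return(finding("recessive_hom", causal))
  if (cnv_biallelic) {
    return(finding("cnv_biallelic", causal[0, ],
                   cnvs[cnvs$alleles_affected == 2, , drop = FALSE]))
  }
  if (n_het >= 2 && aao_le50) {
    return(finding("likely_compound_het",
                   causal[causal$zygosity == "het", , drop = FALSE]))
  }
  if (n_het >= 1 && n_cnv_single >= 1 && aao_le50) {
    return(finding("snv_cnv_compound_het",
                   causal[causal$zygosity == "het", , drop = FALSE],
                   cnvs[cnvs$alleles_affected == 1, , drop = FALSE]))
  }
  if (n_het >= 1 || n_cnv_single >= 1) {
    return(finding("single_het_recessive", causal,
                   cnvs[cnvs$alleles_affected == 1, , drop = FALSE]))
  }
  NULL
}

#' Classify one individual from their gene-level findings
#'
#' Category precedence: `dual` (qualifying findings in two or more distinct
#' genes, each individually causal- or risk-level) > `causal` > `risk` >
#' `single_het_recessive` > `none`. Single-het recessive findings never
#' contribute to dual status; a homozygous risk variant stays a risk finding.
#'
#' @param cohort A `pd_cohort` (see [build_cohort()]).
#' @param sample_id Sample to classify.
#' @param catalog A `pd_catalog`.
#' @param count_xlinked_female_het See [assess_gene()].
#' @return A list with `sample_id`, `category`, and the tibble
#'   `gene_findings`.
#' @export
classify_sample <- function(cohort, sample_id, catalog = default_catalog(),
                            count_xlinked_female_het = TRUE) {
  stopifnot(inherits(cohort, "pd_cohort"))
  meta <- cohort$samples[cohort$samples$sample_id == sample_id, ]
  if (nrow(meta) == 0) rlang::abort(paste0("unknown sample '", sample_id, "'"))
  calls <- dplyr::inner_join(
    cohort$genotypes[cohort$genotypes$sample_id == sample_id, ],
    dplyr::select(catalog$variants, "variant_key", "gene", "tier",
                  "protein_label"),
    by = "variant_key"
  )
  cnvs <- cohort$cnvs[cohort$cnvs$sample_id == sample_id, ]
  genes_touched <- union(unique(calls$gene), unique(cnvs$gene))
  findings <- purrr::map_dfr(genes_touched, function(g) {
    gene <- catalog$genes[catalog$genes$symbol == g, ]
    f <- assess_gene(gene,
                     calls[calls$gene == g, , drop = FALSE],
                     cnvs[cnvs$gene == g, , drop = FALSE],
                     meta, count_xlinked_female_het)
    if (is.null(f)) NULL else f
  })
  list(
    sample_id = sample_id,
    category = category_from_findings(findings),
    gene_findings = findings
  )
}

category_from_findings <- function(findings) {
  if (is.null(findings) || nrow(findings) == 0) return("none")
  causal_genes <- findings$gene[findings$evidence %in% causal_level_evidence]
  risk_genes <- findings$gene[findings$evidence == "risk_variant"]
  qualifying <- unique(c(causal_genes, risk_genes))
  if (length(qualifying) >= 2) return("dual")
  if (length(causal_genes) > 0) return("causal")
  if (length(risk_genes) > 0) return("risk")
  if (any(findings$evidence == "single_het_recessive")) {
    return("single_het_recessive")
  }
  "none"
}

#' Classify every individual in a cohort
#'
#' Vectorized equivalent of applying [classify_sample()] to each sample:
#' deterministic, order-independent, and linear in the number of carriers.
#' Samples without any qualifying call are category `none`, so the output
#' always partitions the cohort across the five categories.
#'
#' @inheritParams classify_sample
#' @return A `pd_findings` object: list with
#'   \describe{
#'     \item{samples}{tibble `sample_id`, `category`.}
#'     \item{genes}{long tibble of gene-level findings (`sample_id`, `gene`,
#'       `evidence`, `variants`, `zygosities`, `causal_level`).}
#'     \item{variant_hits}{per-call tibble (`sample_id`, `gene`,
#'       `protein_label`, `rsid`, `tier`, `gba1_severity`, `zygosity`)
#'       restricted to calls inside qualifying findings, used for spectrum
#'       and per-variant frequency reports.}
#'   }
#' @export
batch_classify <- function(cohort, catalog = default_catalog(),
                           count_xlinked_female_het = TRUE) {
  stopifnot(inherits(cohort, "pd_cohort"))
  calls <- dplyr::inner_join(
    cohort$genotypes,
    dplyr::select(catalog$variants, "variant_key", "gene", "tier",
                  "protein_label", "rsid", "gba1_severity"),
    by = "variant_key"
  ) |>
    dplyr::left_join(
      dplyr::select(cohort$samples, "sample_id", "aao_years", "sex"),
      by = "sample_id"
    )
  geno_sum <- calls |>
    dplyr::group_by(.data$sample_id, .data$gene) |>
    dplyr::summarise(
      risk_n = sum(.data$tier == "risk"),
      c_het = dplyr::n_distinct(
        .data$variant_key[.data$tier %in% causal_tiers &
                            .data$zygosity == "het"]),
      c_hom = sum(.data$tier %in% causal_tiers &
                    .data$zygosity == "hom_alt"),
      c_hemi = sum(.data$tier %in% causal_tiers &
                     .data$zygosity == "hemizygous"),
      causal_labels = paste(
        .data$protein_label[.data$tier %in% causal_tiers], collapse = ","),
      causal_zygs = paste(
        .data$zygosity[.data$tier %in% causal_tiers], collapse = ","),
      risk_labels = paste(
        .data$protein_label[.data$tier == "risk"], collapse = ","),
      risk_zygs = paste(
        .data$zygosity[.data$tier == "risk"], collapse = ","),
      .groups = "drop"
    )
  cnv_sum <- cohort$cnvs |>
    dplyr::group_by(.data$sample_id, .data$gene) |>
    dplyr::summarise(
      cnv_biall = any(.data$alleles_affected == 2),
      cnv_single_n = sum(.data$alleles_affected == 1),
      cnv_labels = paste0("CNV:", .data$event, collapse = ","),
      cnv_zygs = paste(ifelse(.data$alleles_affected == 2, "biallelic",
                              "single_allele"), collapse = ","),
      .groups = "drop"
    )
  per_gene <- dplyr::full_join(geno_sum, cnv_sum,
                               by = c("sample_id", "gene")) |>
    dplyr::mutate(dplyr::across(
      c("risk_n", "c_het", "c_hom", "c_hemi", "cnv_single_n"),
      ~ tidyr::replace_na(.x, 0))) |>
    dplyr::mutate(
      cnv_biall = tidyr::replace_na(.data$cnv_biall, FALSE),
      dplyr::across(c("causal_labels", "causal_zygs", "risk_labels",
                      "risk_zygs", "cnv_labels", "cnv_zygs"),
                    ~ tidyr::replace_na(.x, ""))
    ) |>
    dplyr::left_join(
      dplyr::select(catalog$genes, gene = "symbol", "inheritance"),
      by = "gene"
    ) |>
    dplyr::left_join(
      dplyr::select(cohort$samples, "sample_id", "aao_years", "sex"),
      by = "sample_id"
    ) |>
    dplyr::mutate(
      aao_le50 = !is.na(.data$aao_years) & .data$aao_years <= 50,
      causal_any = .data$c_het + .data$c_hom + .data$c_hemi > 0,
      xl_ok = .data$c_hom + .data$c_hemi > 0 |
        (.data$c_het > 0 &
           (count_xlinked_female_het | .data$sex != "female")),
      evidence = dplyr::case_when(
        inheritance == "risk_locus" & risk_n > 0 ~ "risk_variant",
        inheritance == "autosomal_dominant" &
          (causal_any | (gene == "SNCA" & (cnv_biall | cnv_single_n > 0))) ~
          "dominant_het",
        inheritance == "autosomal_dominant" & risk_n > 0 ~ "risk_variant",
        inheritance == "x_linked" & xl_ok ~ "dominant_het",
        inheritance == "autosomal_recessive" & c_hom > 0 ~ "recessive_hom",
        inheritance == "autosomal_recessive" & cnv_biall ~ "cnv_biallelic",
        inheritance == "autosomal_recessive" & c_het >= 2 & aao_le50 ~
          "likely_compound_het",
        inheritance == "autosomal_recessive" & c_het >= 1 &
          cnv_single_n >= 1 & aao_le50 ~ "snv_cnv_compound_het",
        inheritance == "autosomal_recessive" &
          (c_het >= 1 | cnv_single_n >= 1) ~ "single_het_recessive",
        TRUE ~ NA_character_
      )
    ) |>
    dplyr::filter(!is.na(.data$evidence)) |>
    dplyr::mutate(
      variants = dplyr::case_when(
        evidence == "risk_variant" ~ risk_labels,
        evidence == "cnv_biallelic" ~ cnv_labels,
        TRUE ~ paste_nonempty(.data$causal_labels, .data$cnv_labels)
      ),
      zygosities = dplyr::case_when(
        evidence == "risk_variant" ~ risk_zygs,
        evidence == "cnv_biallelic" ~ cnv_zygs,
        TRUE ~ paste_nonempty(.data$causal_zygs, .data$cnv_zygs)
      ),
      causal_level = .data$evidence %in% causal_level_evidence
    ) |>
    dplyr::select("sample_id", "gene", "evidence", "variants",
                  "zygosities", "causal_level")
  categories <- per_gene |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_qual_genes = dplyr::n_distinct(
        .data$gene[.data$evidence != "single_het_recessive"]),
      any_causal = any(.data$causal_level),
      any_risk = any(.data$evidence == "risk_variant"),
      any_single = any(.data$evidence == "single_het_recessive"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      category = dplyr::case_when(
        n_qual_genes >= 2 ~ "dual",
        any_causal ~ "causal",
        any_risk ~ "risk",
        any_single ~ "single_het_recessive",
        TRUE ~ "none"
      )
    )
  samples_out <- cohort$samples |>
    dplyr::select("sample_id") |>
    dplyr::left_join(dplyr::select(categories, "sample_id", "category"),
                     by = "sample_id") |>
    dplyr::mutate(category = tidyr::replace_na(.data$category, "none"))
  # Per-call record for spectrum/frequency reports, restricted to calls whose
  # gene yielded a qualifying (non-single-het) finding.
  qualifying <- per_gene[per_gene$evidence != "single_het_recessive",
                         c("sample_id", "gene")]
  variant_hits <- calls |>
    dplyr::inner_join(qualifying, by = c("sample_id", "gene")) |>
    dplyr::select("sample_id", "gene", "protein_label", "rsid", "tier",
                  "gba1_severity", "zygosity", "variant_key")
  structure(
    list(samples = samples_out, genes = per_gene,
         variant_hits = variant_hits),
    class = "pd_findings"
  )
}

paste_nonempty <- function(a, b) {
  out <- ifelse(a == "", b, ifelse(b == "", a, paste(a, b, sep = ",")))
  as.character(out)
}

#' @export
print.pd_findings <- function(x, ...) {
  tab <- table(factor(x$samples$category, levels = finding_categories))
  cat("<pd_findings> ", nrow(x$samples), " samples\n", sep = "")
  for (k in finding_categories) {
    cat("  ", format(k, width = 22), tab[[k]], "\n", sep = "")
  }
  invisible(x)
}

#' Export findings as a one-row-per-sample table
#'
#' @param findings A `pd_findings` object.
#' @return Tibble with `sample_id`, `category`, and comma-collapsed `genes`,
#'   `evidence`, `variants` columns.
#' @export
findings_table <- function(findings) {
  stopifnot(inherits(findings, "pd_findings"))
  gsum <- findings$genes |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      genes = paste(.data$gene, collapse = ","),
      evidence = paste(.data$evidence, collapse = ","),
      variants = paste(.data$variants, collapse = ";"),
      .groups = "drop"
    )
  findings$samples |>
    dplyr::left_join(gsum, by = "sample_id") |>
    dplyr::mutate(dplyr::across(c("genes", "evidence", "variants"),
                                ~ tidyr::replace_na(.x, "")))
}
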
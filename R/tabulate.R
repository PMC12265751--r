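#' Half-up rounding
#'
#' Table percentages are rounded half-up (`round()` in R rounds half-even):
#' two decimals in tables, one decimal in prose-style summaries.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

qualifying_samples <- function(findings, scope) {
  f <- findings$samples
  if (scope == "causal_only") {
    causal_dual <- findings$genes |>
      dplyr::filter(.data$causal_level) |>
      dplyr::distinct(.data$sample_id)
    qual <- f$category == "causal" |
      (f$category == "dual" & f$sample_id %in% causal_dual$sample_id)
  } else if (scope == "causal_and_risk") {
    qual <- f$category %in% c("causal", "risk", "dual")
  } else {
    rlang::abort("scope must be 'causal_only' or 'causal_and_risk'")
  }
  f$sample_id[qual]
}

check_findings_cover <- function(findings, manifest) {
  missing <- setdiff(manifest$sample_id, findings$samples$sample_id)
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "findings do not cover manifest sample(s): ",
      paste(utils::head(missing, 5), collapse = ", ")
    ))
  }
}

#' Ancestry-stratified diagnostic yield
#'
#' For each ancestry (plus a Total row) counts individuals with qualifying
#' findings over the stratum denominator. Under `scope = "causal_only"`,
#' qualifying means category `causal` or a dual carrier with at least one
#' causal-level component (a pathogenic LRRK2 + GBA1 dual carrier is a causal
#' finding; a LRRK2-risk + GBA1 dual carrier is not). Under
#' `"causal_and_risk"`, categories `causal`, `risk`, and `dual` all qualify.
#' Single-het recessive carriers never qualify. With
#' `include_enriched = FALSE` the genetic-enrichment cohorts (individuals
#' recruited for known carrier status) are removed from both numerator and
#' denominator, giving unbiased frequency estimates.
#'
#' @param findings A `pd_findings` covering every manifest sample.
#' @param manifest Sample manifest tibble.
#' @param scope `"causal_only"` or `"causal_and_risk"`.
#' @param include_enriched Keep genetic-enrichment cohorts?
#' @param affected Tabulate the affected (`TRUE`, default) or unaffected arm.
#' @return Tibble of yield cells: `ancestry`, `affected`, `scope`,
#'   `include_enriched`, `numerator`, `denominator`, `pct` (half-up, 2 dp).
#' @export
yield_table <- function(findings, manifest, scope = "causal_and_risk",
                        include_enriched = FALSE, affected = TRUE) {
  stopifnot(inherits(findings, "pd_findings"))
  check_findings_cover(findings, manifest)
  strat <- manifest[manifest$affected == affected, ]
  if (!include_enriched) {
    strat <- strat[!strat$cohort_class %in% enrichment_classes, ]
  }
  qual_ids <- qualifying_samples(findings, scope)
  strat$qualifies <- strat$sample_id %in% qual_ids
  per_anc <- strat |>
    dplyr::group_by(ancestry = factor(.data$ancestry,
                                      levels = ancestry_codes)) |>
    dplyr::summarise(numerator = sum(.data$qualifies),
                     denominator = dplyr::n(), .groups = "drop") |>
    tidyr::complete(ancestry,
                    fill = list(numerator = 0L, denominator = 0L)) |>
    dplyr::mutate(ancestry = as.character(.data$ancestry))
  total <- tibble::tibble(ancestry = "Total",
                          numerator = sum(per_anc$numerator),
                          denominator = sum(per_anc$denominator))
  dplyr::bind_rows(per_anc, total) |>
    dplyr::mutate(
      affected = affected,
      scope = scope,
      include_enriched = include_enriched,
      pct = ifelse(.data$denominator == 0, 0,
                   round_half_up(100 * .data$numerator / .data$denominator,
                                 2)),
      .after = "ancestry"
    )
}

#' Gene-by-ancestry carrier counts
#'
#' Counts individuals per gene, ancestry and disease arm. Dual carriers
#' (qualifying variants in two different genes) are counted once, in a
#' `Dual` column only; per-gene columns hold individuals whose single
#' qualifying gene is that gene. `LRRK2` risk-variant carriers (R1628P /
#' G2385R) are tabulated in a separate `LRRK2_risk` column, apart from
#' pathogenic `LRRK2` carriers. Single-het recessive carriers appear in no
#' column.
#'
#' @inheritParams yield_table
#' @return Tibble: `ancestry`, `affected`, `column` (gene symbol,
#'   `LRRK2_risk`, or `Dual`), `n`.
#' @export
gene_table <- function(findings, manifest, include_enriched = FALSE) {
  stopifnot(inherits(findings, "pd_findings"))
  check_findings_cover(findings, manifest)
  strat <- manifest
  if (!include_enriched) {
    strat <- strat[!strat$cohort_class %in% enrichment_classes, ]
  }
  f <- findings$samples |>
    dplyr::inner_join(
      dplyr::select(strat, "sample_id", "ancestry", "affected"),
      by = "sample_id"
    ) |>
    dplyr::filter(.data$category %in% c("causal", "risk", "dual"))
  qual_genes <- findings$genes |>
    dplyr::filter(.data$evidence != "single_het_recessive") |>
    dplyr::mutate(
      column = ifelse(.data$gene == "LRRK2" &
                        .data$evidence == "risk_variant",
                      "LRRK2_risk", .data$gene)
    )
  singles <- f |>
    dplyr::filter(.data$category != "dual") |>
    dplyr::inner_join(dplyr::select(qual_genes, "sample_id", "column"),
                      by = "sample_id")
  duals <- f |>
    dplyr::filter(.data$category == "dual") |>
    dplyr::mutate(column = "Dual")
  counted <- dplyr::bind_rows(
    dplyr::select(singles, "ancestry", "affected", "column"),
    dplyr::select(duals, "ancestry", "affected", "column")
  )
  columns <- c("GBA1", "LRRK2", "LRRK2_risk", "SNCA", "VPS35", "RAB32",
               "PINK1", "PRKN", "PARK7", "ATP13A2", "DCTN1", "DNAJC6",
               "FBXO7", "JAM2", "RAB39B", "SLC20A2", "SYNJ1", "VPS13C",
               "WDR45", "Dual")
  counted |>
    dplyr::count(
      ancestry = factor(.data$ancestry, levels = ancestry_codes),
      affected = .data$affected,
      column = factor(.data$column, levels = columns)
    ) |>
    tidyr::complete(ancestry, affected, column, fill = list(n = 0L)) |>
    dplyr::mutate(ancestry = as.character(.data$ancestry),
                  column = as.character(.data$column)) |>
    dplyr::arrange(.data$ancestry, dplyr::desc(.data$affected))
}

#' GBA1 variant and severity spectrum within one ancestry
#'
#' Per-variant carrier counts among all GBA1 carriers of an ancestry
#' (including the GBA1 component of dual carriers), with the severity class
#' carried by the catalog (severe / mild / risk / unknown). Rare variants can
#' be collapsed into an `Other` entry within their severity group:
#' `collapse_scope = "severe_only"` collapses only severe variants below the
#' threshold, `"all"` collapses within every severity group.
#'
#' @param findings A `pd_findings`.
#' @param manifest Sample manifest tibble.
#' @param ancestry Ancestry code.
#' @param affected Arm to summarise (default affected).
#' @param collapse_threshold Minimum carrier count to keep a variant as its
#'   own entry; `NULL` (default) disables collapsing.
#' @param collapse_scope `"severe_only"` or `"all"`.
#' @param include_enriched Keep genetic-enrichment cohorts?
#' @return Tibble: `ancestry`, `label`, `severity`, `n`, `share` (shares sum
#'   to 1 within the ancestry). Empty when the ancestry has no GBA1 carriers.
#' @export
gba1_spectrum <- function(findings, manifest, ancestry, affected = TRUE,
                          collapse_threshold = NULL,
                          collapse_scope = c("severe_only", "all"),
                          include_enriched = FALSE) {
  stopifnot(inherits(findings, "pd_findings"))
  collapse_scope <- match.arg(collapse_scope)
  strat <- manifest[manifest$ancestry == ancestry &
                      manifest$affected == affected, ]
  if (!include_enriched) {
    strat <- strat[!strat$cohort_class %in% enrichment_classes, ]
  }
  hits <- findings$variant_hits |>
    dplyr::filter(.data$gene == "GBA1",
                  .data$sample_id %in% strat$sample_id)
  if (nrow(hits) == 0) {
    return(tibble::tibble(ancestry = character(), label = character(),
                          severity = character(), n = integer(),
                          share = double()))
  }
  counts <- hits |>
    dplyr::count(label = .data$protein_label,
                 severity = .data$gba1_severity)
  if (!is.null(collapse_threshold)) {
    in_scope <- if (collapse_scope == "severe_only") {
      counts$severity == "severe"
    } else {
      rep(TRUE, nrow(counts))
    }
    counts <- counts |>
      dplyr::mutate(
        label = ifelse(in_scope & .data$n < collapse_threshold,
                       "Other", .data$label)
      ) |>
      dplyr::group_by(.data$label, .data$severity) |>
      dplyr::summarise(n = sum(.data$n), .groups = "drop")
  }
  counts |>
    dplyr::mutate(ancestry = ancestry,
                  share = .data$n / sum(.data$n),
                  .before = "label") |>
    dplyr::arrange(.data$severity, dplyr::desc(.data$n), .data$label)
}

#' Summary of single heterozygous carriers in recessive genes
#'
#' Carriers of one heterozygous pathogenic variant in a recessive gene are
#' not causal, but an early onset (age at onset <= 50 years) in many of them
#' is compatible with a second, undetected variant. This reports, per gene
#' and overall, the carrier count and the proportion with known age at onset
#' of 50 years or less.
#'
#' @inheritParams yield_table
#' @return A list: `per_gene` tibble (`gene`, `n`), and scalars `n_total`,
#'   `n_known_aao`, `n_aao_le50`, `pct_aao_le50` (half-up, 1 dp, among
#'   carriers with known onset).
#' @export
single_het_summary <- function(findings, manifest, affected = TRUE,
                               include_enriched = FALSE) {
  stopifnot(inherits(findings, "pd_findings"))
  strat <- manifest[manifest$affected == affected, ]
  if (!include_enriched) {
    strat <- strat[!strat$cohort_class %in% enrichment_classes, ]
  }
  singles <- findings$samples |>
    dplyr::filter(.data$category == "single_het_recessive") |>
    dplyr::inner_join(
      dplyr::select(strat, "sample_id", "aao_years"),
      by = "sample_id"
    )
  per_gene <- findings$genes |>
    dplyr::filter(.data$sample_id %in% singles$sample_id,
                  .data$evidence == "single_het_recessive") |>
    dplyr::count(.data$gene, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n))
  n_known <- sum(!is.na(singles$aao_years))
  n_le50 <- sum(singles$aao_years <= 50, na.rm = TRUE)
  list(
    per_gene = per_gene,
    n_total = nrow(singles),
    n_known_aao = n_known,
    n_aao_le50 = n_le50,
    pct_aao_le50 = if (n_known == 0) NA_real_ else
      round_half_up(100 * n_le50 / n_known, 1)
  )
}

#' Carrier frequency of a single catalog variant in a stratum
#'
#' Counts individuals carrying a given allele (any zygosity) among a
#' stratum's denominator — e.g., the frequency of the intronic GBA1
#' rs3115534-G among affected individuals of African ancestry.
#'
#' @param cohort A `pd_cohort`.
#' @param catalog A `pd_catalog`.
#' @param label Protein label or rsid of the variant.
#' @param ancestry Ancestry code, or `NULL` for all ancestries.
#' @param affected Arm (default affected).
#' @param include_enriched Keep genetic-enrichment cohorts?
#' @return A list: `n_carriers`, `denominator`, `pct` (half-up, 1 dp).
#' @export
variant_carrier_freq <- function(cohort, catalog, label, ancestry = NULL,
                                 affected = TRUE, include_enriched = FALSE) {
  stopifnot(inherits(cohort, "pd_cohort"))
  vrows <- catalog_variant(catalog, label)
  if (nrow(vrows) == 0) {
    rlang::abort(paste0("variant '", label, "' not in catalog"))
  }
  strat <- cohort$samples[cohort$samples$affected == affected, ]
  if (!is.null(ancestry)) strat <- strat[strat$ancestry == ancestry, ]
  if (!include_enriched) {
    strat <- strat[!strat$cohort_class %in% enrichment_classes, ]
  }
  carriers <- cohort$genotypes |>
    dplyr::filter(.data$variant_key %in% vrows$variant_key,
                  .data$sample_id %in% strat$sample_id) |>
    dplyr::distinct(.data$sample_id)
  denom <- nrow(strat)
  list(
    n_carriers = nrow(carriers),
    denominator = denom,
    pct = if (denom == 0) NA_real_ else
      round_half_up(100 * nrow(carriers) / denom, 1)
  )
}
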
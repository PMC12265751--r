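#' Assign affected PD individuals to age-at-onset comparison groups
#'
#' Three groups per ancestry, mirroring the idiopathic-vs-carrier onset
#' comparison: `IPD` (PD, no qualifying or single-het finding), `GBA1_PD`
#' (sole qualifying finding in GBA1), and `LRRK2_PD` (sole qualifying finding
#' in LRRK2, pathogenic or risk). Dual carriers, carriers in any other gene,
#' single-het recessive carriers, non-PD phenotypes, and individuals with
#' missing age at onset are excluded.
#'
#' @param findings A `pd_findings`.
#' @param manifest Sample manifest tibble.
#' @param pd_phenotype Phenotype label identifying PD (default `"PD"`).
#' @param include_enriched Keep genetic-enrichment cohorts (default FALSE)?
#' @return Tibble: `sample_id`, `ancestry`, `group`, `aao_years`, `sex`.
#' @export
assign_aao_groups <- function(findings, manifest, pd_phenotype = "PD",
                              include_enriched = FALSE) {
  stopifnot(inherits(findings, "pd_findings"))
  strat <- manifest[manifest$affected &
                      manifest$phenotype == pd_phenotype &
                      !is.na(manifest$aao_years), ]
  if (!include_enriched) {
    strat <- strat[!strat$cohort_class %in% enrichment_classes, ]
  }
  qual_gene <- findings$genes |>
    dplyr::filter(.data$evidence != "single_het_recessive") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      sole_gene = if (dplyr::n_distinct(.data$gene) == 1)
        .data$gene[1] else NA_character_,
      .groups = "drop"
    )
  strat |>
    dplyr::inner_join(dplyr::select(findings$samples, "sample_id",
                                    "category"), by = "sample_id") |>
    dplyr::left_join(qual_gene, by = "sample_id") |>
    dplyr::mutate(
      group = dplyr::case_when(
        category == "none" ~ "IPD",
        category %in% c("causal", "risk") & sole_gene == "GBA1" ~ "GBA1_PD",
        category %in% c("causal", "risk") & sole_gene == "LRRK2" ~
          "LRRK2_PD",
        TRUE ~ NA_character_
      )
    ) |>
    dplyr::filter(!is.na(.data$group)) |>
    dplyr::select("sample_id", "ancestry", "group", "aao_years", "sex")
}

#' Compare age at onset between carrier groups and idiopathic PD
#'
#' Ordinary least squares of age at onset on group indicators with `IPD` as
#' the reference level, fitted separately within each ancestry; coefficients
#' are the years-of-onset difference of each carrier group versus idiopathic
#' PD, with two-sided p-values. Group medians are always reported;
#' coefficients require at least two groups and at least two observations in
#' the non-reference group. Optional covariates (e.g., `"sex"`) can be added
#' to the model.
#'
#' @param labeled Output of [assign_aao_groups()] (or any tibble with
#'   `ancestry`, `group`, `aao_years`, plus covariate columns).
#' @param ancestry Restrict to one ancestry; `NULL` fits each ancestry
#'   present.
#' @param covariates Character vector of additional model terms.
#' @return Tibble: `ancestry`, `group`, `n`, `median_aao`, `coefficient`
#'   (NA for the reference group), `se`, `p_value`.
#' @export
compare_aao <- function(labeled, ancestry = NULL, covariates = character()) {
  if (!is.null(ancestry)) {
    labeled <- labeled[labeled$ancestry %in% ancestry, ]
  }
  purrr::map_dfr(split(labeled, labeled$ancestry), function(d) {
    groups <- c("IPD", "GBA1_PD", "LRRK2_PD")
    present <- groups[groups %in% unique(d$group)]
    med <- d |>
      dplyr::group_by(group = factor(.data$group, levels = present)) |>
      dplyr::summarise(n = dplyr::n(),
                       median_aao = stats::median(.data$aao_years),
                       .groups = "drop") |>
      dplyr::mutate(group = as.character(.data$group))
    out <- tibble::tibble(
      ancestry = d$ancestry[1],
      group = med$group, n = med$n, median_aao = med$median_aao,
      coefficient = NA_real_, se = NA_real_, p_value = NA_real_
    )
    enough <- length(present) >= 2 && "IPD" %in% present &&
      any(med$n[med$group != "IPD"] >= 2)
    if (enough) {
      d$group <- factor(d$group, levels = present)
      rhs <- paste(c("group", covariates), collapse = " + ")
      fit <- stats::lm(stats::as.formula(paste("aao_years ~", rhs)),
                       data = d)
      coefs <- summary(fit)$coefficients
      for (g in setdiff(present, "IPD")) {
        term <- paste0("group", g)
        if (term %in% rownames(coefs) && med$n[med$group == g] >= 2) {
          i <- which(out$group == g)
          out$coefficient[i] <- coefs[term, "Estimate"]
          out$se[i] <- coefs[term, "Std. Error"]
          out$p_value[i] <- coefs[term, "Pr(>|t|)"]
        }
      }
    }
    out
  })
}
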
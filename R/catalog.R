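#' Gene definitions for the 18 investigated PD and parkinsonism genes
#'
#' Returns the fixed gene panel driving all classification: three genes linked
#' to autosomal-dominant PD (`LRRK2`, `SNCA`, `VPS35`), three to early-onset
#' autosomal-recessive PD (`PARK7`, `PINK1`, `PRKN`), ten linked to atypical
#' parkinsonism (with `RAB39B` and `WDR45` on the X chromosome), the
#' dominantly acting `RAB32` (S71R only), and `GBA1`, whose variants are all
#' treated as PD risk variants regardless of their Gaucher-disease status.
#'
#' @return A tibble with columns `symbol`, `inheritance`
#'   (`autosomal_dominant`, `autosomal_recessive`, `x_linked`, `risk_locus`)
#'   and `phenotype_class`.
#' @export
#' @examples
#' default_genes()
default_genes <- function() {
  tibble::tribble(
    ~symbol,    ~inheritance,          ~phenotype_class,
    "LRRK2",    "autosomal_dominant",  "typical_pd_dominant",
    "SNCA",     "autosomal_dominant",  "typical_pd_dominant",
    "VPS35",    "autosomal_dominant",  "typical_pd_dominant",
    "RAB32",    "autosomal_dominant",  "typical_pd_dominant",
    "PARK7",    "autosomal_recessive", "early_onset_pd_recessive",
    "PINK1",    "autosomal_recessive", "early_onset_pd_recessive",
    "PRKN",     "autosomal_recessive", "early_onset_pd_recessive",
    "ATP13A2",  "autosomal_recessive", "atypical_parkinsonism",
    "DCTN1",    "autosomal_dominant",  "atypical_parkinsonism",
    "DNAJC6",   "autosomal_recessive", "atypical_parkinsonism",
    "FBXO7",    "autosomal_recessive", "atypical_parkinsonism",
    "JAM2",     "autosomal_recessive", "atypical_parkinsonism",
    "RAB39B",   "x_linked",            "atypical_parkinsonism",
    "SLC20A2",  "autosomal_dominant",  "atypical_parkinsonism",
    "SYNJ1",    "autosomal_recessive", "atypical_parkinsonism",
    "VPS13C",   "autosomal_recessive", "atypical_parkinsonism",
    "WDR45",    "x_linked",            "atypical_parkinsonism",
    "GBA1",     "risk_locus",          "pd_risk"
  )
}

# LRRK2 variants with an established PD-risk (rather than causal) association.
lrrk2_risk_labels <- c("R1628P", "G2385R")

catalog_tiers <- c("pathogenic", "likely_pathogenic", "risk")
gba1_severities <- c("severe", "mild", "risk", "unknown", "not_applicable")

#' Load a tiered variant catalog from a tab-separated file
#'
#' The catalog is the knowledge base of causal (pathogenic / likely
#' pathogenic, per ClinVar-style curation) and risk variants. Required
#' columns: `gene`, `chrom`, `pos`, `ref`, `alt`, `protein_label`, `rsid`,
#' `tier`, `gba1_severity`. Lines starting with `#` are comments.
#'
#' Validation enforces: unique `(chrom, pos, ref, alt)` keys; `tier = "risk"`
#' only for `GBA1` (all of whose variants must be risk-tier) or the two Asian
#' `LRRK2` risk variants R1628P and G2385R; `gba1_severity` set exactly for
#' `GBA1` rows (`not_applicable` elsewhere); every gene resolving to the
#' panel in `genes`.
#'
#' @param path Path to a UTF-8 TSV file.
#' @param genes Gene panel tibble, normally [default_genes()].
#' @return A `pd_catalog` object: list with tibbles `genes` and `variants`.
#' @seealso [default_catalog()], [write_catalog()], [lookup_variant()]
#' @export
load_catalog <- function(path, genes = default_genes()) {
  variants <- readr::read_tsv(
    path,
    comment = "#",
    col_types = readr::cols(
      gene = readr::col_character(),
      chrom = readr::col_character(),
      pos = readr::col_double(),
      ref = readr::col_character(),
      alt = readr::col_character(),
      protein_label = readr::col_character(),
      rsid = readr::col_character(),
      tier = readr::col_character(),
      gba1_severity = readr::col_character()
    ),
    progress = FALSE
  )
  new_catalog(genes, variants)
}

#' Construct and validate a catalog from in-memory tables
#'
#' @param genes Gene panel tibble (see [default_genes()]).
#' @param variants Tibble of catalog variants.
#' @return A validated `pd_catalog` object.
#' @export
new_catalog <- function(genes, variants) {
  required <- c("gene", "chrom", "pos", "ref", "alt", "protein_label",
                "rsid", "tier", "gba1_severity")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("catalog is missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(genes$symbol) > 0) {
    rlang::abort("gene symbols must be unique within a catalog")
  }
  variants <- dplyr::mutate(
    variants,
    chrom = normalize_chrom(.data$chrom),
    pos = as.integer(.data$pos)
  )
  variants$variant_key <- variant_key(variants$chrom, variants$pos,
                                      variants$ref, variants$alt)
  dup <- variants$variant_key[duplicated(variants$variant_key)]
  if (length(dup) > 0) {
    rlang::abort(paste0("duplicate variant key(s) in catalog: ",
                        paste(unique(dup), collapse = ", ")))
  }
  bad_gene <- setdiff(unique(variants$gene), genes$symbol)
  if (length(bad_gene) > 0) {
    rlang::abort(paste0("unknown gene symbol(s) in catalog: ",
                        paste(bad_gene, collapse = ", ")))
  }
  bad_tier <- setdiff(unique(variants$tier), catalog_tiers)
  if (length(bad_tier) > 0) {
    rlang::abort(paste0("invalid tier value(s): ",
                        paste(bad_tier, collapse = ", ")))
  }
  bad_sev <- setdiff(unique(variants$gba1_severity), gba1_severities)
  if (length(bad_sev) > 0) {
    rlang::abort(paste0("invalid gba1_severity value(s): ",
                        paste(bad_sev, collapse = ", ")))
  }
  # All GBA1 variants (including Gaucher-causal ones) count as PD risk
  # variants; risk tier is not permitted anywhere else except LRRK2
  # R1628P/G2385R.
  risk_ok <- variants$gene == "GBA1" |
    (variants$gene == "LRRK2" & variants$protein_label %in% lrrk2_risk_labels)
  offending <- variants$tier == "risk" & !risk_ok
  if (any(offending)) {
    rlang::abort(paste0(
      "risk tier not permitted for: ",
      paste(variants$variant_key[offending], collapse = ", ")
    ))
  }
  gba1_wrong_tier <- variants$gene == "GBA1" & variants$tier != "risk"
  if (any(gba1_wrong_tier)) {
    rlang::abort("all GBA1 catalog variants must carry tier = 'risk'")
  }
  sev_mismatch <- (variants$gene == "GBA1") ==
    (variants$gba1_severity == "not_applicable")
  if (any(sev_mismatch)) {
    rlang::abort(
      "gba1_severity must be not_applicable exactly for non-GBA1 variants"
    )
  }
  structure(
    list(genes = tibble::as_tibble(genes),
         variants = tibble::as_tibble(variants)),
    class = "pd_catalog"
  )
}

#' Write a catalog back to a tab-separated file
#'
#' Inverse of [load_catalog()] up to column order; comment lines are not
#' preserved.
#'
#' @param catalog A `pd_catalog` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "pd_catalog"))
  out <- dplyr::select(catalog$variants, "gene", "chrom", "pos", "ref",
                       "alt", "protein_label", "rsid", "tier",
                       "gba1_severity")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' The default variant catalog shipped with the package
#'
#' Curated from variants named in the multi-ancestry PD literature:
#' GBA1 N409S / E365K / T408M / L483P / L483R / D448H / R463C / R496H and the
#' intronic rs3115534-G (severity "unknown" — not yet covered by the GBA1-PD
#' browser); LRRK2 G2019S, R1441C/G/H, R1067Q, R1325Q, L1795F plus the Asian
#' risk variants R1628P and G2385R; PINK1 L347P and Q456X; VPS35 D620N; RAB32
#' S71R; SNCA A53T; PARK7 E64D; PRKN R275W, T240M, P437L; and one
#' representative pathogenic variant per remaining panel gene. Coordinates are
#' GRCh38, 1-based, VCF allele convention; they act as join keys between the
#' catalog and input VCFs, and for several rare variants are illustrative
#' placeholders within the gene. The catalog is deliberately extensible: add
#' rows to the TSV and reload.
#'
#' @return A validated `pd_catalog`.
#' @export
#' @examples
#' cat <- default_catalog()
#' nrow(cat$genes)     # 18 genes
#' lookup_variant(cat, "chr12", 40340400, "G", "A")$protein_label  # "G2019S"
default_catalog <- function() {
  path <- system.file("extdata", "pd_variant_catalog.tsv",
                      package = "pdcarrier", mustWork = TRUE)
  load_catalog(path)
}

#' Look up a catalog variant by exact key
#'
#' @param catalog A `pd_catalog`.
#' @param chrom Chromosome (with or without `chr` prefix).
#' @param pos 1-based position.
#' @param ref,alt Allele strings.
#' @return A one-row tibble, or `NULL` when the key is absent (such variants
#'   are ignored downstream).
#' @export
lookup_variant <- function(catalog, chrom, pos, ref, alt) {
  stopifnot(inherits(catalog, "pd_catalog"))
  key <- variant_key(normalize_chrom(chrom), as.integer(pos), ref, alt)
  hit <- catalog$variants[catalog$variants$variant_key == key, ]
  if (nrow(hit) == 0) NULL else hit
}

#' Look up catalog variants by protein label or rsid
#'
#' Convenience accessor used by the simulator and reporting code.
#'
#' @param catalog A `pd_catalog`.
#' @param label A `protein_label` or `rsid` value.
#' @param gene Optional gene symbol to disambiguate.
#' @return Matching rows of `catalog$variants` (possibly empty).
#' @export
catalog_variant <- function(catalog, label, gene = NULL) {
  v <- catalog$variants
  hit <- v[v$protein_label == label | (!is.na(v$rsid) & v$rsid == label), ]
  if (!is.null(gene)) hit <- hit[hit$gene == gene, ]
  hit
}

#' @export
print.pd_catalog <- function(x, ...) {
  cat("<pd_catalog> ", nrow(x$genes), " genes, ", nrow(x$variants),
      " variants\n", sep = "")
  tiers <- table(x$variants$tier)
  cat("  tiers: ", paste(names(tiers), tiers, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# --- internal helpers ------------------------------------------------------

# "1"/"chr1" dialects are normalized to chr-prefixed form.
normalize_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}
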
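ancestry_codes <- c("AAC", "AFR", "AJ", "AMR", "CAH", "CAS", "EAS", "EUR",
                    "FIN", "MDE", "SAS")

affected_classes <- c("pd_unselected", "monogenic_recruitment",
                      "other_phenotypes", "genetic_enrichment_affected")
unaffected_classes <- c("controls", "unaffected_family", "population_cohort",
                        "genetic_enrichment_unaffected")
cohort_classes <- c(affected_classes, unaffected_classes)
enrichment_classes <- c("genetic_enrichment_affected",
                        "genetic_enrichment_unaffected")

#' Read a sample manifest
#'
#' Tab-separated with header; columns `sample_id`, `ancestry` (one of the 11
#' codes AAC, AFR, AJ, AMR, CAH, CAS, EAS, EUR, FIN, MDE, SAS), `affected`
#' (logical), `phenotype`, `cohort_class`, `sex` (`male`/`female`/`unknown`),
#' `age_years`, `aao_years`, `family_history`. Age, age at onset and family
#' history may be empty. Enforced invariants: affected-only cohort classes
#' imply `affected = TRUE` (and conversely), and `aao_years <= age_years`
#' whenever both are present.
#'
#' @param path Path to the manifest TSV.
#' @return A tibble of sample metadata.
#' @export
read_sample_manifest <- function(path) {
  m <- readr::read_tsv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      ancestry = readr::col_character(),
      affected = readr::col_logical(),
      phenotype = readr::col_character(),
      cohort_class = readr::col_character(),
      sex = readr::col_character(),
      age_years = readr::col_double(),
      aao_years = readr::col_double(),
      family_history = readr::col_logical()
    ),
    progress = FALSE
  )
  validate_manifest(m)
}

validate_manifest <- function(m) {
  m <- tibble::as_tibble(m)
  if (anyDuplicated(m$sample_id) > 0) {
    rlang::abort("duplicate sample_id in manifest")
  }
  check_enum <- function(values, allowed, what) {
    bad <- which(!values %in% allowed)
    if (length(bad) > 0) {
      rlang::abort(paste0(
        "unknown ", what, " '", values[bad[1]], "' in manifest row ", bad[1]
      ))
    }
  }
  check_enum(m$ancestry, ancestry_codes, "ancestry code")
  check_enum(m$cohort_class, cohort_classes, "cohort_class")
  check_enum(m$sex, c("male", "female", "unknown"), "sex")
  implied_affected <- m$cohort_class %in% affected_classes
  clash <- which(implied_affected != m$affected)
  if (length(clash) > 0) {
    rlang::abort(paste0(
      "affected status contradicts cohort_class in manifest row ", clash[1],
      " (sample ", m$sample_id[clash[1]], ")"
    ))
  }
  bad_aao <- which(!is.na(m$aao_years) & !is.na(m$age_years) &
                     m$aao_years > m$age_years)
  if (length(bad_aao) > 0) {
    rlang::abort(paste0(
      "aao_years exceeds age_years in manifest row ", bad_aao[1],
      " (sample ", m$sample_id[bad_aao[1]], ")"
    ))
  }
  m
}

#' Read genotype calls from a VCF, restricted to catalog variants
#'
#' Parses the GT field of a VCF v4.x file (plain or bgzipped) with
#' \pkg{vcfR}, decomposes multi-allelic records per alternate allele, and
#' keeps only calls at catalog variants. Genotype mapping: one alternate
#' allele on a diploid call is `het`, two are `hom_alt`, a haploid `1` is
#' `hemizygous`; `0/0` and missing genotypes are dropped. Phase separators
#' (`/` vs `|`) are ignored — the pipeline never uses phase.
#'
#' @param path Path to the VCF.
#' @param catalog A `pd_catalog`; non-catalog sites are silently ignored.
#' @return Tibble with `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `variant_key`, `zygosity`.
#' @export
read_vcf <- function(path, catalog) {
  stopifnot(inherits(catalog, "pd_catalog"))
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) {
      rlang::abort(paste0("unreadable VCF '", path, "': ",
                          conditionMessage(e)))
    }
  )
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(empty_genotypes())
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) rlang::abort("VCF has no GT field")
  calls <- tibble::tibble(
    row = rep(seq_len(nrow(gt)), times = ncol(gt)),
    sample_id = rep(colnames(gt), each = nrow(gt)),
    gt = as.vector(gt)
  )
  calls <- dplyr::filter(
    calls,
    !is.na(.data$gt),
    !.data$gt %in% c("0/0", "0|0", ".", "./.", ".|.", "0")
  )
  if (nrow(calls) == 0) {
    return(empty_genotypes())
  }
  calls$chrom <- normalize_chrom(fix$CHROM[calls$row])
  calls$pos <- as.integer(fix$POS[calls$row])
  calls$ref <- fix$REF[calls$row]
  calls$alt_field <- fix$ALT[calls$row]
  # Decompose per alternate allele: an allele index a in the GT maps to the
  # a-th comma-separated ALT.
  alleles <- strsplit(calls$gt, "[/|]")
  alts <- strsplit(calls$alt_field, ",", fixed = TRUE)
  out <- purrr::pmap_dfr(
    list(alleles, alts, seq_len(nrow(calls))),
    function(al, alt_vec, i) {
      al <- al[al != "."]
      idx <- suppressWarnings(as.integer(al))
      idx <- idx[!is.na(idx) & idx > 0]
      if (length(idx) == 0) return(NULL)
      ploidy <- length(al)
      tab <- table(idx)
      tibble::tibble(
        sample_id = calls$sample_id[i],
        chrom = calls$chrom[i],
        pos = calls$pos[i],
        ref = calls$ref[i],
        alt = alt_vec[as.integer(names(tab))],
        zygosity = dplyr::case_when(
          ploidy == 1 ~ "hemizygous",
          as.integer(tab) >= 2 ~ "hom_alt",
          TRUE ~ "het"
        )
      )
    }
  )
  if (is.null(out) || nrow(out) == 0) {
    return(empty_genotypes())
  }
  out$variant_key <- variant_key(out$chrom, out$pos, out$ref, out$alt)
  out <- dplyr::filter(out,
                       .data$variant_key %in% catalog$variants$variant_key)
  dplyr::distinct(out, .data$sample_id, .data$variant_key, .keep_all = TRUE)
}

empty_genotypes <- function() {
  tibble::tibble(
    sample_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), zygosity = character(),
    variant_key = character()
  )
}

#' Read a copy-number-variant call table for SNCA and PRKN
#'
#' Tab-separated with header; columns `sample_id`, `gene` (`SNCA` or
#' `PRKN`), `event` (`multiplication`, `exon_deletion`, `exon_duplication`),
#' `alleles_affected` (1 or 2) and optional `exons` (comma-separated
#' integers). `SNCA` events must be multiplications. CNV calling itself is
#' upstream of this package; this reads a pre-called table.
#'
#' @param path Path to the CNV TSV.
#' @return A tibble of CNV calls.
#' @export
read_cnv_table <- function(path) {
  cnv <- readr::read_tsv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      gene = readr::col_character(),
      event = readr::col_character(),
      alleles_affected = readr::col_integer(),
      exons = readr::col_character()
    ),
    progress = FALSE
  )
  validate_cnv(cnv)
}

validate_cnv <- function(cnv) {
  cnv <- tibble::as_tibble(cnv)
  if (!"exons" %in% names(cnv)) cnv$exons <- NA_character_
  bad <- which(!cnv$gene %in% c("SNCA", "PRKN"))
  if (length(bad) > 0) {
    rlang::abort(paste0("CNV gene must be SNCA or PRKN (row ", bad[1], ")"))
  }
  bad <- which(!cnv$event %in% c("multiplication", "exon_deletion",
                                 "exon_duplication"))
  if (length(bad) > 0) {
    rlang::abort(paste0("invalid CNV event (row ", bad[1], ")"))
  }
  bad <- which(cnv$gene == "SNCA" & cnv$event != "multiplication")
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "SNCA CNV events must be multiplications (row ", bad[1], ")"
    ))
  }
  bad <- which(!cnv$alleles_affected %in% c(1L, 2L))
  if (length(bad) > 0) {
    rlang::abort(paste0("alleles_affected must be 1 or 2 (row ", bad[1], ")"))
  }
  cnv
}

#' Assemble a cohort from manifest, genotypes and CNV calls
#'
#' Checks merge closure (every genotype and CNV sample must exist in the
#' manifest) and reinterprets diploid-coded `hom_alt` calls on X-linked genes
#' in males as `hemizygous` — genotyping arrays often emit diploid calls on
#' the X chromosome.
#'
#' @param samples Manifest tibble ([read_sample_manifest()]).
#' @param genotypes Genotype calls ([read_vcf()]).
#' @param cnvs CNV calls ([read_cnv_table()]); may be empty.
#' @param catalog A `pd_catalog` (used for gene lookup on X).
#' @return A `pd_cohort` object: list of tibbles `samples`, `genotypes`,
#'   `cnvs`.
#' @export
build_cohort <- function(samples, genotypes, cnvs = NULL, catalog = default_catalog()) {
  samples <- validate_manifest(samples)
  if (is.null(cnvs)) {
    cnvs <- tibble::tibble(sample_id = character(), gene = character(),
                           event = character(), alleles_affected = integer(),
                           exons = NA_character_[0])
  }
  cnvs <- validate_cnv(cnvs)
  orphan <- setdiff(unique(c(genotypes$sample_id, cnvs$sample_id)),
                    samples$sample_id)
  if (length(orphan) > 0) {
    rlang::abort(paste0(
      "genotype/CNV calls reference sample(s) absent from manifest: ",
      paste(utils::head(orphan, 5), collapse = ", ")
    ))
  }
  vmeta <- dplyr::select(catalog$variants, "variant_key", "gene")
  gmeta <- dplyr::select(catalog$genes, gene = "symbol", "inheritance")
  genotypes <- genotypes |>
    dplyr::left_join(vmeta, by = "variant_key") |>
    dplyr::left_join(gmeta, by = "gene") |>
    dplyr::left_join(dplyr::select(samples, "sample_id", "sex"),
                     by = "sample_id") |>
    dplyr::mutate(
      zygosity = ifelse(
        .data$inheritance == "x_linked" & .data$sex == "male" &
          .data$zygosity == "hom_alt",
        "hemizygous", .data$zygosity
      )
    ) |>
    dplyr::select(-"gene", -"inheritance", -"sex")
  structure(
    list(samples = samples,
         genotypes = tibble::as_tibble(genotypes),
         cnvs = cnvs),
    class = "pd_cohort"
  )
}

#' Read a cohort from a directory of generated or curated files
#'
#' Expects `manifest.tsv`, `cohort.vcf` (or `.vcf.gz`) and optionally
#' `cnv.tsv`, as written by [write_cohort_files()].
#'
#' @param dir Directory path.
#' @param catalog A `pd_catalog`.
#' @return A `pd_cohort`.
#' @export
read_cohort_dir <- function(dir, catalog = default_catalog()) {
  manifest <- read_sample_manifest(file.path(dir, "manifest.tsv"))
  vcf_path <- file.path(dir, "cohort.vcf")
  if (!file.exists(vcf_path)) vcf_path <- paste0(vcf_path, ".gz")
  genotypes <- read_vcf(vcf_path, catalog)
  cnv_path <- file.path(dir, "cnv.tsv")
  cnvs <- if (file.exists(cnv_path)) read_cnv_table(cnv_path) else NULL
  build_cohort(manifest, genotypes, cnvs, catalog)
}

#' @export
print.pd_cohort <- function(x, ...) {
  cat("<pd_cohort> ", nrow(x$samples), " samples (",
      sum(x$samples$affected), " affected), ",
      nrow(x$genotypes), " genotype calls, ",
      nrow(x$cnvs), " CNV calls\n", sep = "")
  invisible(x)
}
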
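Package: pdcarrier
Title: Carrier Classification and Ancestry-Stratified Diagnostic Yield for
    Parkinson's Disease Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies individuals by their carrier status for causal and
    risk variants in 18 genes linked to Parkinson's disease and parkinsonism,
    starting from a curated variant catalog, VCF genotypes, a structural-variant
    call table for SNCA and PRKN, and a sample manifest. Implements the
    unphased likely-compound-heterozygote rule for recessive genes (two distinct
    heterozygous pathogenic variants with age at onset of 50 years or less),
    dual-carrier logic across genes, ancestry-stratified diagnostic-yield and
    gene-by-ancestry tabulation, GBA1 severity-spectrum summaries, and
    age-at-onset group comparison by linear regression. A synthetic-cohort
    generator emits VCF, manifest and CNV files with planted carrier counts or
    frequencies so the whole pipeline can be exercised and validated without
    access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
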
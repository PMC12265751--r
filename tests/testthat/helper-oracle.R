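# Independent rule-by-rule reference classifier, written as a plain
# per-sample loop with no shared code paths with the package internals.
# Used to cross-check batch_classify on randomized cohorts.

oracle_classify_sample <- function(cohort, sid, catalog = CATALOG) {
  meta <- cohort$samples[cohort$samples$sample_id == sid, ]
  calls <- merge(
    as.data.frame(cohort$genotypes[cohort$genotypes$sample_id == sid, ]),
    as.data.frame(catalog$variants[, c("variant_key", "gene", "tier")]),
    by = "variant_key"
  )
  cnvs <- as.data.frame(cohort$cnvs[cohort$cnvs$sample_id == sid, ])
  genes <- union(unique(calls$gene), unique(cnvs$gene))
  causal_genes <- character(0)
  risk_genes <- character(0)
  single_het <- FALSE
  early <- !is.na(meta$aao_years) && meta$aao_years <= 50
  for (g in genes) {
    inh <- catalog$genes$inheritance[catalog$genes$symbol == g]
    gc <- calls[calls$gene == g, ]
    gv <- cnvs[cnvs$gene == g, ]
    path <- gc[gc$tier != "risk", ]
    risky <- gc[gc$tier == "risk", ]
    if (inh == "risk_locus") {
      if (nrow(risky) > 0) risk_genes <- c(risk_genes, g)
    } else if (inh == "autosomal_dominant") {
      if (nrow(path) > 0 || (g == "SNCA" && nrow(gv) > 0)) {
        causal_genes <- c(causal_genes, g)
      } else if (nrow(risky) > 0) {
        risk_genes <- c(risk_genes, g)
      }
    } else if (inh == "x_linked") {
      if (nrow(path) > 0) causal_genes <- c(causal_genes, g)
    } else { # recessive
      hom <- sum(path$zygosity == "hom_alt")
      hets <- unique(path$variant_key[path$zygosity == "het"])
      biall_cnv <- nrow(gv) > 0 && any(gv$alleles_affected == 2)
      one_cnv <- nrow(gv) > 0 && any(gv$alleles_affected == 1)
      if (hom > 0) {
        causal_genes <- c(causal_genes, g)
      } else if (biall_cnv) {
        causal_genes <- c(causal_genes, g)
      } else if (length(hets) >= 2 && early) {
        causal_genes <- c(causal_genes, g)
      } else if (length(hets) >= 1 && one_cnv && early) {
        causal_genes <- c(causal_genes, g)
      } else if (length(hets) >= 1 || one_cnv) {
        single_het <- TRUE
      }
    }
  }
  qualifying <- unique(c(causal_genes, risk_genes))
  if (length(qualifying) >= 2) return("dual")
  if (length(causal_genes) > 0) return("causal")
  if (length(risk_genes) > 0) return("risk")
  if (single_het) return("single_het_recessive")
  "none"
}

oracle_classify <- function(cohort, catalog = CATALOG) {
  vapply(cohort$samples$sample_id,
         function(s) oracle_classify_sample(cohort, s, catalog),
         character(1))
}
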
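#' Default census configuration: the published multi-ancestry cohort
#'
#' A census-mode [sim_config()] encoding, per ancestry and disease arm, the
#' published per-gene carrier counts of the non-genetically-enriched cohorts
#' (e.g., 532 affected GBA1 carriers of African ancestry, 439 East-Asian
#' LRRK2 risk-variant carriers, 25 Ashkenazi G2019S+GBA1 dual carriers),
#' stratum denominators (40,288 affected and 28,014 unaffected across 11
#' ancestries), the genetic-enrichment blocks that bring the totals to
#' 41,139 / 28,742, and the 461 affected single-het recessive carriers with
#' their onset structure (178 with onset <= 50 years among 344 with known
#' onset). Mechanism splits (homozygous vs CNV vs likely compound
#' heterozygous) follow the per-ancestry narrative counts. Classifying and
#' tabulating a cohort generated from this configuration reproduces the
#' published yield table arithmetic exactly (total causal-and-risk yield
#' 12.80%, causal-only 2.05%, unaffected 7.75%).
#'
#' Where published marginals disagree between tables, the yield-table
#' marginals win; per-variant compositions within GBA1 are spread over the
#' shipped catalog's variants, keeping each ancestry's headline variant
#' counts (rs3115534-G: 120 of 371 AAC affected, 517 of 1,030 AFR affected;
#' N409S leading in AJ; L483P leading in EAS; E365K/T408M leading in EUR).
#'
#' @return A `pd_sim_config`.
#' @export
default_paper_config <- function() {
  p <- function(anc, affected, class, n, v1 = NA, v2 = NA, gene = NA,
                event = NA, alleles = NA, aao = "default", sex = NA,
                enriched = FALSE) {
    plant_unit(anc, affected, class, n, v1, v2, gene, event, alleles,
               aao, sex, enriched)
  }
  # GBA1 heterozygous carriers, label = variant, one row per variant
  hets <- function(anc, affected, counts, enriched = FALSE) {
    dplyr::bind_rows(purrr::imap(
      counts, ~ p(anc, affected, "snv_het", .x, v1 = .y,
                  enriched = enriched)))
  }
  prkn_cnv_hom <- function(anc, n, affected = TRUE) {
    p(anc, affected, "cnv", n, gene = "PRKN", event = "exon_deletion",
      alleles = 2, aao = "early")
  }
  prkn_comphet <- function(anc, n) {
    p(anc, TRUE, "two_het", n, v1 = "R275W", v2 = "T240M", aao = "early")
  }

  plant <- dplyr::bind_rows(
    ## ---- AAC affected: 131 GBA1 + 1 PRKN = 132 (causal 1) ----
    p("AAC", TRUE, "snv_het", 102, v1 = "rs3115534"),
    p("AAC", TRUE, "snv_hom", 18, v1 = "rs3115534"),
    hets("AAC", TRUE, c(N409S = 3, E365K = 3, T408M = 2, L483P = 2,
                       R496H = 1)),
    prkn_cnv_hom("AAC", 1),
    ## ---- AAC unaffected: 222 GBA1 + 2 LRRK2 + 1 LRRK2-risk = 225 ----
    p("AAC", FALSE, "snv_het", 193, v1 = "rs3115534"),
    p("AAC", FALSE, "snv_hom", 10, v1 = "rs3115534"),
    hets("AAC", FALSE, c(E365K = 6, T408M = 5, N409S = 4, L483P = 2,
                        R496H = 2)),
    p("AAC", FALSE, "snv_het", 2, v1 = "G2019S"),
    p("AAC", FALSE, "snv_het", 1, v1 = "R1628P"),

    ## ---- AFR affected: 532 GBA1 + 1 LRRK2 + 2 LRRK2-risk + 1 PRKN ----
    p("AFR", TRUE, "snv_het", 394, v1 = "rs3115534"),
    p("AFR", TRUE, "snv_hom", 123, v1 = "rs3115534"),
    hets("AFR", TRUE, c(N409S = 2, E365K = 2, T408M = 2, L483P = 2,
                       L483R = 2, D448H = 2, R463C = 2, R496H = 1)),
    p("AFR", TRUE, "snv_het", 1, v1 = "G2019S"),
    p("AFR", TRUE, "snv_het", 2, v1 = "R1628P"),
    prkn_comphet("AFR", 1),
    ## ---- AFR unaffected: 573 GBA1 + 1 LRRK2 + 2 LRRK2-risk ----
    p("AFR", FALSE, "snv_het", 538, v1 = "rs3115534"),
    p("AFR", FALSE, "snv_hom", 30, v1 = "rs3115534"),
    hets("AFR", FALSE, c(N409S = 2, E365K = 2, T408M = 1)),
    p("AFR", FALSE, "snv_het", 1, v1 = "R1325Q"),
    p("AFR", FALSE, "snv_het", 2, v1 = "R1628P"),

    ## ---- AJ affected: 256 GBA1 + 201 LRRK2 + 25 dual = 482 ----
    hets("AJ", TRUE, c(N409S = 178, E365K = 30, T408M = 20, L483P = 12,
                      L483R = 6, D448H = 5, R463C = 3, R496H = 2)),
    p("AJ", TRUE, "snv_het", 200, v1 = "G2019S"),
    p("AJ", TRUE, "snv_het", 1, v1 = "R1067Q"),
    p("AJ", TRUE, "dual", 25, v1 = "G2019S", v2 = "N409S"),
    ## ---- AJ unaffected: 44 GBA1 + 15 LRRK2 + 1 dual = 60 ----
    hets("AJ", FALSE, c(N409S = 30, E365K = 8, T408M = 6)),
    p("AJ", FALSE, "snv_het", 15, v1 = "G2019S"),
    p("AJ", FALSE, "dual", 1, v1 = "G2019S", v2 = "N409S"),

    ## ---- AMR affected: 75 GBA1 + 44 LRRK2 + 10 PRKN + 2 ATP13A2
    ##      + 1 dual = 132 (causal 57) ----
    hets("AMR", TRUE, c(E365K = 20, T408M = 18, N409S = 15, L483P = 8,
                       rs3115534 = 5, L483R = 4, D448H = 3, R496H = 2)),
    p("AMR", TRUE, "snv_het", 43, v1 = "G2019S"),
    p("AMR", TRUE, "snv_het", 1, v1 = "R1441G"),
    p("AMR", TRUE, "snv_hom", 3, v1 = "R275W", aao = "early"),
    prkn_cnv_hom("AMR", 3),
    prkn_comphet("AMR", 2),
    p("AMR", TRUE, "snv_cnv", 2, v1 = "R275W", event = "exon_deletion",
      aao = "early"),
    p("AMR", TRUE, "snv_hom", 2, v1 = "R449Q", aao = "early"),
    p("AMR", TRUE, "dual", 1, v1 = "G2019S", v2 = "E365K"),
    ## ---- AMR unaffected: 12 GBA1 + 1 LRRK2 = 13 ----
    hets("AMR", FALSE, c(E365K = 5, T408M = 4, N409S = 3)),
    p("AMR", FALSE, "snv_het", 1, v1 = "G2019S"),

    ## ---- CAH affected: 127 GBA1 + 19 LRRK2 + 4 LRRK2-risk + 1 SNCA
    ##      + 2 VPS35 + 7 PRKN = 160 (causal 29) ----
    p("CAH", TRUE, "snv_het", 82, v1 = "rs3115534"),
    p("CAH", TRUE, "snv_hom", 4, v1 = "rs3115534"),
    hets("CAH", TRUE, c(E365K = 12, T408M = 10, N409S = 8, L483P = 6,
                       R463C = 5)),
    p("CAH", TRUE, "snv_het", 17, v1 = "G2019S"),
    p("CAH", TRUE, "snv_het", 2, v1 = "R1441C"),
    p("CAH", TRUE, "snv_het", 2, v1 = "R1628P"),
    p("CAH", TRUE, "snv_het", 2, v1 = "G2385R"),
    p("CAH", TRUE, "cnv", 1, gene = "SNCA", event = "multiplication",
      alleles = 1),
    p("CAH", TRUE, "snv_het", 2, v1 = "D620N"),
    prkn_cnv_hom("CAH", 4),
    prkn_comphet("CAH", 3),
    ## ---- CAH unaffected: 36 GBA1 + 5 LRRK2 + 1 LRRK2-risk = 42 ----
    p("CAH", FALSE, "snv_het", 31, v1 = "rs3115534"),
    p("CAH", FALSE, "snv_hom", 2, v1 = "rs3115534"),
    hets("CAH", FALSE, c(E365K = 2, N409S = 1)),
    p("CAH", FALSE, "snv_het", 5, v1 = "G2019S"),
    p("CAH", FALSE, "snv_het", 1, v1 = "R1628P"),

    ## ---- CAS affected: 30 GBA1 + 1 LRRK2 + 11 LRRK2-risk + 4 PRKN
    ##      + 1 dual = 47 (causal 5) ----
    hets("CAS", TRUE, c(E365K = 11, T408M = 9, N409S = 4, L483P = 3,
                       L483R = 1, D448H = 1, R463C = 1)),
    p("CAS", TRUE, "snv_het", 1, v1 = "R1441C"),
    p("CAS", TRUE, "snv_het", 8, v1 = "G2385R"),
    p("CAS", TRUE, "snv_het", 3, v1 = "R1628P"),
    prkn_cnv_hom("CAS", 3),
    prkn_comphet("CAS", 1),
    p("CAS", TRUE, "dual", 1, v1 = "G2385R", v2 = "rs3115534"),
    ## ---- CAS unaffected: 9 GBA1 + 3 LRRK2-risk = 12 ----
    hets("CAS", FALSE, c(E365K = 4, T408M = 3, N409S = 2)),
    p("CAS", FALSE, "snv_het", 3, v1 = "G2385R"),

    ## ---- EAS affected: 111 GBA1 + 10 LRRK2 + 439 LRRK2-risk + 4 SNCA
    ##      + 3 VPS35 + 12 PINK1 + 14 PRKN + 1 DCTN1 + 2 SLC20A2
    ##      + 17 dual = 613 (causal 46) ----
    hets("EAS", TRUE, c(L483P = 33, E365K = 14, T408M = 13, N409S = 13,
                       L483R = 12, D448H = 10, R463C = 9, R496H = 7)),
    p("EAS", TRUE, "snv_het", 3, v1 = "R1067Q"),
    p("EAS", TRUE, "snv_het", 3, v1 = "R1441C"),
    p("EAS", TRUE, "snv_het", 2, v1 = "R1441H"),
    p("EAS", TRUE, "snv_het", 2, v1 = "G2019S"),
    p("EAS", TRUE, "snv_het", 180, v1 = "R1628P"),
    p("EAS", TRUE, "snv_het", 229, v1 = "G2385R"),
    p("EAS", TRUE, "two_het", 30, v1 = "R1628P", v2 = "G2385R"),
    p("EAS", TRUE, "cnv", 2, gene = "SNCA", event = "multiplication",
      alleles = 1),
    p("EAS", TRUE, "snv_het", 2, v1 = "A53T"),
    p("EAS", TRUE, "snv_het", 3, v1 = "D620N"),
    p("EAS", TRUE, "snv_hom", 12, v1 = "L347P", aao = "early"),
    prkn_cnv_hom("EAS", 6),
    prkn_comphet("EAS", 6),
    p("EAS", TRUE, "snv_hom", 2, v1 = "R275W", aao = "early"),
    p("EAS", TRUE, "snv_het", 1, v1 = "G71R"),
    p("EAS", TRUE, "snv_het", 2, v1 = "S113L"),
    p("EAS", TRUE, "dual", 17, v1 = "G2385R", v2 = "L483P"),
    ## ---- EAS unaffected: 19 GBA1 + 1 LRRK2 + 217 LRRK2-risk + 1 dual
    ##      + 7 single-het PINK1 ----
    hets("EAS", FALSE, c(L483P = 6, E365K = 4, T408M = 3, N409S = 3,
                        L483R = 3)),
    p("EAS", FALSE, "snv_het", 1, v1 = "R1441C"),
    p("EAS", FALSE, "snv_het", 90, v1 = "R1628P"),
    p("EAS", FALSE, "snv_het", 127, v1 = "G2385R"),
    p("EAS", FALSE, "dual", 1, v1 = "G2385R", v2 = "L483P"),
    p("EAS", FALSE, "snv_het", 7, v1 = "L347P"),

    ## ---- EUR affected: 2501 GBA1 + 248 LRRK2 + 31 LRRK2-risk + 29 SNCA
    ##      + 4 VPS35 + 7 RAB32 + 8 PINK1 + 63 PRKN + 1 PARK7 + 4 DCTN1
    ##      + 2 RAB39B + 1 WDR45 + 26 dual = 2925 (causal 393) ----
    hets("EUR", TRUE, c(E365K = 1194, T408M = 755, N409S = 300,
                       L483P = 120, L483R = 50, D448H = 40, R463C = 30,
                       R496H = 12)),
    hets("EUR", TRUE, c(G2019S = 172, R1441C = 30, R1441G = 20,
                       R1441H = 5, R1325Q = 10, L1795F = 6, R1067Q = 5)),
    p("EUR", TRUE, "snv_het", 16, v1 = "R1628P"),
    p("EUR", TRUE, "snv_het", 15, v1 = "G2385R"),
    p("EUR", TRUE, "cnv", 15, gene = "SNCA", event = "multiplication",
      alleles = 1),
    p("EUR", TRUE, "snv_het", 14, v1 = "A53T"),
    p("EUR", TRUE, "snv_het", 4, v1 = "D620N"),
    p("EUR", TRUE, "snv_het", 7, v1 = "S71R"),
    p("EUR", TRUE, "snv_hom", 4, v1 = "L347P", aao = "early"),
    p("EUR", TRUE, "two_het", 4, v1 = "L347P", v2 = "Q456X",
      aao = "early"),
    p("EUR", TRUE, "snv_hom", 15, v1 = "R275W", aao = "early"),
    prkn_cnv_hom("EUR", 14),
    prkn_comphet("EUR", 20),
    p("EUR", TRUE, "snv_cnv", 14, v1 = "T240M", event = "exon_duplication",
      aao = "early"),
    p("EUR", TRUE, "snv_hom", 1, v1 = "E64D", aao = "early"),
    p("EUR", TRUE, "snv_het", 4, v1 = "G71R"),
    p("EUR", TRUE, "snv_het", 1, v1 = "L119P", sex = "female"),
    p("EUR", TRUE, "snv_hom", 1, v1 = "L119P", sex = "male"),
    p("EUR", TRUE, "snv_het", 1, v1 = "R212X", sex = "female"),
    p("EUR", TRUE, "dual", 20, v1 = "G2019S", v2 = "E365K"),
    p("EUR", TRUE, "dual", 3, v1 = "R1441C", v2 = "T408M"),
    p("EUR", TRUE, "dual", 3, v1 = "D620N", v2 = "N409S"),
    ## single heterozygous recessive-gene carriers (onset-structured):
    ## PRKN 410 (3 of them with two late-onset het variants), PINK1 16,
    ## ATP13A2 10, other recessive genes 25; overall 178 early / 166 late /
    ## 117 unknown onset.
    p("EUR", TRUE, "snv_het", 80, v1 = "R275W", aao = "early"),
    p("EUR", TRUE, "snv_het", 80, v1 = "T240M", aao = "early"),
    p("EUR", TRUE, "snv_het", 75, v1 = "R275W", aao = "late"),
    p("EUR", TRUE, "snv_het", 70, v1 = "P437L", aao = "late"),
    p("EUR", TRUE, "snv_het", 52, v1 = "T240M", aao = "missing"),
    p("EUR", TRUE, "snv_het", 50, v1 = "P437L", aao = "missing"),
    p("EUR", TRUE, "two_het", 3, v1 = "R275W", v2 = "T240M",
      aao = "late"),
    p("EUR", TRUE, "snv_het", 8, v1 = "L347P", aao = "early"),
    p("EUR", TRUE, "snv_het", 5, v1 = "L347P", aao = "late"),
    p("EUR", TRUE, "snv_het", 3, v1 = "Q456X", aao = "missing"),
    p("EUR", TRUE, "snv_het", 4, v1 = "R449Q", aao = "early"),
    p("EUR", TRUE, "snv_het", 4, v1 = "R449Q", aao = "late"),
    p("EUR", TRUE, "snv_het", 2, v1 = "F182L", aao = "missing"),
    p("EUR", TRUE, "snv_het", 2, v1 = "R153X", aao = "early"),
    p("EUR", TRUE, "snv_het", 3, v1 = "R153X", aao = "late"),
    p("EUR", TRUE, "snv_het", 3, v1 = "R153X", aao = "missing"),
    p("EUR", TRUE, "snv_het", 2, v1 = "Q734X", aao = "early"),
    p("EUR", TRUE, "snv_het", 2, v1 = "Q734X", aao = "late"),
    p("EUR", TRUE, "snv_het", 2, v1 = "Q734X", aao = "missing"),
    p("EUR", TRUE, "snv_het", 1, v1 = "R498X", aao = "early"),
    p("EUR", TRUE, "snv_het", 2, v1 = "R498X", aao = "late"),
    p("EUR", TRUE, "snv_het", 2, v1 = "R498X", aao = "missing"),
    p("EUR", TRUE, "snv_het", 1, v1 = "R258Q", aao = "early"),
    p("EUR", TRUE, "snv_het", 1, v1 = "R258Q", aao = "late"),
    p("EUR", TRUE, "snv_het", 2, v1 = "R258Q", aao = "missing"),
    p("EUR", TRUE, "snv_het", 1, v1 = "W79X", aao = "late"),
    p("EUR", TRUE, "snv_het", 1, v1 = "W79X", aao = "missing"),
    ## ---- EUR unaffected: 937 GBA1 + 35 LRRK2 + 19 LRRK2-risk + 3 SNCA
    ##      + 5 dual = 999; plus 1 single-het PRKN ----
    hets("EUR", FALSE, c(E365K = 450, T408M = 300, N409S = 101,
                        L483P = 40, L483R = 20, D448H = 15, R463C = 8,
                        R496H = 3)),
    hets("EUR", FALSE, c(G2019S = 25, R1441C = 5, R1325Q = 5)),
    p("EUR", FALSE, "snv_het", 10, v1 = "R1628P"),
    p("EUR", FALSE, "snv_het", 9, v1 = "G2385R"),
    p("EUR", FALSE, "snv_het", 3, v1 = "A53T"),
    p("EUR", FALSE, "dual", 5, v1 = "G2019S", v2 = "E365K"),
    p("EUR", FALSE, "snv_het", 1, v1 = "R275W"),

    ## ---- FIN affected: 14 GBA1 ----
    hets("FIN", TRUE, c(E365K = 6, T408M = 5, N409S = 3)),
    ## ---- FIN unaffected: 1 GBA1 T408M ----
    hets("FIN", FALSE, c(T408M = 1)),

    ## ---- MDE affected: 19 GBA1 + 42 LRRK2 + 1 SNCA + 1 RAB32
    ##      + 10 PINK1 + 4 PRKN + 3 dual = 80 (causal 61) ----
    hets("MDE", TRUE, c(N409S = 3, E365K = 3, T408M = 3, L483P = 2,
                       L483R = 2, D448H = 2, R463C = 2, R496H = 2)),
    p("MDE", TRUE, "snv_het", 35, v1 = "G2019S"),
    p("MDE", TRUE, "snv_het", 7, v1 = "R1441C"),
    p("MDE", TRUE, "cnv", 1, gene = "SNCA", event = "multiplication",
      alleles = 1),
    p("MDE", TRUE, "snv_het", 1, v1 = "S71R"),
    p("MDE", TRUE, "snv_hom", 7, v1 = "L347P", aao = "early"),
    p("MDE", TRUE, "two_het", 3, v1 = "L347P", v2 = "Q456X",
      aao = "early"),
    prkn_cnv_hom("MDE", 2),
    prkn_comphet("MDE", 2),
    p("MDE", TRUE, "dual", 3, v1 = "G2019S", v2 = "N409S"),
    ## ---- MDE unaffected: 1 LRRK2 G2019S ----
    p("MDE", FALSE, "snv_het", 1, v1 = "G2019S"),

    ## ---- SAS affected: 29 GBA1 + 1 LRRK2 + 1 LRRK2-risk + 5 PRKN ----
    hets("SAS", TRUE, c(L483R = 11, N409S = 5, E365K = 4, T408M = 4,
                       L483P = 3, D448H = 2)),
    p("SAS", TRUE, "snv_het", 1, v1 = "R1067Q"),
    p("SAS", TRUE, "snv_het", 1, v1 = "R1628P"),
    p("SAS", TRUE, "snv_hom", 2, v1 = "R275W", aao = "early"),
    prkn_cnv_hom("SAS", 1),
    prkn_comphet("SAS", 2),
    ## ---- SAS unaffected: 3 GBA1 L483R ----
    hets("SAS", FALSE, c(L483R = 3)),

    ## ---- genetic-enrichment blocks (recruited carriers) ----
    hets("AAC", TRUE, c(E365K = 2), enriched = TRUE),
    p("AJ", TRUE, "snv_het", 199, v1 = "G2019S", enriched = TRUE),
    hets("AJ", TRUE, c(N409S = 100), enriched = TRUE),
    p("AMR", TRUE, "snv_het", 2, v1 = "G2019S", enriched = TRUE),
    p("CAH", TRUE, "snv_het", 1, v1 = "G2019S", enriched = TRUE),
    p("CAS", TRUE, "snv_het", 1, v1 = "G2019S", enriched = TRUE),
    p("EAS", TRUE, "snv_het", 7, v1 = "G2019S", enriched = TRUE),
    hets("EAS", TRUE, c(L483P = 4), enriched = TRUE),
    p("EUR", TRUE, "snv_het", 228, v1 = "G2019S", enriched = TRUE),
    hets("EUR", TRUE, c(E365K = 109), enriched = TRUE),
    p("MDE", TRUE, "snv_het", 24, v1 = "G2019S", enriched = TRUE),
    hets("SAS", TRUE, c(N409S = 2), enriched = TRUE),
    p("AJ", FALSE, "snv_het", 242, v1 = "G2019S", enriched = TRUE),
    hets("AJ", FALSE, c(N409S = 214), enriched = TRUE),
    p("AMR", FALSE, "snv_het", 2, v1 = "G2019S", enriched = TRUE),
    hets("AMR", FALSE, c(E365K = 2), enriched = TRUE),
    hets("CAH", FALSE, c(E365K = 1), enriched = TRUE),
    p("CAS", FALSE, "snv_het", 1, v1 = "G2019S", enriched = TRUE),
    p("EUR", FALSE, "snv_het", 173, v1 = "G2019S", enriched = TRUE),
    hets("EUR", FALSE, c(E365K = 61), enriched = TRUE),
    p("MDE", FALSE, "snv_het", 2, v1 = "G2019S", enriched = TRUE)
  )

  strata <- dplyr::bind_rows(
    strata_block(TRUE, FALSE,
                 c(AAC = 371, AFR = 1030, AJ = 1745, AMR = 2140,
                   CAH = 812, CAS = 753, EAS = 3363, EUR = 28859,
                   FIN = 120, MDE = 596, SAS = 499)),
    strata_block(FALSE, FALSE,
                 c(AAC = 855, AFR = 1743, AJ = 695, AMR = 1481,
                   CAH = 337, CAS = 370, EAS = 2503, EUR = 19539,
                   FIN = 14, MDE = 242, SAS = 235)),
    strata_block(TRUE, TRUE,
                 c(AAC = 2, AJ = 300, AMR = 3, CAH = 1, CAS = 3,
                   EAS = 31, EUR = 480, FIN = 1, MDE = 24, SAS = 6)),
    strata_block(FALSE, TRUE,
                 c(AJ = 463, AMR = 4, CAH = 2, CAS = 1, EUR = 256,
                   MDE = 2))
  )
  sim_config("census", plant = plant, strata = strata)
}

strata_block <- function(affected, enriched, counts) {
  tibble::tibble(ancestry = names(counts), affected = affected,
                 enriched = enriched, n_total = as.integer(counts))
}
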
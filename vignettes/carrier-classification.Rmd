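---
title: "Methods: carrier classification, yield tabulation, and cohort simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: carrier classification, yield tabulation, and cohort simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdcarrier)
library(dplyr)
```

## The problem

Monogenic and strong-risk variants explain a clinically meaningful fraction
of Parkinson's disease (PD), but the responsible genes and variants differ
sharply between ancestries: the intronic *GBA1* rs3115534-G allele dominates
in African and African-admixed populations, *LRRK2* G2019S in Ashkenazi
Jewish and Middle Eastern populations, the *LRRK2* risk variants
R1628P/G2385R in East Asians. Estimating a cohort's *diagnostic yield* — the
proportion of individuals carrying a qualifying variant — therefore requires
(i) a curated variant catalog, (ii) a per-individual decision procedure that
handles dominant, recessive, X-linked, and risk-only genes, and (iii)
tabulation that is explicit about who counts where. `pdcarrier` implements
this pipeline over standard inputs (VCF genotypes, a sample manifest, a
pre-called CNV table) and pairs it with a cohort simulator so every step can
be validated without access-restricted subject-level data.

## Variant catalog

The gene panel is fixed: three autosomal-dominant PD genes (*LRRK2*,
*SNCA*, *VPS35*) plus *RAB32* (S71R), three early-onset recessive genes
(*PARK7*, *PINK1*, *PRKN*), ten atypical-parkinsonism genes (with *RAB39B*
and *WDR45* X-linked), and *GBA1*. Variants carry a tier — `pathogenic`,
`likely_pathogenic` (jointly "causal-eligible"; results never separate
them), or `risk`. Two constraints are enforced at load time: every *GBA1*
variant is a risk variant, including variants causal for Gaucher disease;
and the only *LRRK2* risk variants are R1628P and G2385R. *GBA1* variants
additionally carry a severity class (severe / mild / risk / unknown);
rs3115534-G is `unknown` because severity browsers do not yet cover it.

The shipped catalog (`default_catalog()`) holds the recurrently reported
variants per gene and is deliberately extensible — it is a knowledge table,
not an annotation engine. Coordinates are GRCh38, 1-based, VCF allele
convention; they serve as exact join keys between catalog and VCF, and for
several rare variants are illustrative placements within the gene. No
ClinVar querying or ACMG scoring happens at run time: tiers are curated
inputs.

## Classification rules

Each gene in each individual is assessed independently
(`assess_gene()`), then the per-gene findings combine into one category per
individual (`classify_sample()` / `batch_classify()`):

1. **Risk variants** (all of *GBA1*; *LRRK2* R1628P/G2385R) give risk-level
   evidence at any zygosity. Homozygous risk genotypes are recorded but do
   not escalate the category. Carrying both *LRRK2* risk variants is still
   one finding.
2. **Dominant genes**: one causal-eligible het/hom variant suffices; an
   *SNCA* multiplication is a causal dominant mechanism.
3. **X-linked genes**: any causal-eligible variant qualifies. Female
   heterozygous carriers count as causal-level by default
   (`count_xlinked_female_het`), since carrier reports in this field
   usually omit zygosity; the flag exists because the penetrance argument
   cuts both ways. Diploid-coded male X genotypes (`1/1`) are reinterpreted
   as hemizygous at cohort assembly, as genotyping arrays emit them.
4. **Recessive genes**: a homozygous causal-eligible variant or a biallelic
   CNV is causal with *no* onset condition. Without phase information, two
   distinct heterozygous causal-eligible variants are interpreted as a
   *likely compound heterozygote* only when age at onset (AAO) is known and
   ≤ 50 years; one het SNV plus a single-allele CNV qualifies under the
   same gate. Everything else with at least one pathogenic allele is a
   *single-het recessive* carrier — never causal, never
   category-qualifying.

The AAO gate is inclusive at exactly 50 and fails closed: missing onset
means no compound-het call. A single-allele CNV with no partnering variant
is also treated as a single-het carrier (one pathogenic allele); two
identical het calls at one variant can never form a compound het.

Within a gene, causal-level evidence takes precedence over risk-level: an
individual with both *LRRK2* G2019S and G2385R is a causal carrier. This
ordering is forced by monotonicity — adding a causal variant must never
demote an individual — and by the tabulation convention that risk-column
counts exclude pathogenic carriers.

Across genes, the category precedence is `dual` (two or more distinct
genes, each individually causal- or risk-level) > `causal` > `risk` >
`single_het_recessive` > `none`. Single-het findings never contribute to
dual status: a het *PINK1* carrier with a *LRRK2* risk variant is `risk`,
with the single-het finding recorded as evidence. A biallelic recessive
carrier who also carries a *GBA1* risk variant is `dual` — the reported
tables keep a separate dual column, and this choice is applied uniformly.
Unaffected individuals pass through identical rules.

## Tabulation conventions

`yield_table()` reports numerator/denominator/percentage per ancestry plus
a Total row, per disease arm. Under `causal_only`, dual carriers count only
if at least one component is causal-level (a pathogenic *LRRK2* + *GBA1*
dual is a causal finding; an *LRRK2*-risk + *GBA1* dual is not). Excluding
genetic-enrichment cohorts (individuals recruited *because of* known
carrier status) removes them from numerator and denominator alike — the
unbiased estimate. Percentages are rounded half-up: two decimals in
tables, one decimal in prose-style figures (`round_half_up()`; R's
`round()` is half-even and would disagree on ties). Unaffected family
members and population cohorts pool with controls in the unaffected
denominator.

`gene_table()` counts each qualifying individual exactly once: dual
carriers in a `Dual` column only, *LRRK2* risk-variant carriers in an
`LRRK2_risk` column apart from pathogenic *LRRK2* carriers, and single-het
carriers nowhere (they are summarised separately by
`single_het_summary()`, including the share with onset ≤ 50 among carriers
with known onset). `gba1_spectrum()` reports per-variant carrier counts
and shares among an ancestry's *GBA1* carriers — including the *GBA1*
component of dual carriers — with optional collapsing of rare variants
into an `Other` entry within their severity group, either for severe
variants only or for all groups. Ranking ties break lexicographically by
protein label, for determinism.

## Age-at-onset comparison

`assign_aao_groups()` restricts to affected PD cases with known onset and
forms three groups per ancestry: idiopathic PD (no qualifying and no
single-het finding), *GBA1*-PD (sole qualifying gene *GBA1*), and
*LRRK2*-PD (sole qualifying gene *LRRK2*, pathogenic or risk). Dual
carriers, carriers in other genes, and single-het carriers are excluded —
their onset is confounded by the other finding. `compare_aao()` fits
ordinary least squares of onset on group indicators with IPD as reference,
separately per ancestry; the coefficient is the onset difference in years.
No covariates are included by default (a `covariates` hook accepts e.g.
`"sex"`), significance is two-sided at α = 0.05 without multiple-testing
correction, and medians are reported alongside. With fewer than two groups
or fewer than two non-reference observations, only medians are returned.
The two-group coefficient equals the difference in group means, which the
tests verify in closed form; coefficients are invariant to adding a
constant to every onset.

## The cohort simulator

`generate_cohort()` emits a manifest, genotype calls, CNV calls, and a
truth record, deterministically for a given seed; `write_cohort_files()`
serialises them as `manifest.tsv`, a plain-text VCF v4.2 (`cohort.vcf`,
sites restricted to the catalog), `cnv.tsv`, and `truth.json`.

**Census mode** plants exact carrier counts per stratum: each planted unit
specifies a mechanism (het/hom SNV, two distinct hets, CNV, SNV+CNV,
dual), its variants, and an onset rule. `default_paper_config()` encodes
the published non-enriched multi-ancestry cohort that this pipeline
models: 40,288 affected and 28,014 unaffected individuals across 11
ancestries with the reported per-gene carrier counts (e.g. 131 affected
*GBA1* carriers of 371 African-admixed samples, 120 of them rs3115534-G;
439 East-Asian *LRRK2* risk carriers of 3,363; 2,501 European *GBA1*
carriers of 28,859; 25 Ashkenazi G2019S+*GBA1* dual carriers), the
genetic-enrichment blocks that complete the 41,139 / 28,742 totals, and
461 single-het recessive carriers of which 178 of 344 with known onset are
≤ 50 years. Where published marginal tables disagree by a few counts, the
yield-table marginals were taken as definitive and gene compositions
adjusted minimally; these reconciliations are configuration choices,
visible in `default_paper_config()`. Classify-and-tabulate on this
configuration reproduces the published yield arithmetic exactly — total
causal+risk yield 12.80%, causal-only 2.05%, unaffected 7.75% — which is
what the acceptance suite asserts.

**Binomial mode** draws heterozygous carrier status independently per
variant at configured per-ancestry frequencies, for calibration-style
checks: estimated carrier frequencies fall inside the 95% binomial
interval of the planted frequency in ≥ 93 of 100 replicate seeds, and
planted onset shifts are recovered within two standard errors at ≥ 500
cases per group.

**Onset model.** Onset is normal, truncated to [5, 98] years (the range
observed in unselected PD cohorts), with mean 60 and SD 10 for idiopathic
cases — a modelling choice matching the reported median of unselected PD,
not a fitted distribution. Carriers whose sole qualifying gene is *GBA1*
or *LRRK2* are shifted by −5 and −2 years, the midpoints of the reported
3–8 and 1–4 year ranges. Planted compound heterozygotes draw onset in
[5, 50]; planted late-onset two-het carriers in (50, 98]. A configurable
fraction (default 0.3, matching observed missingness) of onsets is
blanked at random — but only for samples whose classification does not
depend on onset, otherwise census counts could not be exact. Age at
sampling is onset plus a non-negative normal delay; unaffected individuals
have no onset.

**What the simulator does not emulate** — and hence what passing tests do
and do not show about real data: no genotyping error or missing genotypes,
no linkage disequilibrium or relatedness, no population substructure
within ancestry labels, no upstream QC artifacts, no phasing ambiguity
beyond the absence of phase itself, and CNVs arrive as a clean pre-called
table. Recovery of planted counts validates the decision logic and
bookkeeping, not robustness to noisy calling.

## Problem sizes and run times

The default census cohort (~70,000 samples, ~9,300 genotype calls) is
generated, written, re-read through the VCF path, and classified in well
under a minute on one core; classification cost scales with the number of
carriers, not the cohort size. Randomized property-test cohorts use
200–1,000 samples, and the replicate-seed suites use 100 replicates —
sizes chosen to make binomial and OLS checks decisive while keeping the
full test suite fast.

## Known limitations

Compound-heterozygote inference from unphased data is heuristic; the
onset gate trades sensitivity in late-onset biallelic carriers for
specificity, mirroring clinical practice. The shipped catalog is
illustrative rather than exhaustive, so absolute yields from user data
depend entirely on the catalog supplied. CNV input is taken at face
value. The X-linked female-het convention is configurable because the
field has no consensus. The AAO regression is unadjusted by default; with
strong between-ancestry confounding, per-ancestry stratification is the
only control applied.
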
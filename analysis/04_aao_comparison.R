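#!/usr/bin/env Rscript
# Step 4: age-at-onset comparison of GBA1-PD and LRRK2-PD against
# idiopathic PD within each ancestry, by ordinary least squares with IPD as
# the reference group.
suppressMessages({library(pdcarrier); library(dplyr)})

cohort <- read_cohort_dir("results/cohort")
findings <- batch_classify(cohort)

labeled <- assign_aao_groups(findings, cohort$samples)
res <- compare_aao(labeled)
readr::write_tsv(res, "results/aao_comparison.tsv")

message("Onset comparison across ", length(unique(res$ancestry)),
        " ancestries -> results/aao_comparison.tsv")
sig <- res |>
  filter(!is.na(p_value), p_value < 0.05) |>
  mutate(line = sprintf("  %s %s: %+.1f years vs IPD (SE %.2f, p = %.2g)",
                        ancestry, group, coefficient, se, p_value))
message("Significant onset differences (alpha = 0.05, two-sided):")
for (l in sig$line) message(l)
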
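#!/usr/bin/env Rscript
# Classify the phenotyped population into brown/cream/white by CIE76
# distance to the parental references, and compare the L* channel across
# groups with one-way ANOVA + Tukey HSD.

suppressPackageStartupMessages(library(lintmap))
dir.create("results", showWarnings = FALSE)

ph <- read_phenotypes_csv("results/phenotypes.csv")
avg <- average_replicates(ph)
means <- phenotype_means()
cls <- classify_colors(avg, brown_ref = means["2", ],
                       white_ref = means["0", ], cream_band = 5)
utils::write.csv(cls, "results/color_groups.csv", row.names = FALSE)

message(sprintf("parental Delta-E: %.2f",
                delta_e(means["0", ], means["2", ])))
cmp <- compare_groups(avg$L, cls$group, trait = "L*")
print(cmp)
utils::write.table(cmp$pairwise, "results/color_group_comparison.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("all pairwise L* contrasts among the three groups are reported above")
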
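#!/usr/bin/env Rscript
# Differential expression: simulate counts for two pigmented mutant lines
# and a white control with the causal transcription factor planted 179x and
# 756x up, test each mutant against the control (FDR < 0.05, two-fold), and
# summarize the planted flavonoid-pathway cohort.

suppressPackageStartupMessages(library(lintmap))
dir.create("results", showWarnings = FALSE)
seed <- 2026L

grp <- rep(c("mutant_a", "mutant_b", "control"), each = 3L)
pathway_genes <- 1:10
planted <- rbind(
  data.frame(gene = 1L, group = "mutant_a", fold = 179, base_mean = 50),
  data.frame(gene = 1L, group = "mutant_b", fold = 756, base_mean = 50),
  data.frame(gene = 2:10, group = "mutant_b", fold = 4, base_mean = NA))
counts <- simulate_counts(2000L, grp, planted = planted, seed = seed)
write_counts_tsv(counts, "results/counts.tsv")
norm <- cpm_normalize(counts)

for (line in c("mutant_a", "mutant_b")) {
  keep <- grp %in% c(line, "control")
  deg <- test_deg(norm[, keep], grp[keep], line_a = line,
                  line_b = "control")
  utils::write.table(deg, sprintf("results/deg_%s.tsv", line),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s vs control: %d genes at FDR<0.05 & 2-fold; %s: %.0f-fold",
                  line, sum(deg$significant), deg$gene[1],
                  deg$fold_change[1]))
  pw <- summarize_pathway(deg, data.frame(gene = deg$gene[pathway_genes],
                                          pathway = "flavonoid"))
  utils::write.table(pw, sprintf("results/pathway_%s.tsv", line),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  print(pw)
}
message("the flavonoid cohort's median fold is larger in mutant_b, ",
        "matching the planted ordering of the two pigmented lines")
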
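#!/usr/bin/env Rscript
# Simulate the F2 mapping population: 508 individuals from a brown x white
# cross, incomplete dominance at one locus, three CIELab technical
# replicates per plant. Writes phenotypes and the carrier segregation test.

suppressPackageStartupMessages(library(lintmap))
dir.create("results", showWarnings = FALSE)
seed <- 2026L

genome <- default_genome()
config <- cross_config(seed = seed)
pop <- assign_phenotypes(simulate_f2(genome, config))

write_phenotypes_csv(
  cbind(pop$phenotypes, group = as.character(pop$group)[pop$phenotypes$id]),
  "results/phenotypes.csv")

tab <- table(pop$group)
message(sprintf("phenotype groups: brown %d, cream %d, white %d",
                tab[["brown"]], tab[["cream"]], tab[["white"]]))

carriers <- sum(tab[c("brown", "cream")])
seg <- chi_square_ratio(c(carriers, tab[["white"]]), c(3, 1))
print(seg)
write_segregation_tsv(seg, "results/segregation.tsv")
message(sprintf(
  "carrier:white = %d:%d fits 3:1 (chi2 %.2f, p %.2f) -> single-locus model",
  carriers, tab[["white"]], seg$chi2, seg$p_value))
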
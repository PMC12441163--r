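#!/usr/bin/env Rscript
# Bulked-segregant genome scan: bulk 77 brown and 77 white segregants,
# simulate their called variant sets, subtract identical variants, bin the
# residue in 5-Mb windows and report the peak region.

suppressPackageStartupMessages(library(lintmap))
dir.create("results", showWarnings = FALSE)
seed <- 2026L

genome <- default_genome()
config <- cross_config(seed = seed)
pop <- assign_phenotypes(simulate_f2(genome, config))
bulks <- make_bulks(pop)
sites <- parental_variant_sites(genome)
bv <- simulate_bulk_variants(genome, pop, bulks, config, sites)
write_variants_vcf(bv[[1]], "results/bulk_brown.vcf", genome)
write_variants_vcf(bv[[2]], "results/bulk_white.vcf", genome)

diffset <- subtract_shared_variants(bv[[1]], bv[[2]], names = names(bulks))
write_variants_vcf(diffset, "results/bulk_differential.vcf", genome)
message(sprintf("bulk sizes: %d / %d variants; %d remain after subtraction",
                nrow(bv[[1]]), nrow(bv[[2]]), nrow(diffset)))

bins <- bin_counts(diffset, genome, bin_width = 5e6)
peak <- detect_peak(bins)
write_bins_bed(bins, "results/scan_bins.bed")
write_bins_bed(peak, "results/peak_region.bed")
utils::write.table(bins, "results/scan_bins.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
print(peak)
cl <- genome$causal_locus
message(sprintf("causal locus %s:%s %s inside the peak region",
                cl$chrom, format(cl$pos, big.mark = ",", scientific = FALSE),
                if (peak$chrom == cl$chrom && peak$start < cl$pos &&
                    peak$end >= cl$pos) "lies" else "does NOT lie"))
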
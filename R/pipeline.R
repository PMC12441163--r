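#' Run the full synthetic mapping pipeline
#'
#' End-to-end driver over the package's stages: simulate an F2 population,
#' phenotype and classify it, test carrier segregation against 3:1, build
#' the two phenotype bulks, simulate and subtract their variant sets, bin
#' and scan for the peak, genotype the marker panel and report the
#' co-segregation interval, annotate a synthetic LTR element with
#' presence/absence calls at the locus, and run the differential-expression
#' comparison on simulated counts. All stage outputs land in `output_dir`
#' with a manifest; rerunning with the same seed reproduces the files
#' byte-identically.
#'
#' @param output_dir Directory for stage outputs (created if needed).
#' @param seed Integer seed for the whole run.
#' @param genome A [genome_model()].
#' @param config A [cross_config()]; its seed is overridden by `seed`.
#' @param bin_width Scan window width in bp.
#' @param panel Marker panel (defaults to [default_marker_panel()]).
#' @param n_genes,planted_fold Expression stage size and planted effect.
#' @return Invisible list with all intermediate results.
#' @export
run_pipeline <- function(output_dir, seed = 1L,
                         genome = default_genome(),
                         config = cross_config(),
                         bin_width = 5e6,
                         panel = default_marker_panel(genome),
                         n_genes = 2000L, planted_fold = 179) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  config$seed <- seed
  p <- function(...) file.path(output_dir, ...)

  pop <- simulate_f2(genome, config)
  pop <- assign_phenotypes(pop)
  write_phenotypes_csv(
    cbind(pop$phenotypes,
          group = as.character(pop$group)[pop$phenotypes$id]),
    p("phenotypes.csv"))

  tab <- table(pop$group)
  carriers <- sum(tab[c("brown", "cream")])
  seg <- chi_square_ratio(c(carriers, tab[["white"]]), c(3, 1))
  write_segregation_tsv(seg, p("segregation.tsv"))

  bulks <- make_bulks(pop)
  sites <- parental_variant_sites(genome)
  bv <- simulate_bulk_variants(genome, pop, bulks, config, sites)
  write_variants_vcf(bv[[1]], p("bulk_brown.vcf"), genome)
  write_variants_vcf(bv[[2]], p("bulk_white.vcf"), genome)
  diffset <- subtract_shared_variants(bv[[1]], bv[[2]],
                                      names = names(bulks))
  write_variants_vcf(diffset, p("bulk_differential.vcf"), genome)
  bins <- bin_counts(diffset, genome, bin_width)
  peak <- detect_peak(bins)
  write_bins_bed(bins, p("scan_bins.bed"))
  if (!isTRUE(peak$no_peak)) write_bins_bed(peak, p("peak_region.bed"))

  calls <- genotype_markers(pop, panel)
  rec <- score_recombinants(calls,
                            data.frame(id = seq_len(pop$n),
                                       group = pop$group))
  interval <- find_interval(panel, rec)
  write_interval_tsv(interval, calls,
                     data.frame(id = seq_len(pop$n), group = pop$group),
                     p("interval.tsv"), p("marker_matrix.tsv"))

  el <- synth_ltr_element(seed = seed)
  fx <- ltr_locus_fixtures(el$element, el$ltr5, seed = seed + 1L)
  ann <- annotate_ltr(el$element)
  write_fasta(c(element = el$element, occupied_locus = fx$present,
                empty_locus = fx$clean), p("ltr_locus.fasta"))
  write_ltr_gff3(ann, "element", p("ltr_annotation.gff3"))
  pav <- list(occupied = call_pav(fx$present, el$element),
              empty = call_pav(fx$clean, el$element))
  utils::write.table(
    data.frame(locus = names(pav),
               status = vapply(pav, `[[`, "", "status"),
               coverage = vapply(pav, `[[`, 0, "coverage"),
               remnant = vapply(pav, `[[`, "", "remnant")),
    p("pav_calls.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  groups_expr <- rep(c("mutant", "control"), each = 3L)
  counts <- simulate_counts(n_genes, groups_expr,
                            planted = data.frame(gene = 1L,
                                                 group = "mutant",
                                                 fold = planted_fold,
                                                 base_mean = 50),
                            seed = seed + 2L)
  deg <- test_deg(cpm_normalize(counts), groups_expr,
                  line_a = "mutant", line_b = "control")
  write_counts_tsv(counts, p("counts.tsv"))
  utils::write.table(deg, p("deg_results.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pw <- summarize_pathway(deg, data.frame(gene = deg$gene[1],
                                          pathway = "flavonoid"))
  utils::write.table(pw, p("pathway_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  write_manifest(p("manifest.json"), seed, config, genome,
                 extra = list(bin_width = bin_width,
                              n_genes = n_genes,
                              planted_fold = planted_fold,
                              n_markers = nrow(panel)))
  invisible(list(population = pop, segregation = seg, bulks = bulks,
                 differential = diffset, bins = bins, peak = peak,
                 interval = interval, ltr = ann, pav = pav, deg = deg))
}
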
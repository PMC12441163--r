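# Seeded replication studies over the synthetic generator. These back the
# package's calibration claims; tests and the acceptance script call them at
# the same problem sizes the methods vignette documents.

.rep_seed <- function(seed, i) (seed + 7919L * i) %% .Machine$integer.max

#' Replicated genome-scan study: does the peak window hit the locus?
#'
#' For each replicate: simulate the default cross, bulk the brown and white
#' groups, simulate and subtract the bulk variant sets, bin, and record
#' whether the detected peak window contains the causal locus.
#'
#' @param n_reps Number of replicates.
#' @param seed Base seed; replicate r runs under a seed derived from it.
#' @param genome,config Study conditions.
#' @param bin_width Scan window width (bp).
#' @return data.frame with one row per replicate (`hit`, `peak_chrom`,
#'   `peak_count`).
#' @export
bsa_peak_study <- function(n_reps = 50, seed = 1L,
                           genome = default_genome(),
                           config = cross_config(),
                           bin_width = 5e6) {
  cl <- genome$causal_locus
  out <- lapply(seq_len(n_reps), function(r) {
    config$seed <- .rep_seed(seed, r)
    pop <- assign_phenotypes(simulate_f2(genome, config))
    bulks <- make_bulks(pop)
    sites <- parental_variant_sites(genome)
    bv <- simulate_bulk_variants(genome, pop, bulks, config, sites)
    peak <- detect_peak(bin_counts(
      subtract_shared_variants(bv[[1]], bv[[2]]), genome, bin_width))
    hit <- !isTRUE(peak$no_peak) && peak$chrom == cl$chrom &&
      any(peak$windows$start < cl$pos & peak$windows$end >= cl$pos)
    data.frame(replicate = r, hit = hit,
               peak_chrom = if (isTRUE(peak$no_peak)) NA else peak$chrom,
               peak_count = if (isTRUE(peak$no_peak)) 0 else peak$peak_count)
  })
  do.call(rbind, out)
}

#' Replicated interval-mapping study
#'
#' For each replicate: simulate the cross, genotype the marker panel, score
#' recombinants against the phenotype groups, and record whether the
#' reported interval brackets the causal position and whether the panel
#' marker nearest the locus co-segregates (zero recombinants).
#'
#' @inheritParams bsa_peak_study
#' @param panel Marker panel.
#' @return data.frame per replicate (`bracketed`, `nearest_coseg`, `span`).
#' @export
interval_study <- function(n_reps = 50, seed = 1L,
                           genome = default_genome(),
                           config = cross_config(),
                           panel = default_marker_panel(genome)) {
  cl <- genome$causal_locus
  nearest <- panel$name[which.min(abs(panel$pos - cl$pos))]
  out <- lapply(seq_len(n_reps), function(r) {
    config$seed <- .rep_seed(seed, r)
    pop <- assign_phenotypes(simulate_f2(genome, config))
    calls <- genotype_markers(pop, panel)
    rec <- score_recombinants(calls,
                              data.frame(id = seq_len(pop$n),
                                         group = pop$group))
    iv <- find_interval(panel, rec)
    data.frame(replicate = r,
               bracketed = iv$left_pos <= cl$pos & iv$right_pos >= cl$pos,
               nearest_coseg = nearest %in%
                 iv$per_marker$name[iv$per_marker$recombinants == 0],
               span = iv$span, open = iv$open)
  })
  do.call(rbind, out)
}

#' Differential-expression calibration study
#'
#' Per seed, runs (a) a pure-null experiment (`n_genes` genes, two lines,
#' `n_reps_per_line` replicates) recording the false discovery proportion
#' among flagged genes, and (b) a planted experiment with one gene upscaled
#' `fold_a`-fold in line `mutant_a` and `fold_b`-fold in line `mutant_b`
#' against a shared control, recording whether the planted gene is flagged
#' and the recovered fold changes.
#'
#' @param n_seeds Number of independent seeds.
#' @param seed Base seed.
#' @param n_genes Genes per experiment.
#' @param n_reps_per_line Replicates per line.
#' @param fold_a,fold_b Planted fold changes.
#' @param dispersion Negative-binomial dispersion.
#' @return data.frame per seed (`fdp`, `n_flagged_null`, `planted_flagged`,
#'   `fold_a_hat`, `fold_b_hat`).
#' @export
deg_calibration_study <- function(n_seeds = 20, seed = 1L, n_genes = 2000L,
                                  n_reps_per_line = 2L,
                                  fold_a = 179, fold_b = 756,
                                  dispersion = 0.05) {
  out <- lapply(seq_len(n_seeds), function(r) {
    s <- .rep_seed(seed, r)
    # (a) null: every flagged gene is a false discovery
    grp0 <- rep(c("mutant", "control"), each = n_reps_per_line)
    c0 <- simulate_counts(n_genes, grp0, dispersion = dispersion, seed = s)
    d0 <- test_deg(cpm_normalize(c0), grp0,
                   line_a = "mutant", line_b = "control")
    nfl <- sum(d0$significant)
    fdp <- if (nfl > 0) 1 else 0          # all-null: any discovery is false
    # (b) planted: one gene, two mutant lines against a common control
    grp1 <- rep(c("mutant_a", "mutant_b", "control"),
                each = n_reps_per_line)
    planted <- data.frame(gene = c(1L, 1L),
                          group = c("mutant_a", "mutant_b"),
                          fold = c(fold_a, fold_b), base_mean = 50)
    c1 <- simulate_counts(n_genes, grp1, planted = planted,
                          dispersion = dispersion, seed = s + 1L)
    norm1 <- cpm_normalize(c1)
    da <- test_deg(norm1[, grp1 != "mutant_b"], grp1[grp1 != "mutant_b"],
                   line_a = "mutant_a", line_b = "control")
    fb <- fold_change(norm1, grp1, "mutant_b", "control")
    data.frame(seed_index = r, fdp = fdp, n_flagged_null = nfl,
               planted_flagged = da$significant[1],
               fold_a_hat = da$fold_change[1], fold_b_hat = unname(fb[1]))
  })
  do.call(rbind, out)
}

#' Segregation-test calibration under a true 3:1 ratio
#'
#' Draws carrier counts from Binomial(n, 3/4) and records the fraction of
#' replicates in which the goodness-of-fit test does *not* reject at
#' `alpha` — the test's empirical coverage.
#'
#' @param n_reps Replicates.
#' @param seed Base seed.
#' @param n Population size per replicate.
#' @param alpha Test level.
#' @return List with `pass_rate` and the vector of p-values.
#' @export
segregation_calibration <- function(n_reps = 1000, seed = 1L, n = 508L,
                                    alpha = 0.05) {
  set.seed(.rep_seed(seed, 1L))
  carriers <- stats::rbinom(n_reps, n, 0.75)
  pvals <- vapply(carriers, function(k)
    chi_square_ratio(c(k, n - k), c(3, 1))$p_value, numeric(1))
  list(pass_rate = mean(pvals >= alpha), p_values = pvals)
}
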
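test_that("causal genotypes segregate 1:2:1 and carriers near 3/4", {
  g <- small_genome()
  pop <- simulate_f2(g, cross_config(n_f2 = 10000L, seed = 11L))
  freq <- tabulate(pop$causal_genotype + 1L, 3L) / pop$n
  se <- sqrt(c(.25 * .75, .5 * .5, .25 * .75) / pop$n)
  expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 3 * se))

  pop508 <- simulate_f2(g, cross_config(n_f2 = 508L, seed = 12L))
  carriers <- sum(pop508$causal_genotype >= 1L)
  # binomial(508, 0.75): mean 381, sd 9.76
  expect_true(abs(carriers - 381) < 4 * 9.76)
})

test_that("a 0-cM chromosome never recombines", {
  g <- genome_model(data.frame(name = "chr1", length_bp = 1e6,
                               length_cM = 0),
                    causal_locus = list(chrom = "chr1", pos = 5e5))
  pop <- simulate_f2(g, cross_config(n_f2 = 200L, seed = 5L))
  left <- genotype_at(pop, "chr1", 1)
  right <- genotype_at(pop, "chr1", 1e6)
  expect_identical(left, right)
  expect_true(all(lengths(pop$gametes$chr1$breaks) == 0L))
})

test_that("invalid genomes and configs are rejected", {
  expect_error(genome_model(data.frame(name = "c", length_bp = 0,
                                       length_cM = 10)),
               "lengths must be > 0")
  expect_error(genome_model(data.frame(name = "c", length_bp = 100,
                                       length_cM = 10),
                            causal_locus = list(chrom = "c", pos = 200)),
               "outside")
  expect_error(cross_config(noise_sd = -1), "noise_sd")
  expect_error(cross_config(dropout = 1.5), "probabilities")
})

test_that("noiseless phenotypes hit the class means and classify perfectly", {
  g <- small_genome()
  cfg <- cross_config(n_f2 = 300L, noise_sd = 0, seed = 21L)
  pop <- assign_phenotypes(simulate_f2(g, cfg))
  avg <- average_replicates(pop$phenotypes)
  m <- cfg$dominance
  for (cls in c("0", "1", "2")) {
    ids <- which(pop$causal_genotype == as.integer(cls))
    if (!length(ids)) next
    expect_equal(unname(as.matrix(avg[avg$id %in% ids, c("L", "a", "b")])),
                 matrix(m[cls, ], nrow = length(ids), ncol = 3,
                        byrow = TRUE))
  }
  # heterozygote midpoint is exactly equidistant -> cream; recovery is 100%
  truth <- c("white", "cream", "brown")[pop$causal_genotype + 1L]
  expect_identical(as.character(pop$group), truth)
})

test_that("bulks are disjoint within-group samples of the requested size", {
  g <- small_genome()
  pop <- assign_phenotypes(simulate_f2(g, cross_config(n_f2 = 508L,
                                                       seed = 31L)))
  b <- make_bulks(pop, "brown", "white", 50L)
  expect_length(b$brown, 50L)
  expect_length(b$white, 50L)
  expect_length(intersect(b$brown, b$white), 0L)
  expect_true(all(pop$group[b$brown] == "brown"))
  expect_true(all(pop$group[b$white] == "white"))
  empty <- make_bulks(pop, "brown", "white", 0L)
  expect_identical(lengths(empty), c(brown = 0L, white = 0L))
  expect_error(make_bulks(pop, "brown", "white", 200L), "fewer than")
})

test_that("same seed reproduces the simulation exactly", {
  g <- small_genome()
  cfg <- cross_config(n_f2 = 100L, seed = 77L)
  p1 <- assign_phenotypes(simulate_f2(g, cfg))
  p2 <- assign_phenotypes(simulate_f2(g, cfg))
  expect_identical(p1$causal_genotype, p2$causal_genotype)
  expect_identical(p1$phenotypes, p2$phenotypes)
  expect_identical(p1$gametes, p2$gametes)
})

test_that("noise-free bulk variant sets differ only near the causal locus", {
  # two chromosomes: one carries the locus, the other is unlinked
  g <- genome_model(data.frame(name = c("chr1", "chr2"),
                               length_bp = c(2e6, 2e6),
                               length_cM = c(50, 50)),
                    variant_density = 2e-4,
                    causal_locus = list(chrom = "chr1", pos = 1e6))
  unlinked_clean <- logical(20)
  causal_in_diff <- logical(20)
  for (r in 1:20) {
    cfg <- cross_config(n_f2 = 508L, bulk_size = 77L,
                        genotyping_error = 0, dropout = 0, seed = 100L + r)
    pop <- assign_phenotypes(simulate_f2(g, cfg))
    bulks <- make_bulks(pop)
    sites <- parental_variant_sites(g)
    # force a site at the causal position itself
    sites <- rbind(sites, data.frame(chrom = "chr1", pos = 1e6, ref = "A",
                                     alt = "T", class = "SNP"))
    bv <- simulate_bulk_variants(g, pop, bulks, cfg, sites)
    d <- subtract_shared_variants(bv[[1]], bv[[2]])
    unlinked_clean[r] <- !any(d$chrom == "chr2")
    causal_in_diff[r] <- any(d$chrom == "chr1" & d$pos == 1e6)
  }
  expect_true(all(causal_in_diff))
  expect_gte(mean(unlinked_clean), 0.99)
})

test_that("an empty bulk yields an empty variant set", {
  g <- small_genome(density = 1e-4)
  cfg <- cross_config(n_f2 = 50L, seed = 9L, genotyping_error = 0,
                      dropout = 0)
  pop <- assign_phenotypes(simulate_f2(g, cfg))
  bv <- simulate_bulk_variants(g, pop, list(none = integer(0)), cfg)
  expect_identical(nrow(bv$none), 0L)
})

test_that("simulated counts carry the planted fold and library structure", {
  grp <- rep(c("m", "c"), each = 10L)
  cnt <- simulate_counts(200L, grp,
                         planted = data.frame(gene = 1L, group = "m",
                                              fold = 179,
                                              base_mean = 1000),
                         dispersion = 0, seed = 2L, depth_sdlog = 0)
  ratio <- mean(cnt[1, grp == "m"]) / mean(cnt[1, grp == "c"])
  expect_lt(abs(ratio / 179 - 1), 0.1)
  # null genes share their expected mean across groups
  null_ratio <- rowMeans(cnt[-1, grp == "m"]) / rowMeans(cnt[-1, grp == "c"])
  expect_lt(abs(median(null_ratio) - 1), 0.25)
  expect_error(simulate_counts(10L, grp,
                               planted = data.frame(gene = 1L, group = "m",
                                                    fold = 0)),
               "fold_change")
})
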
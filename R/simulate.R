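#' Simulate an F2 population from a biparental cross
#'
#' Each F2 individual receives two gametes, each a recombinant mosaic of the
#' two parental genomes produced by a heterozygous F1. Crossover counts per
#' gamete and chromosome are Poisson with mean `length_cM / 100` (Haldane,
#' no interference); crossover positions are uniform on the physical map.
#' The genotype at any site is derivable from the stored breakpoints, so the
#' same simulated meioses drive phenotypes, bulk variant sets and marker
#' genotyping consistently.
#'
#' @param genome A [genome_model()].
#' @param config A [cross_config()]; `config$seed`, when non-NULL, seeds the
#'   generator so reruns are byte-identical.
#' @return An object of class `f2_population` with elements `genome`,
#'   `config`, `n`, per-chromosome gamete mosaics, and `causal_genotype`
#'   (0/1/2 copies of the mutant allele per individual).
#' @export
simulate_f2 <- function(genome, config) {
  stopifnot(inherits(genome, "genome_model"), inherits(config, "cross_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_f2
  chrs <- genome$chromosomes
  gametes <- vector("list", nrow(chrs))
  names(gametes) <- chrs$name
  for (ci in seq_len(nrow(chrs))) {
    len <- chrs$length_bp[ci]
    ng <- 2L * n
    nx <- stats::rpois(ng, chrs$length_cM[ci] / 100)
    pos <- stats::runif(sum(nx), 0, len)
    breaks <- split(pos, factor(rep.int(seq_len(ng), nx), levels = seq_len(ng)))
    breaks <- lapply(breaks, sort)
    # column g (1/2) of `start` holds the parental origin of gamete g at
    # position 0; gamete (i, g) is stored at flat index (g - 1) * n + i
    start <- matrix(sample(0:1, ng, replace = TRUE), ncol = 2L)
    gametes[[ci]] <- list(start = start, breaks = breaks)
  }
  pop <- structure(list(genome = genome, config = config, n = n,
                        gametes = gametes),
                   class = "f2_population")
  if (!is.null(genome$causal_locus))
    pop$causal_genotype <- genotype_at(pop, genome$causal_locus$chrom,
                                       genome$causal_locus$pos)
  pop
}

# parental origin (0 = white parent, 1 = mutant parent) of one gamete at a
# sorted-or-not vector of positions
.gamete_alleles <- function(gam, n, ind, g, positions) {
  idx <- (g - 1L) * n + ind
  b <- gam$breaks[[idx]]
  s <- gam$start[ind, g]
  if (length(b) == 0L) return(rep.int(s, length(positions)))
  (s + findInterval(positions, b)) %% 2L
}

#' Causal-allele dosage of every individual at given positions
#'
#' @param pop An `f2_population`.
#' @param chrom Chromosome name.
#' @param pos Numeric vector of positions (bp).
#' @return For a single position, an integer vector (one 0/1/2 dosage per
#'   individual); for several positions, a `length(pos)` x `n` matrix.
#' @export
genotype_at <- function(pop, chrom, pos) {
  gam <- pop$gametes[[chrom]]
  if (is.null(gam)) stop("unknown chromosome: ", chrom)
  vapply(seq_len(pop$n), function(i) {
    .gamete_alleles(gam, pop$n, i, 1L, pos) +
      .gamete_alleles(gam, pop$n, i, 2L, pos)
  }, numeric(length(pos)))
}

#' Assign CIELab phenotypes and color groups to an F2 population
#'
#' Each individual's color is drawn from a Gaussian centered on the mean of
#' its causal genotype class (incomplete dominance: the heterozygote mean is
#' the midpoint of the parental means by default); `n_replicates` technical
#' replicates are emitted per individual, averaged, and classified against
#' the parental reference colors.
#'
#' @param pop An `f2_population` with causal genotypes.
#' @param config A [cross_config()]; defaults to the one stored in `pop`.
#' @param n_replicates Technical replicates per individual.
#' @return `pop` with added `phenotypes` (data.frame `id`, `replicate`, `L`,
#'   `a`, `b`) and `group` (factor brown/cream/white per individual).
#' @export
assign_phenotypes <- function(pop, config = pop$config, n_replicates = 3L) {
  stopifnot(inherits(pop, "f2_population"), !is.null(pop$causal_genotype))
  if (config$noise_sd < 0) stop("noise_sd must be >= 0")
  means <- config$dominance
  g <- pop$causal_genotype
  reps <- as.integer(n_replicates)
  mu <- means[as.character(rep(g, each = reps)), , drop = FALSE]
  vals <- mu + matrix(stats::rnorm(length(mu), 0, config$noise_sd),
                      nrow = nrow(mu))
  ph <- data.frame(id = rep(seq_len(pop$n), each = reps),
                   replicate = rep.int(seq_len(reps), pop$n),
                   L = pmin(pmax(vals[, 1], 0), 100),
                   a = vals[, 2], b = vals[, 3])
  avg <- average_replicates(ph)
  cls <- classify_colors(avg,
                         brown_ref = means["2", ], white_ref = means["0", ],
                         cream_band = config$cream_band)
  pop$phenotypes <- ph
  pop$group <- cls$group[match(seq_len(pop$n), cls$id)]
  pop
}

#' Draw two disjoint phenotype bulks
#'
#' Samples `bulk_size` individuals without replacement within each named
#' phenotype group (membership is random within group).
#'
#' @param pop An `f2_population` with assigned groups.
#' @param group_a,group_b Phenotype group labels of the two bulks.
#' @param bulk_size Individuals per bulk.
#' @return Named list of two sorted integer id vectors.
#' @export
make_bulks <- function(pop, group_a = "brown", group_b = "white",
                       bulk_size = pop$config$bulk_size) {
  stopifnot(!is.null(pop$group))
  bulk_size <- as.integer(bulk_size)
  out <- lapply(c(group_a, group_b), function(gr) {
    ids <- which(pop$group == gr)
    if (length(ids) < bulk_size)
      stop(sprintf("group '%s' has %d individuals, fewer than bulk_size %d",
                   gr, length(ids), bulk_size))
    if (bulk_size == 0L) return(integer(0))
    sort(sample(ids, bulk_size))
  })
  names(out) <- c(group_a, group_b)
  out
}
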
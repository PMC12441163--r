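#' Genome model for cross simulation
#'
#' Describes the chromosomes of the simulated genome, the expected density of
#' fixed sequence differences between the two parental lines, and the position
#' of the causal (fiber-color) locus.
#'
#' @param chromosomes data.frame with columns `name`, `length_bp` (physical
#'   length, bp) and `length_cM` (genetic map length, centiMorgans).
#' @param variant_density Expected parental-difference sites per bp.
#' @param causal_locus `list(chrom =, pos =)` giving the causal locus, or
#'   `NULL` for a neutral genome.
#' @return An object of class `genome_model`.
#' @examples
#' g <- genome_model(data.frame(name = "chr1", length_bp = 1e6, length_cM = 50),
#'                   variant_density = 1e-4,
#'                   causal_locus = list(chrom = "chr1", pos = 5e5))
#' @export
genome_model <- function(chromosomes, variant_density = 1e-3,
                         causal_locus = NULL) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length_bp", "length_cM") %in% names(chromosomes)))
  chromosomes$name <- as.character(chromosomes$name)
  if (nrow(chromosomes) == 0L)
    stop("genome must have at least one chromosome")
  if (any(chromosomes$length_bp <= 0))
    stop("chromosome physical lengths must be > 0")
  if (any(chromosomes$length_cM < 0))
    stop("genetic map lengths must be >= 0")
  if (anyDuplicated(chromosomes$name))
    stop("duplicated chromosome names")
  if (!is.finite(variant_density) || variant_density <= 0)
    stop("variant_density must be > 0")
  if (!is.null(causal_locus)) {
    i <- match(causal_locus$chrom, chromosomes$name)
    if (is.na(i))
      stop("causal locus chromosome not present in the genome")
    if (causal_locus$pos < 1 || causal_locus$pos > chromosomes$length_bp[i])
      stop("causal locus position outside its chromosome")
  }
  structure(list(chromosomes = chromosomes,
                 variant_density = variant_density,
                 causal_locus = causal_locus),
            class = "genome_model")
}

#' Default desk-scale genome
#'
#' Five 50-Mb chromosomes of 100 cM each (about 2 cM/Mb), one parental
#' difference per kb, and the causal locus in the middle of the fifth 5-Mb
#' window of chromosome A07 — a configurable stand-in for the 26-chromosome
#' tetraploid cotton genome.
#'
#' @return A `genome_model`.
#' @export
default_genome <- function() {
  genome_model(
    data.frame(name = c("A05", "A06", "A07", "A08", "A09"),
               length_bp = 50e6, length_cM = 100),
    variant_density = 1e-3,
    causal_locus = list(chrom = "A07", pos = 22.5e6)
  )
}

#' Parental phenotype class means in CIELab space
#'
#' Row "2" is the brown parent mean (L*, a*, b*), row "0" the white parent,
#' and row "1" the heterozygote, taken as the arithmetic midpoint under
#' incomplete dominance.
#'
#' @param brown,white Length-3 numeric (L, a, b) class means.
#' @return A 3 x 3 numeric matrix with rownames "0", "1", "2".
#' @export
phenotype_means <- function(brown = c(67.75, 11.58, 30.33),
                            white = c(96.49, 0.64, 10.25)) {
  m <- rbind("0" = white, "1" = (brown + white) / 2, "2" = brown)
  colnames(m) <- c("L", "a", "b")
  m
}

#' Configuration of the F2 cross and bulk design
#'
#' @param n_f2 Number of F2 individuals.
#' @param bulk_size Individuals per phenotype bulk.
#' @param dominance 3 x 3 matrix of (L, a, b) phenotype means for causal
#'   genotypes 0/1/2 (rows named "0", "1", "2"); see [phenotype_means()].
#' @param noise_sd Per-channel Gaussian sd of a single technical replicate.
#' @param cream_band Half-band (in Delta-E units) of the intermediate "cream"
#'   class used when classifying colors.
#' @param genotyping_error Probability that a bulk-level variant call is
#'   flipped.
#' @param dropout Probability that a truly present variant is missed in a
#'   bulk.
#' @param seed RNG seed applied at the start of [simulate_f2()]; `NULL` uses
#'   the current RNG state.
#' @return An object of class `cross_config`.
#' @export
cross_config <- function(n_f2 = 508L, bulk_size = 77L,
                         dominance = phenotype_means(),
                         noise_sd = 1.0, cream_band = 5,
                         genotyping_error = 0.02, dropout = 0.05,
                         seed = NULL) {
  stopifnot(n_f2 >= 1, bulk_size >= 0)
  if (!is.matrix(dominance) || !all(c("0", "1", "2") %in% rownames(dominance)))
    stop("dominance must be a matrix with rows named '0', '1', '2'")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  for (p in c(genotyping_error, dropout))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  structure(list(n_f2 = as.integer(n_f2), bulk_size = as.integer(bulk_size),
                 dominance = dominance, noise_sd = noise_sd,
                 cream_band = cream_band,
                 genotyping_error = genotyping_error, dropout = dropout,
                 seed = seed),
            class = "cross_config")
}
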
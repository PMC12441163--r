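.BASES <- c("A", "C", "G", "T")

#' Instantiate fixed parental-difference sites along the genome
#'
#' Sites occur as a Poisson process at `genome$variant_density` per bp; each
#' carries a REF/ALT pair (a fraction are short anchored insertions, the rest
#' SNPs). Both bulks must be generated against the same site list.
#'
#' @param genome A [genome_model()].
#' @param indel_fraction Fraction of sites that are indels.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `class`.
#' @export
parental_variant_sites <- function(genome, indel_fraction = 0.1) {
  chrs <- genome$chromosomes
  per_chrom <- lapply(seq_len(nrow(chrs)), function(ci) {
    len <- chrs$length_bp[ci]
    n <- stats::rpois(1L, len * genome$variant_density)
    n <- min(n, len)
    if (n == 0L)
      return(data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        class = character()))
    pos <- sort(sample.int(len, n))
    ref <- sample(.BASES, n, replace = TRUE)
    ref_i <- match(ref, .BASES)
    # SNP alt: a uniformly chosen base different from ref
    alt <- .BASES[1L + (ref_i - 1L + sample.int(3L, n, replace = TRUE)) %% 4L]
    cls <- rep("SNP", n)
    is_ind <- stats::runif(n) < indel_fraction
    if (any(is_ind)) {
      k <- sum(is_ind)
      ins3 <- paste0(sample(.BASES, k, TRUE), sample(.BASES, k, TRUE),
                     sample(.BASES, k, TRUE))
      alt[is_ind] <- paste0(ref[is_ind],
                            substring(ins3, 1L, sample.int(3L, k, TRUE)))
      cls[is_ind] <- "indel"
    }
    data.frame(chrom = chrs$name[ci], pos = pos, ref = ref, alt = alt,
               class = cls)
  })
  out <- do.call(rbind, per_chrom)
  rownames(out) <- NULL
  out
}

#' Simulate the called variant set of each bulk
#'
#' A mutant-parent variant is called present in a bulk iff at least one bulk
#' member carries the mutant-parent allele at that site (presence/absence at
#' the pooled level, not allele frequency). The truth is then perturbed:
#' present calls are dropped with probability `config$dropout`, and every
#' call is flipped with probability `config$genotyping_error`. Near the
#' causal locus the white bulk is depleted of mutant-parent alleles, with
#' depletion decaying with genetic distance — the signal the genome scan
#' detects.
#'
#' @param genome A [genome_model()].
#' @param pop An `f2_population`.
#' @param bulks Named list of individual-id vectors (see [make_bulks()]).
#' @param config A [cross_config()].
#' @param sites Site list from [parental_variant_sites()]; generated if
#'   `NULL`. Pass the same object for related bulk sets.
#' @return Named list of variant data.frames (`chrom`, `pos`, `ref`, `alt`,
#'   `class`), one per bulk.
#' @export
simulate_bulk_variants <- function(genome, pop, bulks, config = pop$config,
                                   sites = NULL) {
  if (is.null(sites)) sites <- parental_variant_sites(genome)
  chroms <- unique(sites$chrom)
  lapply(bulks, function(ids) {
    present <- logical(nrow(sites))
    if (length(ids) > 0L) {
      for (chrom in chroms) {
        rows <- which(sites$chrom == chrom)
        posv <- sites$pos[rows]
        gam <- pop$gametes[[chrom]]
        acc <- logical(length(rows))
        for (i in ids) {
          al <- .gamete_alleles(gam, pop$n, i, 1L, posv) +
            .gamete_alleles(gam, pop$n, i, 2L, posv)
          acc <- acc | (al > 0L)
          if (all(acc)) break
        }
        present[rows] <- acc
      }
    }
    obs <- present
    if (any(obs) && config$dropout > 0)
      obs[obs] <- stats::runif(sum(obs)) >= config$dropout
    if (config$genotyping_error > 0)
      obs <- xor(obs, stats::runif(length(obs)) < config$genotyping_error)
    out <- sites[obs, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Simulate a negative-binomial count matrix with planted effects
#'
#' Gene base means are log-normal; per-sample sequencing depth factors are
#' log-normal (the library-size model); counts are negative binomial with the
#' given dispersion (`dispersion = 0` gives Poisson). Planted genes have
#' their mean multiplied by `fold` in the named group.
#'
#' @param n_genes Number of genes.
#' @param groups Character vector of line labels, one per sample (>= 2
#'   replicates per line are required downstream).
#' @param planted Optional data.frame with columns `gene` (index), `group`,
#'   `fold` and optionally `base_mean`.
#' @param dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param seed Optional RNG seed.
#' @param base_meanlog,base_sdlog Log-normal parameters of gene base means.
#' @param depth_sdlog Log-normal sd of per-sample depth factors.
#' @return Integer matrix genes x samples with dim names; attribute
#'   `depth_factors` records the simulated depths.
#' @export
simulate_counts <- function(n_genes, groups, planted = NULL,
                            dispersion = 0.05, seed = NULL,
                            base_meanlog = log(100), base_sdlog = 1,
                            depth_sdlog = 0.2) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(planted)) {
    stopifnot(all(c("gene", "group", "fold") %in% names(planted)))
    if (any(planted$fold <= 0)) stop("fold_change must be > 0")
    if (!all(planted$group %in% groups))
      stop("planted group not among sample groups")
  }
  n_s <- length(groups)
  base <- stats::rlnorm(n_genes, base_meanlog, base_sdlog)
  if (!is.null(planted) && !is.null(planted$base_mean)) {
    has <- !is.na(planted$base_mean)
    base[planted$gene[has]] <- planted$base_mean[has]
  }
  depth <- stats::rlnorm(n_s, 0, depth_sdlog)
  mu <- outer(base, depth)
  if (!is.null(planted)) {
    for (r in seq_len(nrow(planted))) {
      cols <- which(groups == planted$group[r])
      mu[planted$gene[r], cols] <- mu[planted$gene[r], cols] * planted$fold[r]
    }
  }
  counts <- if (dispersion <= 0) {
    stats::rpois(length(mu), mu)
  } else {
    stats::rnbinom(length(mu), size = 1 / dispersion, mu = mu)
  }
  m <- matrix(counts, nrow = n_genes,
              dimnames = list(sprintf("gene_%05d", seq_len(n_genes)),
                              make.unique(paste0(groups, "_rep"))))
  attr(m, "depth_factors") <- depth
  m
}
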
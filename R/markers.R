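#' Define a dominant marker panel
#'
#' Markers are mutant-specific PCR assays: they call positive (P) in any
#' carrier of the mutant allele (heterozygous or homozygous), negative (N)
#' otherwise, so recombination fractions are not estimable — only
#' concordance with the phenotype.
#'
#' @param name Unique marker names.
#' @param chrom Chromosome per marker.
#' @param pos Position (bp) per marker.
#' @return data.frame `name`, `chrom`, `pos`.
#' @export
marker_panel <- function(name, chrom, pos) {
  if (length(chrom) == 1L) chrom <- rep(chrom, length(name))
  stopifnot(length(name) == length(chrom), length(name) == length(pos))
  if (anyDuplicated(name)) stop("marker names must be unique")
  data.frame(name = as.character(name), chrom = as.character(chrom),
             pos = as.numeric(pos))
}

#' Default 11-marker panel around the causal region
#'
#' Spans roughly the peak window of the default genome with increasing
#' density toward the locus; the closest marker sits 2.9 kb from it,
#' mirroring the distance of the reported fully co-segregating assay from
#' its candidate gene.
#'
#' @param genome A [genome_model()] with a causal locus.
#' @return A [marker_panel()].
#' @export
default_marker_panel <- function(genome = default_genome()) {
  cl <- genome$causal_locus
  if (is.null(cl)) stop("genome has no causal locus")
  off <- c(-2.5e6, -1.5e6, -0.7e6, -0.3e6, -0.15e6, -0.05e6,
           2900, 0.15e6, 0.5e6, 1.1e6, 2.0e6)
  marker_panel(sprintf("BF%03d", seq_along(off)), cl$chrom, cl$pos + off)
}

#' Genotype dominant markers across an F2 population
#'
#' @param pop An `f2_population`.
#' @param panel A [marker_panel()].
#' @param error_rate Per-call probability of flipping P/N.
#' @return data.frame `individual`, `marker`, `call` (P/N).
#' @export
genotype_markers <- function(pop, panel, error_rate = 0) {
  stopifnot(error_rate >= 0, error_rate <= 1)
  calls <- lapply(seq_len(nrow(panel)), function(mi) {
    g <- genotype_at(pop, panel$chrom[mi], panel$pos[mi])
    call <- ifelse(g >= 1L, "P", "N")
    if (error_rate > 0) {
      flip <- stats::runif(length(call)) < error_rate
      call[flip] <- ifelse(call[flip] == "P", "N", "P")
    }
    data.frame(individual = seq_len(pop$n), marker = panel$name[mi],
               call = call)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Count phenotype-discordant individuals per marker
#'
#' For a dominant mutant-specific marker, a recombinant is an individual
#' calling P with a white phenotype, or N with a brown or cream phenotype
#' (cream individuals are carriers under incomplete dominance). Missing
#' calls are excluded.
#'
#' @param calls data.frame `individual`, `marker`, `call` (P/N/NA).
#' @param groups Phenotype group per individual: either a data.frame
#'   (`id`, `group`) or a vector indexed by individual id.
#' @return data.frame `marker`, `recombinants`, `n_informative`.
#' @export
score_recombinants <- function(calls, groups) {
  if (is.data.frame(groups)) {
    grp <- as.character(groups$group)[match(calls$individual, groups$id)]
  } else {
    grp <- as.character(groups)[calls$individual]
  }
  has_call <- !is.na(calls$call) & calls$call %in% c("P", "N")
  if (any(has_call & is.na(grp)))
    stop("individual with a marker call but no phenotype group")
  carrier <- grp %in% c("brown", "cream")
  rec <- (calls$call == "P" & grp == "white") |
    (calls$call == "N" & carrier)
  agg <- stats::aggregate(cbind(recombinants = rec[has_call],
                                n_informative = rep(1L, sum(has_call))),
                          by = list(marker = calls$marker[has_call]), sum)
  agg
}

#' Locate the co-segregation interval of a marker panel
#'
#' Markers with zero recombinants form the co-segregating set; the flanking
#' markers are the nearest markers on each side of that set with at least
#' one recombinant, and the interval span is the distance between the
#' flanks. With no zero-recombinant marker the minimum-recombinant marker(s)
#' are reported and the interval is flagged open; missing flanks fall back
#' to the outermost panel markers (also flagged open).
#'
#' @param panel A [marker_panel()]; all markers must share a chromosome.
#' @param recombinants Output of [score_recombinants()].
#' @return Object of class `interval_result`.
#' @export
find_interval <- function(panel, recombinants) {
  if (length(unique(panel$chrom)) != 1L)
    stop("interval mapping requires markers on a single chromosome")
  m <- merge(panel, recombinants, by.x = "name", by.y = "marker")
  if (nrow(m) != nrow(panel)) stop("recombinant counts missing for some markers")
  m <- m[order(m$pos), , drop = FALSE]
  rownames(m) <- NULL
  zero <- m$recombinants == 0
  open <- FALSE
  if (any(zero)) {
    co <- m$name[zero]
    lo <- min(m$pos[zero]); hi <- max(m$pos[zero])
  } else {
    open <- TRUE
    mn <- min(m$recombinants)
    co <- m$name[m$recombinants == mn]   # ties: report all tied markers
    lo <- min(m$pos[m$recombinants == mn])
    hi <- max(m$pos[m$recombinants == mn])
  }
  left_ok <- m$pos < lo & m$recombinants >= 1
  right_ok <- m$pos > hi & m$recombinants >= 1
  if (any(left_ok)) {
    left <- m[which(left_ok)[which.max(m$pos[left_ok])], ]
  } else {
    left <- m[1L, ]; open <- TRUE
  }
  if (any(right_ok)) {
    right <- m[which(right_ok)[which.min(m$pos[right_ok])], ]
  } else {
    right <- m[nrow(m), ]; open <- TRUE
  }
  structure(list(co_segregating = co,
                 left_marker = left$name, left_pos = left$pos,
                 right_marker = right$name, right_pos = right$pos,
                 span = right$pos - left$pos, open = open,
                 per_marker = m),
            class = "interval_result")
}

#' @export
print.interval_result <- function(x, ...) {
  cat(sprintf("Co-segregating marker(s): %s\n",
              paste(x$co_segregating, collapse = ", ")))
  cat(sprintf("Interval%s: %s (%s bp) .. %s (%s bp), span %s bp\n",
              if (x$open) " (open)" else "",
              x$left_marker, format(x$left_pos, big.mark = ",", scientific = FALSE),
              x$right_marker, format(x$right_pos, big.mark = ",", scientific = FALSE),
              format(x$span, big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' Write the interval summary and a P/N genotype matrix
#'
#' The matrix view (individuals in rows, markers in columns, entries P/N,
#' phenotype group appended) mirrors how co-segregation panels are usually
#' presented.
#'
#' @param interval An `interval_result`.
#' @param calls,groups As in [score_recombinants()].
#' @param interval_file,matrix_file Output paths (TSV).
#' @export
write_interval_tsv <- function(interval, calls, groups,
                               interval_file, matrix_file = NULL) {
  pm <- interval$per_marker
  pm$co_segregating <- pm$name %in% interval$co_segregating
  utils::write.table(pm, interval_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(matrix_file)) {
    wide <- stats::reshape(calls, idvar = "individual", timevar = "marker",
                           direction = "wide")
    names(wide) <- sub("^call\\.", "", names(wide))
    if (is.data.frame(groups)) {
      wide$group <- as.character(groups$group)[match(wide$individual,
                                                     groups$id)]
    } else {
      wide$group <- as.character(groups)[wide$individual]
    }
    utils::write.table(wide, matrix_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(interval_file)
}
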
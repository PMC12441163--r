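.variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

#' Subtract variants shared by the two bulks
#'
#' Returns the symmetric difference of the two bulk variant sets under the
#' identity key (chrom, pos, ref, alt) — genotype/zygosity is deliberately
#' not part of the key. Each retained variant is tagged with its bulk of
#' origin. Identical variants present in both bulks carry no mapping
#' information and are removed.
#'
#' @param bulk_a,bulk_b Variant data.frames (`chrom`, `pos`, `ref`, `alt`,
#'   ...). If both carry a `contigs` attribute (as VCF-derived sets do),
#'   their coordinate systems are cross-checked.
#' @param names Length-2 character, origin labels for the output.
#' @return data.frame of bulk-differential variants with an `origin` column,
#'   ordered by chromosome and position.
#' @export
subtract_shared_variants <- function(bulk_a, bulk_b,
                                     names = c("bulk_a", "bulk_b")) {
  ca <- attr(bulk_a, "contigs"); cb <- attr(bulk_b, "contigs")
  if (!is.null(ca) && !is.null(cb)) {
    bad <- c(setdiff(unique(bulk_a$chrom), cb),
             setdiff(unique(bulk_b$chrom), ca))
    if (length(bad))
      stop("coordinate-system mismatch: contig(s) ",
           paste(unique(bad), collapse = ", "),
           " absent from the other set's header")
  }
  ka <- .variant_key(bulk_a); kb <- .variant_key(bulk_b)
  only_a <- bulk_a[!(ka %in% kb), , drop = FALSE]
  only_b <- bulk_b[!(kb %in% ka), , drop = FALSE]
  if (nrow(only_a)) only_a$origin <- names[1]
  else only_a$origin <- character(0)
  if (nrow(only_b)) only_b$origin <- names[2]
  else only_b$origin <- character(0)
  out <- rbind(only_a, only_b)
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count variants in fixed-width genomic windows
#'
#' Windows are 0-based half-open `[0, w), [w, 2w), ...` per chromosome; a
#' variant at 1-based position p falls in window `floor((p - 1) / w)`. Every
#' window of every genome chromosome is emitted, including empty ones, so
#' window counts sum to the number of variants.
#'
#' @param variants Variant data.frame (`chrom`, `pos`).
#' @param genome A [genome_model()] supplying chromosome lengths.
#' @param bin_width Window width in bp (default 5 Mb).
#' @return data.frame `chrom`, `start`, `end` (0-based half-open), `count`.
#' @export
bin_counts <- function(variants, genome, bin_width = 5e6) {
  stopifnot(bin_width > 0)
  chrs <- genome$chromosomes
  unknown <- setdiff(unique(variants$chrom), chrs$name)
  if (length(unknown))
    stop("variant on chromosome absent from genome: ",
         paste(unknown, collapse = ", "))
  out <- lapply(seq_len(nrow(chrs)), function(ci) {
    len <- chrs$length_bp[ci]
    nb <- as.integer(ceiling(len / bin_width))
    pos <- variants$pos[variants$chrom == chrs$name[ci]]
    if (any(pos < 1 | pos > len))
      stop("variant position outside chromosome ", chrs$name[ci])
    idx <- as.integer((pos - 1) %/% bin_width) + 1L
    starts <- (seq_len(nb) - 1) * bin_width
    data.frame(chrom = chrs$name[ci], start = starts,
               end = pmin(starts + bin_width, len),
               count = tabulate(idx, nb))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Locate the peak window of a genome scan
#'
#' The peak is the window with the global maximum count (ties broken by
#' lowest chromosome name, then lowest start). The reported region is the
#' maximal run of adjacent windows on the peak chromosome whose counts are
#' at least `extend_fraction` times the peak count.
#'
#' @param bins Output of [bin_counts()].
#' @param extend_fraction Fraction of the peak count a window must reach to
#'   be absorbed into the region, in `[0, 1]`.
#' @return Object of class `peak_region`; when all windows are empty the
#'   result is flagged with `no_peak = TRUE`.
#' @export
detect_peak <- function(bins, extend_fraction = 0.5) {
  stopifnot(nrow(bins) >= 1L,
            extend_fraction >= 0, extend_fraction <= 1)
  if (all(bins$count == 0))
    return(structure(list(no_peak = TRUE), class = "peak_region"))
  top <- bins[order(-bins$count, bins$chrom, bins$start), ][1, ]
  cb <- bins[bins$chrom == top$chrom, , drop = FALSE]
  cb <- cb[order(cb$start), , drop = FALSE]
  pk <- which(cb$start == top$start)
  thr <- extend_fraction * top$count
  l <- pk; r <- pk
  while (l > 1L && cb$count[l - 1L] >= thr) l <- l - 1L
  while (r < nrow(cb) && cb$count[r + 1L] >= thr) r <- r + 1L
  structure(list(no_peak = FALSE, chrom = top$chrom,
                 start = cb$start[l], end = cb$end[r],
                 peak_count = top$count,
                 windows = cb[l:r, , drop = FALSE]),
            class = "peak_region")
}

#' @export
print.peak_region <- function(x, ...) {
  if (isTRUE(x$no_peak)) {
    cat("No peak: all windows empty\n")
    return(invisible(x))
  }
  # user-facing coordinates are 1-based inclusive
  cat(sprintf("Peak region %s:%s-%s (%d window%s), peak count %d\n",
              x$chrom, format(x$start + 1, big.mark = ",", scientific = FALSE),
              format(x$end, big.mark = ",", scientific = FALSE), nrow(x$windows),
              if (nrow(x$windows) == 1) "" else "s", x$peak_count))
  invisible(x)
}
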
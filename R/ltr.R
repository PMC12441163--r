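#' Random nucleotide sequence
#'
#' @param n Length in bp.
#' @param seed Optional RNG seed.
#' @return A character string over A/C/G/T.
#' @export
random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

.seq_chr <- function(x) {
  if (inherits(x, "DNAString") || inherits(x, "DNAStringSet"))
    x <- as.character(x)
  toupper(as.character(x)[1])
}

# all k-mers of s with their start positions, N-containing ones dropped
.kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(list(kmer = character(0), pos = integer(0)))
  pos <- seq_len(n - k + 1L)
  km <- substring(s, pos, pos + k - 1L)
  keep <- !grepl("N", km, fixed = TRUE)
  list(kmer = km[keep], pos = pos[keep])
}

# exact seed pairs (i < j) within one sequence, separated by >= min_sep
.self_seed_pairs <- function(s, k, min_sep) {
  km <- .kmers(s, k)
  grp <- split(km$pos, km$kmer)
  grp <- grp[lengths(grp) >= 2L]
  if (!length(grp))
    return(data.frame(i = integer(0), j = integer(0)))
  ij <- do.call(rbind, lapply(grp, function(p) {
    if (length(p) == 2L) matrix(p, nrow = 1L) else t(utils::combn(p, 2L))
  }))
  ok <- (ij[, 2] - ij[, 1]) >= min_sep
  data.frame(i = ij[ok, 1], j = ij[ok, 2])
}

# exact seed pairs between a query and a subject sequence
.cross_seed_pairs <- function(query, subject, k) {
  kq <- .kmers(query, k)
  ks <- .kmers(subject, k)
  if (!length(kq$pos) || !length(ks$pos))
    return(data.frame(i = integer(0), j = integer(0)))
  qtab <- split(kq$pos, kq$kmer)
  hit <- ks$kmer %in% names(qtab)
  if (!any(hit)) return(data.frame(i = integer(0), j = integer(0)))
  js <- ks$pos[hit]
  qs <- qtab[ks$kmer[hit]]
  data.frame(i = unlist(qs, use.names = FALSE),
             j = rep.int(js, lengths(qs)))
}

# Greedy colinear chaining of seed pairs within a diagonal band: a seed may
# extend a chain when both coordinates advance and its diagonal drifts by at
# most `band` from the chain's last seed. Returns the chain with the widest
# combined span, or NULL.
.chain_seeds <- function(pairs, band = 50) {
  np <- nrow(pairs)
  if (np == 0L) return(NULL)
  ord <- order(pairs$i, pairs$j)
  i <- pairs$i[ord]; j <- pairs$j[ord]
  last_i <- integer(0); last_j <- integer(0)
  min_i <- integer(0); min_j <- integer(0)
  sizes <- integer(0)
  chain_of <- integer(np)
  for (s in seq_len(np)) {
    d <- j[s] - i[s]
    cand <- which(last_i < i[s] & last_j < j[s] &
                    abs((last_j - last_i) - d) <= band)
    if (length(cand)) {
      cid <- cand[which.max(sizes[cand])]
      last_i[cid] <- i[s]; last_j[cid] <- j[s]
      sizes[cid] <- sizes[cid] + 1L
    } else {
      cid <- length(sizes) + 1L
      last_i[cid] <- i[s]; last_j[cid] <- j[s]
      min_i[cid] <- i[s]; min_j[cid] <- j[s]
      sizes[cid] <- 1L
    }
    chain_of[s] <- cid
  }
  span <- (last_i - min_i) + (last_j - min_j)
  best <- which.max(span)
  list(min_i = min_i[best], max_i = last_i[best],
       min_j = min_j[best], max_j = last_j[best],
       n_seeds = sizes[best])
}

# Percent-identity of two candidate repeat copies: exact match short-circuits;
# otherwise a global alignment with match +1, mismatch -2, gap -3.
.align_identity <- function(x, y) {
  if (identical(x, y)) return(1.0)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(x),
                                       Biostrings::DNAString(y),
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 3,
                                       type = "global")
  Biostrings::pid(aln, type = "PID1") / 100
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Annotate long-terminal-repeat structure in a sequence
#'
#' Finds the highest-scoring pair of similar subsequences separated by at
#' least `min_ltr` bp via exact k-mer seeding and banded colinear chaining,
#' then reports the 5' LTR, internal region and 3' LTR lengths, the LTR pair
#' identity (global alignment), and any target-site duplication flanking the
#' element.
#'
#' @param seq Sequence (character or `DNAString`).
#' @param min_ltr Minimum LTR length (bp).
#' @param min_identity Minimum LTR-pair identity to accept.
#' @param k Seed k-mer length.
#' @param band Diagonal drift tolerated while chaining (absorbs small indels
#'   between the two LTR copies).
#' @param tsd_range Length range (bp) of a target-site duplication to look
#'   for immediately outside the element.
#' @return An object of class `ltr_annotation`, or `NULL` when no repeat
#'   pair meets the thresholds.
#' @export
annotate_ltr <- function(seq, min_ltr = 500, min_identity = 0.8,
                         k = 15, band = 50, tsd_range = c(4, 6)) {
  s <- .seq_chr(seq)
  if (nchar(s) < 2 * min_ltr)
    stop("sequence shorter than twice min_ltr")
  pairs <- .self_seed_pairs(s, k, min_sep = min_ltr)
  ch <- .chain_seeds(pairs, band)
  if (is.null(ch)) return(NULL)
  i_end <- ch$max_i + k - 1L
  if (i_end >= ch$min_j) {
    # chains overlapping into the second copy: trim the 5' copy back
    i_end <- ch$min_j - 1L
    if (i_end - ch$min_i + 1L < min_ltr) return(NULL)
  }
  j_end <- ch$max_j + k - 1L
  l5 <- i_end - ch$min_i + 1L
  l3 <- j_end - ch$min_j + 1L
  internal <- ch$min_j - i_end - 1L
  if (l5 < min_ltr || l3 < min_ltr) return(NULL)
  ltr5 <- substr(s, ch$min_i, i_end)
  ltr3 <- substr(s, ch$min_j, j_end)
  ident <- .align_identity(ltr5, ltr3)
  if (ident < min_identity) return(NULL)
  tsd <- NA_character_
  for (t in seq(tsd_range[2], tsd_range[1])) {
    if (ch$min_i - t < 1L || j_end + t > nchar(s)) next
    before <- substr(s, ch$min_i - t, ch$min_i - 1L)
    after <- substr(s, j_end + 1L, j_end + t)
    if (identical(before, after) && !grepl("N", before, fixed = TRUE)) {
      tsd <- before
      break
    }
  }
  structure(list(start = ch$min_i, end = j_end,
                 ltr5_length = l5, ltr3_length = l3,
                 internal_length = internal,
                 identity = ident, tsd = tsd,
                 n_seeds = ch$n_seeds),
            class = "ltr_annotation")
}

#' @export
print.ltr_annotation <- function(x, ...) {
  cat(sprintf(
    "LTR element %d-%d: 5'LTR %d bp | internal %d bp | 3'LTR %d bp; identity %.4f%s\n",
    x$start, x$end, x$ltr5_length, x$internal_length, x$ltr3_length,
    x$identity,
    if (is.na(x$tsd)) "" else sprintf("; TSD %s", x$tsd)))
  invisible(x)
}

# chain a query against both orientations of a region; returns the best
# orientation with forward-strand subject coordinates
.best_cross_chain <- function(query, region, k, band) {
  n <- nchar(region)
  best <- NULL
  for (strand in c("+", "-")) {
    sub <- if (strand == "+") region else .revcomp(region)
    ch <- .chain_seeds(.cross_seed_pairs(query, sub, k), band)
    if (is.null(ch)) next
    cov <- (ch$max_i + k - 1L - ch$min_i + 1L) / nchar(query)
    if (is.null(best) || cov > best$coverage) {
      j1 <- ch$min_j; j2 <- ch$max_j + k - 1L
      if (strand == "-") { tmp <- j1; j1 <- n - j2 + 1L; j2 <- n - tmp + 1L }
      best <- list(coverage = cov, strand = strand,
                   q_start = ch$min_i, q_end = ch$max_i + k - 1L,
                   s_start = j1, s_end = j2, chain = ch, subject = sub)
    }
  }
  best
}

#' Call presence/absence of an element at a locus
#'
#' The element is present when its seeded alignment to the region covers at
#' least `min_coverage` of the element at identity >= `min_identity` (both
#' strands scanned; coordinates always reported on the forward strand of the
#' region). Otherwise the call is absent, with remnant evidence: `solo_LTR`
#' when one LTR copy alone aligns, `partial` when a substantial fragment
#' does, `none` when no signature of the element remains.
#'
#' @param region Locus sequence (character or `DNAString`).
#' @param element Full element sequence.
#' @param min_identity,min_coverage Presence thresholds.
#' @param k,band Seeding/chaining parameters (see [annotate_ltr()]).
#' @return Object of class `pav_call` with `status`, `coverage`, `identity`,
#'   `match_start`, `match_end`, `strand`, `remnant`.
#' @export
call_pav <- function(region, element, min_identity = 0.85,
                     min_coverage = 0.8, k = 15, band = 50) {
  r <- .seq_chr(region); e <- .seq_chr(element)
  if (!nchar(r) || !nchar(e)) stop("empty sequence")
  best <- .best_cross_chain(e, r, k, band)
  if (!is.null(best) && best$coverage >= min_coverage) {
    espan <- substr(e, best$q_start, best$q_end)
    rspan <- substr(best$subject,
                    if (best$strand == "+") best$s_start else
                      nchar(r) - best$s_end + 1L,
                    if (best$strand == "+") best$s_end else
                      nchar(r) - best$s_start + 1L)
    ident <- .align_identity(espan, rspan)
    if (ident >= min_identity)
      return(structure(list(status = "present", coverage = best$coverage,
                            identity = ident,
                            match_start = best$s_start,
                            match_end = best$s_end,
                            strand = best$strand, remnant = "none"),
                       class = "pav_call"))
  }
  remnant <- "none"
  ann <- tryCatch(annotate_ltr(e, min_ltr = min(500, floor(nchar(e) / 4)),
                               min_identity = 0.7, k = k, band = band),
                  error = function(e2) NULL)
  if (!is.null(ann)) {
    for (ltr in c(substr(e, ann$start, ann$start + ann$ltr5_length - 1L),
                  substr(e, ann$end - ann$ltr3_length + 1L, ann$end))) {
      bl <- .best_cross_chain(ltr, r, k, band)
      if (!is.null(bl) && bl$coverage >= 0.8) {
        remnant <- "solo_LTR"
        break
      }
    }
  }
  if (remnant == "none" && !is.null(best) && best$coverage >= 0.2)
    remnant <- "partial"
  structure(list(status = "absent",
                 coverage = if (is.null(best)) 0 else best$coverage,
                 identity = NA_real_, match_start = NA_integer_,
                 match_end = NA_integer_, strand = NA_character_,
                 remnant = remnant),
            class = "pav_call")
}

#' @export
print.pav_call <- function(x, ...) {
  if (x$status == "present") {
    cat(sprintf("present: %d-%d (%s), coverage %.3f, identity %.4f\n",
                x$match_start, x$match_end, x$strand, x$coverage, x$identity))
  } else {
    cat(sprintf("absent (coverage %.3f), remnant evidence: %s\n",
                x$coverage, x$remnant))
  }
  invisible(x)
}

#' Scan an empty insertion site for excision signatures
#'
#' Looks for a residual solo LTR (either LTR of the element aligning in the
#' site, both strands) and for a target-site duplication: a motif of length
#' within `tsd_range` duplicated in immediate tandem at the insertion point
#' (optionally jittered by up to `jitter` bp). Solo-LTR evidence takes
#' precedence over a TSD; clean sequence yields `none`.
#'
#' @param empty_site Site sequence spanning the putative insertion point
#'   with flank on both sides.
#' @param element Full element sequence.
#' @param tsd_range `c(min, max)` TSD length in bp.
#' @param insertion_point 1-based position of the last base before the
#'   putative insertion point; defaults to the middle of the site.
#' @param jitter Positional tolerance around `insertion_point` (bp).
#' @param k,band Seeding/chaining parameters.
#' @return List with `evidence` (`solo_LTR`/`TSD`/`none`), `tsd_motif`,
#'   `solo_coverage`.
#' @export
scan_remnants <- function(empty_site, element, tsd_range = c(4, 6),
                          insertion_point = NULL, jitter = 0,
                          k = 15, band = 50) {
  s <- .seq_chr(empty_site); e <- .seq_chr(element)
  if (length(tsd_range) != 2L || tsd_range[1] > tsd_range[2] ||
      tsd_range[1] < 1)
    stop("degenerate tsd_range")
  if (is.null(insertion_point)) insertion_point <- nchar(s) %/% 2L
  solo_cov <- 0
  ann <- tryCatch(annotate_ltr(e, min_ltr = min(500, floor(nchar(e) / 4)),
                               min_identity = 0.7, k = k, band = band),
                  error = function(e2) NULL)
  if (!is.null(ann)) {
    for (ltr in c(substr(e, ann$start, ann$start + ann$ltr5_length - 1L),
                  substr(e, ann$end - ann$ltr3_length + 1L, ann$end))) {
      bl <- .best_cross_chain(ltr, s, k, band)
      if (!is.null(bl)) solo_cov <- max(solo_cov, bl$coverage)
    }
  }
  tsd_motif <- NA_character_
  for (t in seq(tsd_range[2], tsd_range[1])) {
    for (off in seq(-jitter, jitter)) {
      p <- insertion_point + off
      if (p - t + 1L < 1L || p + t > nchar(s)) next
      left <- substr(s, p - t + 1L, p)
      right <- substr(s, p + 1L, p + t)
      if (identical(left, right) && !grepl("N", left, fixed = TRUE)) {
        tsd_motif <- left
        break
      }
    }
    if (!is.na(tsd_motif)) break
  }
  evidence <- if (solo_cov >= 0.8) "solo_LTR"
  else if (!is.na(tsd_motif)) "TSD"
  else "none"
  list(evidence = evidence, tsd_motif = tsd_motif, solo_coverage = solo_cov)
}

#' Construct a synthetic LTR element with known structure
#'
#' Builds `5'LTR + internal + 3'LTR` where the 3' LTR is the 5' LTR with
#' `ltr3_extra` random bases inserted midway — by default reproducing the
#' 2877 / 4687 / 2879 bp layout used throughout the package's tests. Purely
#' synthetic sequence; no real element is copied.
#'
#' @param ltr_len 5' LTR length (bp).
#' @param internal_len Internal (polyprotein) region length (bp).
#' @param ltr3_extra Extra bases inserted into the 3' LTR copy.
#' @param seed Optional RNG seed.
#' @return List with `element`, `ltr5`, `ltr3`, `internal` strings.
#' @export
synth_ltr_element <- function(ltr_len = 2877, internal_len = 4687,
                              ltr3_extra = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ltr5 <- random_dna(ltr_len)
  internal <- random_dna(internal_len)
  ltr3 <- ltr5
  if (ltr3_extra > 0) {
    at <- ltr_len %/% 2L
    ltr3 <- paste0(substr(ltr5, 1, at), random_dna(ltr3_extra),
                   substr(ltr5, at + 1L, ltr_len))
  }
  list(element = paste0(ltr5, internal, ltr3),
       ltr5 = ltr5, ltr3 = ltr3, internal = internal)
}

#' Synthetic locus fixtures around one insertion site
#'
#' From an element and random flanks, builds the four locus states used to
#' exercise [call_pav()] and [scan_remnants()]: the occupied site (element
#' flanked by its target-site duplication), the pre-insertion/clean-excision
#' state (single TSD copy, no trace), a TSD-remnant site (tandem TSD pair),
#' and a solo-LTR site.
#'
#' @param element Element sequence (e.g. from [synth_ltr_element()]).
#' @param ltr5 The element's 5' LTR sequence.
#' @param flank Flank length on each side (bp).
#' @param tsd TSD motif.
#' @param seed Optional RNG seed for the flanks.
#' @return List of sequences `present`, `clean`, `tsd_site`, `solo_site`,
#'   plus `insertion_point` (position of the junction in the empty sites).
#' @export
ltr_locus_fixtures <- function(element, ltr5, flank = 2000, tsd = "ACGTA",
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f5 <- random_dna(flank); f3 <- random_dna(flank)
  list(present = paste0(f5, tsd, element, tsd, f3),
       clean = paste0(f5, tsd, f3),
       tsd_site = paste0(f5, tsd, tsd, f3),
       solo_site = paste0(f5, tsd, ltr5, tsd, f3),
       insertion_point = flank + nchar(tsd))
}
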
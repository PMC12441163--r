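# Internal coordinates are 0-based half-open; VCF/GFF3 are written 1-based
# inclusive and BED 0-based half-open, converting only at these boundaries.

#' Write a variant set as VCF 4.2
#'
#' Sites-only VCF with the variant class (`VC`) and, when present, the bulk
#' of origin (`ORIGIN`) as INFO fields, plus contig header lines taken from
#' the genome model.
#'
#' @param variants data.frame `chrom`, `pos`, `ref`, `alt`, optionally
#'   `class` and `origin`.
#' @param file Output path.
#' @param genome Optional [genome_model()] for `##contig` header lines.
#' @return `file`, invisibly.
#' @export
write_variants_vcf <- function(variants, file, genome = NULL) {
  hdr <- c("##fileformat=VCFv4.2", "##source=lintmap")
  if (!is.null(genome))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          genome$chromosomes$name,
                          as.integer(genome$chromosomes$length_bp)))
  hdr <- c(hdr,
           '##INFO=<ID=VC,Number=1,Type=String,Description="Variant class">')
  has_origin <- "origin" %in% names(variants)
  if (has_origin)
    hdr <- c(hdr, paste0('##INFO=<ID=ORIGIN,Number=1,Type=String,',
                         'Description="Bulk of origin">'))
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", sep = "\t"))
  info <- if ("class" %in% names(variants))
    paste0("VC=", variants$class) else rep(".", nrow(variants))
  if (has_origin) info <- paste0(info, ";ORIGIN=", variants$origin)
  body <- if (nrow(variants))
    paste(variants$chrom, format(variants$pos, scientific = FALSE,
                                 trim = TRUE),
          ".", variants$ref, variants$alt, ".", ".", info, sep = "\t")
  else character(0)
  writeLines(c(hdr, body), file)
  invisible(file)
}

#' Read a variant set from VCF
#'
#' Multi-allelic records are split into one row per alternate allele before
#' keying, and contig names from the header are attached as the `contigs`
#' attribute for coordinate-system checks.
#'
#' @param file VCF path.
#' @return data.frame `chrom`, `pos`, `ref`, `alt`, `class`.
#' @export
read_variants_vcf <- function(file) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)   # single-record files drop the dim
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix)) {
    alts <- strsplit(fix$ALT, ",", fixed = TRUE)
    reps <- lengths(alts)
    out <- data.frame(chrom = rep(fix$CHROM, reps),
                      pos = as.integer(rep(fix$POS, reps)),
                      ref = rep(fix$REF, reps),
                      alt = unlist(alts, use.names = FALSE))
    out$class <- ifelse(nchar(out$ref) != nchar(out$alt) |
                          nchar(out$ref) > 1L, "indel", "SNP")
  } else {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      class = character(0))
  }
  contigs <- sub("^##contig=<ID=([^,>]+).*$", "\\1",
                 grep("^##contig=", v@meta, value = TRUE))
  attr(out, "contigs") <- if (length(contigs)) contigs else NULL
  out
}

#' Write / read phenotype measurements as CSV
#'
#' Schema: `id`, `replicate`, `L`, `a`, `b`, optionally `group`.
#'
#' @param ph Phenotype data.frame.
#' @param file Path.
#' @export
write_phenotypes_csv <- function(ph, file) {
  stopifnot(all(c("id", "replicate", "L", "a", "b") %in% names(ph)))
  utils::write.csv(ph, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_phenotypes_csv
#' @export
read_phenotypes_csv <- function(file) {
  ph <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("id", "replicate", "L", "a", "b")
  if (!all(need %in% names(ph)))
    stop("phenotype CSV must have columns ", paste(need, collapse = ", "))
  ph
}

#' Write / read a gene count matrix as TSV (genes x samples)
#'
#' @param counts Matrix with gene rownames.
#' @param file Path.
#' @export
write_counts_tsv <- function(counts, file) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write scan windows or a peak region as BED (0-based half-open)
#'
#' @param bins Output of [bin_counts()] (the `count` goes in the BED score
#'   column) or a `peak_region`.
#' @param file Path.
#' @export
write_bins_bed <- function(bins, file) {
  if (inherits(bins, "peak_region")) {
    if (isTRUE(bins$no_peak)) stop("no peak to write")
    df <- data.frame(chrom = bins$chrom,
                     start = format(bins$start, scientific = FALSE),
                     end = format(bins$end, scientific = FALSE),
                     name = "peak_region", score = bins$peak_count)
  } else {
    df <- data.frame(chrom = bins$chrom,
                     start = format(bins$start, scientific = FALSE,
                                    trim = TRUE),
                     end = format(bins$end, scientific = FALSE, trim = TRUE),
                     name = paste0("bin_", seq_len(nrow(bins))),
                     score = bins$count)
  }
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Write sequences as FASTA / read FASTA
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @param file Path.
#' @export
write_fasta <- function(seqs, file) {
  if (!inherits(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(seqs, file)
  invisible(file)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  stats::setNames(as.character(x), names(x))
}

#' Export an LTR annotation as GFF3
#'
#' Emits a `mobile_genetic_element` feature spanning the element plus one
#' `long_terminal_repeat` feature per LTR, in 1-based inclusive coordinates
#' on the given sequence.
#'
#' @param ann An `ltr_annotation`.
#' @param seqid Name of the annotated sequence.
#' @param file Path.
#' @export
write_ltr_gff3 <- function(ann, seqid, file) {
  gr <- GenomicRanges::GRanges(
    seqnames = seqid,
    ranges = IRanges::IRanges(
      start = c(ann$start, ann$start, ann$end - ann$ltr3_length + 1L),
      end = c(ann$end, ann$start + ann$ltr5_length - 1L, ann$end)),
    type = c("mobile_genetic_element", "long_terminal_repeat",
             "long_terminal_repeat"))
  gr$ID <- c("ltr_element_1", "ltr_element_1_5p", "ltr_element_1_3p")
  gr$Parent <- c(NA, "ltr_element_1", "ltr_element_1")
  rtracklayer::export(gr, file, format = "gff3")
  invisible(file)
}

#' Write a run manifest
#'
#' Structured echo of the configuration and seed; deliberately excludes
#' timestamps so identical runs produce identical manifests.
#'
#' @param file Path.
#' @param seed Seed used for the run.
#' @param config A [cross_config()] (or any list).
#' @param genome A [genome_model()].
#' @param extra Optional named list of further settings.
#' @export
write_manifest <- function(file, seed, config, genome, extra = list()) {
  payload <- list(
    package = "lintmap",
    version = as.character(utils::packageVersion("lintmap")),
    seed = seed,
    config = unclass(config),
    genome = list(chromosomes = genome$chromosomes,
                  variant_density = genome$variant_density,
                  causal_locus = genome$causal_locus),
    settings = extra)
  jsonlite::write_json(payload, file, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(file)
}
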
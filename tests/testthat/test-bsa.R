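vdf <- function(chrom, pos, ref = "A", alt = "T") {
  data.frame(chrom = rep_len(chrom, length(pos)), pos = pos,
             ref = rep_len(ref, length(pos)),
             alt = rep_len(alt, length(pos)),
             class = rep_len("SNP", length(pos)))
}

test_that("shared variants are subtracted, leaving the symmetric difference", {
  a <- vdf("c1", c(10, 20))
  b <- vdf("c1", c(20, 30))
  d <- subtract_shared_variants(a, b)
  expect_equal(d$pos, c(10, 30))
  expect_equal(d$origin, c("bulk_a", "bulk_b"))
  expect_identical(nrow(subtract_shared_variants(a, a)), 0L)
  # unordered-set commutativity
  d2 <- subtract_shared_variants(b, a, names = c("bulk_b", "bulk_a"))
  expect_equal(d[order(d$pos), c("chrom", "pos", "origin")],
               d2[order(d2$pos), c("chrom", "pos", "origin")])
})

test_that("symmetric-difference size matches brute force on random sets", {
  set.seed(14)
  for (r in 1:25) {
    pa <- sample(100, sample(0:30, 1))
    pb <- sample(100, sample(0:30, 1))
    a <- vdf("c1", sort(pa)); b <- vdf("c1", sort(pb))
    d <- subtract_shared_variants(a, b)
    expect_identical(nrow(d),
                     length(pa) + length(pb) - 2L * length(intersect(pa, pb)))
  }
})

test_that("contig mismatch between variant sets is an error", {
  a <- vdf("c1", 10); attr(a, "contigs") <- c("c1")
  b <- vdf("c2", 10); attr(b, "contigs") <- c("c2")
  expect_error(subtract_shared_variants(a, b), "mismatch")
})

test_that("binning follows the half-open window convention", {
  g <- genome_model(data.frame(name = "c1", length_bp = 15e6,
                               length_cM = 10))
  b <- bin_counts(vdf("c1", c(1, 4999999, 5000001)), g, 5e6)
  expect_equal(b$count, c(2, 1, 0))
  expect_equal(b$start, c(0, 5e6, 10e6))
  expect_equal(b$end, c(5e6, 10e6, 15e6))
  # empty set: all windows still emitted, all zero
  b0 <- bin_counts(vdf("c1", numeric(0)), g, 5e6)
  expect_equal(b0$count, c(0, 0, 0))
  expect_error(bin_counts(vdf("c1", 16e6), g, 5e6), "outside")
  expect_error(bin_counts(vdf("cX", 5), g, 5e6), "absent")
})

test_that("no variant is lost or double-counted by binning", {
  set.seed(8)
  g <- genome_model(data.frame(name = c("c1", "c2"),
                               length_bp = c(9e6, 4e6),
                               length_cM = c(10, 10)))
  v <- rbind(vdf("c1", sample(9e6, 500)), vdf("c2", sample(4e6, 200)))
  b <- bin_counts(v, g, 1e6)
  expect_equal(sum(b$count), nrow(v))
  # Poisson-like thinning: mean count near density * width on c1
  expect_lt(abs(mean(b$count[b$chrom == "c1"]) - 500 / 9), 3 * sqrt(500) / 9)
})

test_that("peak detection extends by the count threshold", {
  g <- genome_model(data.frame(name = "c1", length_bp = 20e6,
                               length_cM = 10))
  mk <- function(counts) data.frame(chrom = "c1",
                                    start = (seq_along(counts) - 1) * 5e6,
                                    end = seq_along(counts) * 5e6,
                                    count = counts)
  p1 <- detect_peak(mk(c(3, 2, 100, 4)), extend_fraction = 0.5)
  expect_equal(nrow(p1$windows), 1L)
  expect_equal(p1$peak_count, 100)
  expect_equal(p1$start, 10e6)
  p2 <- detect_peak(mk(c(3, 60, 100, 55, 4)), extend_fraction = 0.5)
  expect_equal(nrow(p2$windows), 3L)
  expect_equal(p2$start, 5e6)
  expect_equal(p2$end, 20e6)
  p0 <- detect_peak(mk(c(0, 0, 0)))
  expect_true(p0$no_peak)
})

test_that("VCF round trip preserves variant identity and splits ALT alleles", {
  g <- genome_model(data.frame(name = c("c1", "c2"),
                               length_bp = c(1e6, 1e6), length_cM = c(1, 1)))
  v <- data.frame(chrom = c("c1", "c2"), pos = c(100L, 200L),
                  ref = c("A", "C"), alt = c("T", "CTT"),
                  class = c("SNP", "indel"),
                  origin = c("bulk_a", "bulk_b"))
  f <- tempfile(fileext = ".vcf")
  write_variants_vcf(v, f, g)
  back <- read_variants_vcf(f)
  expect_equal(back[c("chrom", "pos", "ref", "alt", "class")],
               v[c("chrom", "pos", "ref", "alt", "class")])
  expect_identical(attr(back, "contigs"), c("c1", "c2"))
  # hand-written multi-allelic record splits per alternate allele
  f2 <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=c1,length=1000>",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t"),
               paste("c1", "50", ".", "G", "A,T", ".", ".", ".",
                     sep = "\t")), f2)
  multi <- read_variants_vcf(f2)
  expect_identical(nrow(multi), 2L)
  expect_equal(multi$alt, c("A", "T"))
  expect_equal(multi$pos, c(50L, 50L))
})
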
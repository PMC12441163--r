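# Shared fixtures, built in code at load time.

# parental CIELab means (brown and white lines)
BROWN_LAB <- c(67.75, 11.58, 30.33)
WHITE_LAB <- c(96.49, 0.64, 10.25)

# one-chromosome desk genome for fast simulation tests
small_genome <- function(len = 1e6, cm = 50, density = 1e-4,
                         causal = len / 2) {
  genome_model(data.frame(name = "chr1", length_bp = len, length_cM = cm),
               variant_density = density,
               causal_locus = list(chrom = "chr1", pos = causal))
}

# synthetic LTR element at the published component lengths, plus locus
# states; annotated once here because several test files reuse it
fix_el <- synth_ltr_element(seed = 42)
fix_ann <- annotate_ltr(fix_el$element)
fix_loci <- ltr_locus_fixtures(fix_el$element, fix_el$ltr5, seed = 43)

# a small element that keeps remnant-scan property loops cheap
fix_small_el <- synth_ltr_element(ltr_len = 100, internal_len = 100,
                                  ltr3_extra = 0, seed = 44)
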
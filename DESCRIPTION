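Package: lintmap
Title: Bulked-Segregant Mapping of a Brown-Lint Locus in Cotton F2 Populations
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of the mapping analysis that localizes a
    rust-brown fiber locus in upland cotton: CIELab (CIE76) color phenotyping and
    classification of F2 segregants, Mendelian segregation goodness-of-fit,
    bulked-segregant variant subtraction with fixed-width genomic binning and peak
    detection, dominant-marker co-segregation interval mapping, LTR-retrotransposon
    structure annotation with presence/absence and excision-signature calling, and
    differential-expression summaries. A synthetic F2-population generator emulates
    the study design (508 individuals, 77+77 bulks, incomplete dominance, a causal
    locus with an upstream LTR element) so every stage is exercisable without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    limma,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
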
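---
title: "Methods: mapping a brown-fiber locus with bulked segregants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping a brown-fiber locus with bulked segregants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lintmap)
```

`lintmap` reconstructs, stage by stage, how a qualitative fiber-color locus
is mapped in an F2 cotton population: phenotype the segregants in CIELab
space, confirm single-locus inheritance, localize the locus by subtracting
the pooled variant calls of contrasting bulks, narrow it with dominant
markers, characterize a structural allele (an LTR retrotransposon upstream
of the candidate gene), and connect it to expression. This vignette states
the models behind each stage, the defaults and why they were chosen, what
the synthetic generator does and does not emulate, and the numerical
corner-case policies.

## The genetic model

One biallelic locus with incomplete dominance: genotypes 0/1/2 copies of
the mutant (brown) allele give white, intermediate ("cream"/tan) and brown
lint. An F2 therefore segregates 1:2:1 in genotype and 3:1 in
carrier:white phenotype. Meiosis follows the Haldane model — crossover
counts per gamete and chromosome are Poisson with mean `length_cM / 100`
and positions are uniform, i.e. no interference. The map function is a
modelling choice here (crossover interference is real in cotton but
irrelevant to window-scale mapping); genetic distance enters only through
the local recombination fraction around the locus.

## Phenotyping and classification

Fiber color is a CIELab triple (L\* lightness 0–100, a\* green–red, b\*
blue–yellow). Three technical replicates per plant are averaged
channel-wise; distances are CIE76,
$\Delta E = \sqrt{(\Delta L^*)^2 + (\Delta a^*)^2 + (\Delta b^*)^2}$.
The square root matters: the conventional perceptibility anchors (ΔE < 1
imperceptible, ΔE > ~5 clearly distinct) only hold on the rooted scale.

The three-group rule is the package's own, since grouping in this kind of
study is usually done ad hoc from significance of the color separation: a
sample is brown if it is more than `cream_band` ΔE units closer to the
brown parental reference than to the white one, white in the mirror case,
cream otherwise. The default half-band of ΔE = 5 sits at the "clearly
different color" anchor and is small against the ~36.7 ΔE separating the
parents; a noiseless heterozygote (midpoint color) is exactly equidistant
and classifies cream for any positive band. Group comparisons of any trait
(color channels, combustion calorimetry) use one-way ANOVA with Tukey HSD
(Tukey–Kramer under imbalance) via `compare_groups()`.

## Segregation testing

`chi_square_ratio()` is the Pearson statistic against arbitrary ratio
weights, df = k − 1, no Yates correction — with a correction the published
value for 395:113 vs 3:1 (χ² = 2.06) is not reproduced. Brown and cream
are pooled as carriers before testing, since both carry the dominant
allele. The test's empirical level is checked by simulation
(`segregation_calibration()`): over Binomial(508, 3/4) carrier draws the
exact pass rate at α = 0.05 is 95.45%, and 1,000 replicates estimate it
within about ±1.4%.

## The bulk comparison

Bulks are modelled at the presence/absence level: a parental-difference
site is called in a bulk iff any member carries the mutant-parent allele.
This matches a pipeline that subtracts *called variant identity* between
bulks rather than comparing allele frequencies (no SNP-index), and it is
what makes the subtraction informative: away from the locus both 77-plant
bulks contain a carrier with probability $1 - 0.25^{77} \approx 1$, so
shared variants vanish under the symmetric difference; at the locus the
white bulk is all genotype 0 and misses mutant-parent variants with
probability $(1-r)^{154}$ at recombination fraction $r$, so the residue
piles up around the causal position. Calls are then perturbed by dropout
(P(miss a present variant) = 0.05) and genotyping error (P(flip) = 0.02) —
the two pooled-sequencing noise modes that matter at the set level. The
identity key is (chrom, pos, ref, alt); multi-allelic records are split
per alternate allele before keying; zygosity is ignored.

Window counts use 0-based half-open 5-Mb tiles (1-based inclusive in all
user-facing output); the peak region extends from the maximum window over
adjacent windows with at least `extend_fraction = 0.5` of the peak count.
Raw counts are scanned without smoothing or a significance band — at the
default noise levels the causal window exceeds the background by many
times its Poisson spread, and a confidence band would suggest a precision
of localization the 5-Mb grid does not have.

## Marker mapping

Mutant-specific dominant assays call P in any carrier, so heterozygous and
homozygous plants are indistinguishable and only concordance with the
phenotype is counted: a recombinant is P∧white or N∧carrier. With cream
plants counted as carriers, the per-plant discordance probability at
recombination fraction $r$ is $r - r^2/2$. Markers with zero recombinants
co-segregate; the interval is delimited by the nearest flanking markers
with at least one recombinant, and is flagged open when no zero-recombinant
marker exists (all tied minima reported) or a flank is missing. The
default 11-marker panel densifies toward the locus with the nearest assay
2.9 kb away — the distance at which a fully co-segregating marker is
expected in a population of 508 (expected recombinants ≈ 0.03).

## LTR element annotation

The structural allele is an upstream Ty3/Gypsy-style retrotransposon:
5′LTR–internal–3′LTR with near-identical LTRs and a target-site
duplication. `annotate_ltr()` finds the LTR pair by exact k-mer seeding
(k = 15) of repeated words separated by at least `min_ltr`, greedy
colinear chaining within a 50-bp diagonal band (absorbing small indels
between the copies), and a global alignment of the two candidate copies
(match +1, mismatch −2, gap −3) for the identity estimate. On the bundled
synthetic element — built to the published component lengths, 2877-bp LTR,
4687-bp internal region, and the LTR copy with a 2-bp insertion — it
recovers (2877, 4687, 2879) exactly. Thresholds: `min_ltr` 500 bp,
identity ≥ 0.8 for annotation; presence requires the element to chain over
≥ 0.8 of its length at ≥ 0.85 identity (`call_pav()`, both strands
scanned, forward-strand coordinates reported). Remnant evidence at an
empty site: a solo LTR when either LTR alone chains over ≥ 0.8 of its
length; a TSD when a 4–6-bp motif is duplicated in immediate tandem at the
declared insertion point (the chance rate of that event in random sequence
is $\sum_{t=4}^{6} 4^{-t} \approx 0.005$, which the property tests verify
as the false-positive ceiling); otherwise none. A clean site — no TSD
doubling, no LTR — is indistinguishable from a locus that never carried
the element, which is precisely the biological reading the pipeline
supports. Note the published element description ("~10.7 kb") slightly
exceeds the sum of its stated components (10,443 bp); the component
lengths are treated as authoritative for fixtures.

## Expression

Counts are CPM-normalized (library size = column sum), shifted by a
pseudocount of 1 on the CPM scale, and logged. The default test is the
moderated linear model (limma with `trend = TRUE`): with 2–3 replicates
per line a per-gene variance has so few degrees of freedom that *no*
effect size can reach genome-wide significance under BH across thousands
of genes, so gene-wise variance pooling is not a refinement but a
requirement; the mean–variance trend additionally keeps low-count genes
from inflating the null. The plain per-gene one-way ANOVA remains
available (`method = "anova"`; with two lines it equals the pooled t-test
and backs that invariant's test). Significance = q < 0.05 and ≥ 2-fold;
fold changes are pseudocounted ratios of mean CPM, so a reported 179-fold
gene with a low-expressed denominator reads slightly below the planted
ratio — an intentional bias that stabilizes ratios near zero. Genes with
zero variance everywhere are untestable and reported with p = NA, q = 1,
not significant. DEG *counts* on real data are not expected to match any
particular published total: normalization/test stacks differ and the
synthetic counts are not a transcriptome model.

## The synthetic generator: what it does and does not show

Defaults are the study design: n = 508 F2 plants, 77 + 77 bulks drawn
randomly within phenotype group (how bulk members were chosen from the
phenotyped plants is not usually reported; random-within-group is the
neutral choice), three replicates of color per plant with per-channel
Gaussian sd 1.0 (comparable to the parental technical-replicate spread),
parental class means (96.49, 0.64, 10.25) and (67.75, 11.58, 30.33) with
the heterozygote at their midpoint, genotyping error 0.02 and dropout
0.05. The desk-scale genome is 5 chromosomes × 50 Mb at 100 cM (≈2 cM/Mb,
a realistic cotton-like density) with one parental difference per kb and
the causal locus at A07:22,500,000; sizes are configurable upward to a
full 26-chromosome layout.

The generator emulates set-level bulk calls, Mendelian meiosis and planted
expression effects. It does not model read-level sequencing error,
alignment artifacts, tetraploid homoeolog confusion, allele-frequency
gradients within bulks, or linkage disequilibrium beyond the simulated
cross — so passing tests demonstrate that the *pipeline logic* localizes
the locus under its stated noise model, not that any particular real
dataset would yield the same counts.

## Problem sizes and determinism

The replication studies run at: 50 crosses for peak localization, 50 for
interval bracketing, 20 seeds for expression calibration (2,000 genes,
2 replicates/line for the null; planted genes at base mean 50 so the fold
is measurable against the pseudocount), and 1,000 replicates for the
segregation level — sizes at which every rate above is estimated to a few
percent while a full run stays comfortable on a laptop. All randomness
flows through seeds derived from one base seed; `run_pipeline()` reruns
byte-identically, and manifests deliberately omit timestamps.
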
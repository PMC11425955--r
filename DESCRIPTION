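Package: cssldrought
Title: Drought-Resistance Dissection of Interspecific Cotton
    Chromosome-Segment Substitution Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of drought-resistance phenomics and QTL
    mapping in a Gossypium hirsutum x G. barbadense chromosome-segment
    substitution line (CSSL) population. Aggregates multi-year trial data
    to per-line BLUPs, computes drought-resistance coefficients (DRC), the
    membership-function value of drought resistance (MFVD) and five-level
    drought grades, and maps condition-dependent QTL with three strategies:
    a kinship-corrected mixed-linear-model association scan, a stepwise
    likelihood-ratio additive scan on an introgression bin map, and bulked
    segregant analysis via the pooled delta SNP-index with Monte-Carlo
    confidence bands tailored to the low, locus-specific donor-allele
    frequencies of CSSL panels. QTL from the three methods are named,
    co-localized, haplotyped at their peak SNPs, and summarized by a
    resistant-haplotype pyramiding analysis. A synthetic CSSL study
    generator with known ground truth makes every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    IRanges,
    S4Vectors,
    vcfR
Suggests:
    lme4,
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
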
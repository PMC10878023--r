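Package: cloneconfound
Title: Genetic Confound Screening for CRISPR-Edited Clonal Cell Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An audited re-analysis toolkit for detecting genetic confounds in
    comparisons of CRISPR/Cas9-edited versus control clonal cell lines.
    Provides a CRISPR off-target landscape scanner with PAM degeneracy and
    1-bp bulge support, GATK-style hard filtering of SNV/INDEL calls,
    clone-unique INDEL definition with coverage requirements in the sister
    clone, a resampling-based off-target INDEL enrichment test against
    random-region and subsampled wild-type nulls, allele-frequency drift and
    differential-genotype screens, binned read-depth copy-number screening
    with N-masking and external CNV/translocation concordance, strain-matched
    methylation sample pairing with paired tests and FDR adjustment, and a
    seeded synthetic-data generator that plants known truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
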
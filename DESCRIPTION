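Package: mitodrift
Title: Mitochondrial DNA Population Genetics and Drift Resampling Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Curation and analysis of complete mtDNA genome alignments for
    population studies: site masking and missing-base imputation, haplotype
    collapsing, haplotype and nucleotide diversity with their sampling
    variances, exact binomial confidence intervals for haplogroup
    frequencies, pairwise Phi-ST and hierarchical AMOVA with permutation
    tests, Mantel tests against great-circle geographic distances,
    rho-statistic founder dating, and a Wright-Fisher resampling test of
    shared ancestry that scores the compatibility of observed haplogroup
    frequencies in two daughter populations with a common ancestor under
    pure drift. Includes a synthetic-data generator emulating the
    statistical structure of multi-population mtDNA surveys and a
    reproducible pipeline driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    seqinr,
    geosphere,
    vegan,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
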
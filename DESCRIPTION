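Package: jcar
Title: Joint Conditional Autoregressive Association Testing of Genetic
    and Epigenetic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Gene-based association testing of SNP genotypes and DNA
    methylation with a continuous phenotype in family samples.  Genetic
    and methylation random effects follow conditional autoregressive
    (CAR) priors built from identity-by-state and Gaussian kernel
    similarities, familial correlation is modelled through the pedigree
    kinship matrix, and association is assessed with a linear score test
    on the profiled restricted likelihood whose p-value is the tail
    probability of an indefinite quadratic form in normal variables,
    obtained by numerical inversion of the characteristic function
    (Davies-type).  Includes a genome-wide gene-based scan driver, a
    family-structured data simulator, and readers and writers for the
    standard file formats (VCF, BED, PED, TSV matrices).
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
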
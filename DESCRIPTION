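Package: admixcolor
Title: Pigmentation Genetics in Two-Way Admixed Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for quantitative pigmentation
    genetics in recently admixed African-European cohorts. Generates synthetic
    cohorts with calibrated genome-wide ancestry, local-ancestry tracts,
    ancestry-informative genotypes and additive phenotypes; quantifies skin
    color as a robust square-root melanin (MM) index from reflectance panels
    and eye color as an arc-length (T) index along a principal curve fitted to
    normalized iris RGB values; runs genotype-based, local-ancestry-based and
    conditional association scans with principal-component stratification
    control and genomic-control diagnostics; decomposes phenotypic variance
    into locus-specific and genome-wide-ancestry components via
    population-attributable variance with overlap algebra; and estimates
    detection power by simulation under admixture stratification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    withr,
    vcfR,
    yaml,
    jsonlite,
    png
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
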
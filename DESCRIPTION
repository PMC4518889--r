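Package: snpmask
Title: Variant-Aware Microarray Probe Masking and eQTL Bias Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Removes microarray probes whose genomic footprint intersects
    population or strain variants read from VCF, rebuilds internally
    consistent platform annotations (generic TSV and simplified PGF/CLF
    dialects), and quantifies the hybridization bias such variants induce
    in cis-eQTL mapping. Includes a linear-regression eQTL scanner with
    best-locus selection and Benjamini-Hochberg FDR, an exact-binomial
    allele-effect direction diagnostic, uncorrected-versus-corrected run
    comparison, and a synthetic-data generator (backcross and population
    designs) that emulates probe-level SNP attenuation so the whole
    pipeline is testable without external accessions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
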
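Package: bsnphap
Title: SNP-Panel Haplotyping, Recombination and Clustering for the Chicken MHC-B Region
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for high-resolution typing of the chicken MHC-B region from a
    dense SNP panel anchored to the AB268588 reference sequence. Implements
    copy-number-aware genotype calling from KASP endpoint fluorescence and qPCR
    genome-equivalent estimation, haplotype inference by homozygote subtraction
    within lines, detection of recombinant haplotypes with breakpoint
    localization and 1000-bp hotspot profiling, recombination and LEI0258
    VNTR mutation-rate estimation, and haplotype family clustering by
    neighbor-joining with bootstrap support and median pairwise patristic
    distance thresholds. A seeded population simulator with truth tables makes
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    grDevices,
    yaml
Suggests:
    igraph,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
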
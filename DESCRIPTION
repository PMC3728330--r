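Package: bsaqtl
Title: QTL Mapping from Pooled Extreme-Phenotype Sequencing (Bulked Segregant Analysis)
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for next-generation-sequencing-assisted bulked
    segregant analysis (QTL-seq) of biparental crosses. Given per-SNP parental
    allele depths in two extreme-phenotype DNA pools, computes the per-SNP
    likelihood-ratio G statistic and its tricube-smoothed sliding-window G'
    profile, estimates a robust log-normal null for G' with a
    Benjamini-Hochberg FDR threshold, scans for differential SNPs by
    Jensen-Shannon divergence with Bonferroni correction, profiles the
    windowed reference-parent allele-frequency difference between pools, and
    delineates QTL intervals with summit statistics and resistant-allele
    source. Includes modified-Mott FASTQ quality trimming, SNP filtering and
    coverage summaries, and a seeded simulator of F3 extreme-tail pooled
    sequencing experiments for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    vcfR,
    yaml,
    jsonlite
Suggests:
    Biostrings,
    S4Vectors,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
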
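Package: concatMRD
Title: Concatemer Consensus Error Correction and ctDNA Molecular
    Residual Disease Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Whole-genome cell-free DNA analysis built on rolling-circle
    concatemer sequencing. Tandem copies of each template molecule are
    compared within a read pair to remove PCR and sequencing errors at the
    single-read level ("repeat confirmation"), yielding molecule-resolved
    pileups with background error rates in the 1e-7 range. On top of the
    corrected pileup the package estimates per-substitution-type error
    rates, calls molecular residual disease (MRD) with a constrained
    maximum-likelihood binomial likelihood-ratio test over a tumor-informed
    marker set, simulates detection rates and limits of detection across
    error rate, depth, marker count and circulating variant allele
    frequency, and implements white-blood-cell-free tumor-specific marker
    selection. A synthetic-fixture generator produces reference sequences,
    concatemer read sets, plasma pileups and multi-patient cohorts so the
    whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    data.table,
    jsonlite,
    stats,
    utils,
    Biostrings,
    Rsamtools,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
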
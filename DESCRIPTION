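Package: asmpatch
Title: Upgrade Draft Microbial Assemblies with Corrected Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Improves draft microbial genome assemblies using corrected
    PacBio long reads (CPBLRs). Implements a three-stage procedure:
    assembly modification (N-gap filling by spanning-read consensus and
    splitting of chimeric contigs at zero-coverage positions), greedy
    longest-first representative sequence selection with containment-based
    redundancy removal, and iterative contig connection by strict and easy
    long-read bridging with repeat-aware gates. Ships a synthetic assembly
    simulator with ground-truth tracking so every stage can be validated
    against known genome layouts, plus a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
VignetteBuilder: knitr
SystemRequirements: BLAST+ (blastn, makeblastdb) on the PATH
Config/testthat/edition: 3
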
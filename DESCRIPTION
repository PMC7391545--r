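Package: hapbreed
Title: Design and Bookkeeping Tools for Haplodiploid Breeding Resources
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and tracking laboratory breeding resources in
    haplodiploid arthropods such as spider mites. Implements the four-state
    sib-mating cross-type chain and the inbreeding-coefficient recursion for
    haplodiploids (with exact dyadic-rational arithmetic), a seeded
    gene-dropping simulator of inbred-line creation with a line-panel
    attrition model, enumeration and scheduling of controlled
    interpopulation crossing designs (matched pairs over four founder
    populations, round robin over three) with equal-representation founding
    censuses, and effective-generation bookkeeping for serial-transfer
    experimental evolution with backup and base-population replenishment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
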
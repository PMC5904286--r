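Package: cdpcr
Title: Absolute Microbial Enumeration by Chip-Based Digital PCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for absolute enumeration of microbial genomic targets by
    chip-based digital PCR (cdPCR). Converts per-chip positive/qualified
    well counts into template concentrations via Poisson partition
    statistics with confidence intervals and quality-control flags;
    implements a full dilution-series assay validation workflow (dynamic
    range, limit of quantification, limit of detection, false-positive
    rate, linearity/efficiency); provides exact noncentral-t power and
    replicate-number analysis for method comparison; and includes a
    stochastic chip simulator (Poisson occupancy, well dropout, per-well
    error rates, viability-PCR effects) for method evaluation with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
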
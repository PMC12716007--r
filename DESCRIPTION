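Package: phytoscreen
Title: Microplate Bioassay Processing and Dual-Score Prioritization of Plant Extracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes 96-well plate-reader assays for natural-product
    screening (DPPH radical scavenging and hyaluronidase, tyrosinase,
    lipoxygenase and collagenase inhibition): optical-density correction,
    inhibition percentages under control- and blank-referenced formulas,
    and technical-replicate statistics. Fits linear calibration curves to
    express ferric-reducing antioxidant power (FRAP) as Fe(2+) equivalents
    and total phenolic content (TPC) as gallic acid equivalents on a
    dry-weight basis. Converts inhibition percentages to semi-quantitative
    plus-grades, computes normalized bioactivity and innovation scores,
    applies dual-score thresholds to shortlist candidate species, and runs
    an ordered multi-stage funnel filter over candidate registries with a
    full audit trail. A synthetic-data module generates plates with known
    ground truth and registries with prescribed per-stage retention so the
    whole pipeline is testable without instrument files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
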
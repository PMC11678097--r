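Package: edrisk
Title: Elemental Exposure and Health-Risk Assessment for Energy Drinks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toxicological risk assessment of multi-element concentration
    panels measured in beverages by ICP-OES/ICP-MS. Computes estimated
    daily intake (EDI), non-carcinogenic hazard quotients (HQ) and hazard
    indices (HI), and incremental lifetime cancer risk (ILCR) with
    categorical risk bands, for configurable exposure scenarios and
    toxicity reference tables. Includes regulatory-limit exceedance
    screening via one-sample t-tests, between-brand comparison by the
    tie-corrected Kruskal-Wallis H test with Bonferroni family-wise
    control, a synthetic panel generator for validation, and a bundled
    reference panel of nine commercial energy-drink brands.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
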
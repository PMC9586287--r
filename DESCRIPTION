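Package: ttcmoe
Title: Provisional Margin-of-Exposure Prioritization for Data-Poor Chemicals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: High-throughput, structure-based risk prioritization for chemicals
    lacking traditional toxicity data. Assigns thresholds of toxicological
    concern (TTC) from SMILES structures via functional-group detection,
    genotoxicity structural alerts and a Cramer decision-tree classifier;
    derives oral equivalent doses (OED) from in vitro AC50 values by
    steady-state in vitro-to-in vivo extrapolation with population Monte
    Carlo; computes NOAEL-based points of departure by an empirical-quantile
    rule; forms margins of exposure (MoE = PoD / upper-95 exposure) and ranks
    chemicals; and provides comparison statistics between the three MoE
    variants. Includes a synthetic-data module that emulates the required
    input tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Open Babel (via the ChemmineOB bindings)
Config/testthat/edition: 3
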
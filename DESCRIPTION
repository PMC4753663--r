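Package: fermentomics
Title: Metabolic Profiling of ABE Fermentation with PLS/VIP Modeling and
    Pathway Networks
Version: 0.1.0
Authors@R:
    person("Fermentomics", "Developers", email = "fermentomics@example.org",
           role = c("aut", "cre"))
Description: An integrated analysis pipeline for time-resolved intracellular
    metabolic profiling of acetone-butanol-ethanol (ABE) fermentations.
    Computes specific growth and butanol production rates and
    internal-standard/biomass-normalized relative abundances from
    fermentation time courses and GC-MS peak-area tables; fits per-response
    partial least squares (NIPALS) regressions with cross-validated Q2,
    regression coefficients and VIP scores; classifies metabolites into the
    nine VIP-by-coefficient-sign types; runs metabolite-set
    over-representation analysis (one-sided Fisher's exact test) with
    pathway-topology impact by out-degree centrality; and assembles the
    resulting bipartite metabolite-pathway network. Includes a synthetic-data
    generator with planted effects so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
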
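Package: hetpath
Title: Heterologous Pathway Design by Network Expansion and Flux Balance
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Designs heterologous production pathways for nonnative
    metabolites in industrial host microorganisms. Iteratively expands a
    host genome-scale metabolic network with candidate reactions from a
    KEGG-ligand-style reaction table until no further metabolite is
    connectable, backtraces the minimal-iteration set of heterologous
    reactions required to reach any connected target, and screens
    producibility and growth-coupled production by flux balance analysis
    (maximum target flux, and target flux at fixed maximal biomass).
    Includes a chi-square category-enrichment comparison of producible
    metabolites across hosts, self-contained worked-example fixtures, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
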
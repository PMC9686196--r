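Package: npadsorb
Title: Faceted Nanoparticle Construction and Anisotropic Polymer
    Adsorption Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds Wulff-constructed face-centered-cubic metal
    nanoparticles and classifies their surface atoms into {111} and {100}
    crystal facets; computes facet-resolved Shrake-Rupley
    solvent-accessible surface areas and adsorption coverage series;
    follows the cluster-formation kinetics of poly(lactic-co-glycolic
    acid) (PLGA) oligomers with hierarchical density-based clustering and
    radial distribution functions; and reconstructs adsorption
    potentials of mean force from umbrella-sampling windows with the
    weighted histogram analysis method, including polar free-energy
    landscapes and an enthalpy-entropy decomposition.  A
    synthetic-trajectory generator with tunable facet affinity and a
    ground-truth event log stands in for the molecular-dynamics engine,
    so every stage of the pipeline is verifiable at the desk.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
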
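Package: leafFBA
Title: Constraint-Based Analysis of Compartmentalized Leaf Metabolism
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for constraint-based analysis of compartmentalized
    plant leaf metabolic models: weighted L1 (total-flux) minimizing flux
    balance analysis with fixed biomass-transporter fluxes and a
    maintenance ATPase demand, flux variability analysis at the fixed
    optimum, RuBisCO carboxylation/oxygenation (Vc/Vo) scans via exact
    reaction lumping, photon-flux (light) scans with a cyclic <=
    non-cyclic photophosphorylation coupling, random-weight enzymatic
    cost ensembles with transporter mode classification, flux-parameter
    correlation, stoichiometric consistency checks (leaks, energy
    generating cycles, elemental balance), tabular and SBML model I/O,
    and a curated synthetic four-compartment (cytosol, chloroplast,
    mitochondrion, peroxisome) core leaf network for download-free
    testing. All linear programs are solved by an internal
    bounded-variable two-phase simplex.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    boot
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'model-methods.R'
    'fba.R'
    'consistency.R'
    'scenarios.R'
    'correlation.R'
    'ensemble.R'
    'fva.R'
    'io-sbml.R'
    'io-table.R'
    'leafFBA-package.R'
    'lp.R'
    'parse.R'
    'synthetic.R'
    'pipeline.R'
    'statistics.R'
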
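Package: hispi
Title: Histidine Pairwise Interactions in Protein Structures
Version: 0.1.0
Authors@R:
    person("hispi", "maintainers", email = "hispi@example.org", role = c("aut", "cre"))
Description: Mines histidine-aromatic and histidine-cation residue pairs from
    protein structures (PDB or mmCIF), computes ring-geometry descriptors
    (centroid distance D, inter-plane angle P, elevation angles T-theta-1 and
    T-theta-2; cation-pi D, theta-1, theta-2), classifies interaction
    geometries as pi-stacked, CH-pi, cation-pi or hydrogen bonded, infers
    histidine tautomer and charge state from deuterium positions in neutron
    structures and from hydrogen-bond patterns under three protonation
    scenarios, stratifies interactions by side-chain pKa category, clusters
    geometry space with full-covariance Gaussian mixtures to select
    representative pairs, and extracts methyl-capped model-compound fragments
    (e.g. 4-methylimidazole, toluene) for quantum-chemistry input. Includes a
    synthetic-structure generator that places residue pairs at exact target
    geometries so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
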
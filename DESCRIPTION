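Package: lbdgeo
Title: Interface Geometry of Dimeric Ligand-Binding Domains and
    Structure-Activity Correlation for AMPA Receptor Modulators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of molecular-dynamics snapshots of the dimeric
    ligand-binding domain (LBD) of ionotropic glutamate (AMPA) receptors.
    Computes the eight centroid-plane geometric descriptors of subunit
    arrangement (inter-plane angle, face heights, distances and lateral
    shifts between the small helix, large helix and central beta-sheet
    elements of each subunit), averages them over a stated trajectory
    window, and correlates them -- together with supplied MM/GBSA binding
    energies -- with allosteric-modulator activity via principal component
    analysis. Also ships an electrophysiology activity registry
    (concentration-response encoding, potentiation metrics, PAM/NAM/NA
    classification), a monoisotopic adduct-ion mass validator for HRMS
    identity checks, RMSD trajectory quality control, and a synthetic dimer
    generator with analytic ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    broom,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
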
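Package: oligoqc
Title: Quality Assessment of Predicted Homo-Oligomeric Protein Assemblies
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to assess predicted structures of homo-oligomeric protein
    assemblies such as the pentamers formed by BTB/POZ-domain (KCTD-like)
    proteins. Implements domain-decomposed reliability statistics on predicted
    aligned error (PAE) matrices with stable/unstable and reliable/partially
    reliable grading, Kabsch superposition with iterative outlier rejection and
    symmetry-aware whole-oligomer chain-mapping search, cyclic (Cn) symmetry
    estimation, buried interface areas by Shrake-Rupley solvent accessibility,
    open-ring detection, axial pore profiles, Calpha-based secondary-structure
    assignment, and multi-model trajectory stability analysis (RMSD series,
    secondary-structure evolution, closest-to-average frame). A synthetic-data
    generator produces assemblies, PAE matrices and trajectories with known
    ground truth so the whole pipeline is verifiable without external model
    archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
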
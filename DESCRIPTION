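Package: EnsembleContacts
Title: Contact Profiling of Structural Ensembles of Protein Dimers
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Per-frame geometric detection of hydrogen bonds, salt bridges
    and hydrophobic/aromatic side-chain contacts in multi-model PDB
    ensembles; aggregation into residue-pair occupancies; partition of
    contacts into the three interfaces of an SH2-domain-mediated
    transcription-factor dimer (intermolecular phosphotyrosine-motif/SH2,
    intermolecular motif/motif, intramolecular motif/SH2); conformational
    clustering with representative-structure selection; covariance-based
    sampling-convergence diagnostics (cosine content); and annotation of
    disease variants onto the computed interfaces. Ships a synthetic
    ensemble generator with exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, jsonlite, pracma
Suggests: testthat (>= 3.0.0), bio3d, optparse, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
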
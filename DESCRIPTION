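Package: h3graft
Title: Antibody CDR-H3 Loop Grafting, Ensemble Sampling and Consensus Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for wholesale redesign of the antibody CDR-H3 loop by virtual
    screening of an H3 sequence library. Candidate H3 sequences of varying length
    are grafted into a parental antibody-antigen complex via stem templates,
    loop conformational ensembles are generated by propensity-guided dihedral
    sampling with cyclic-coordinate-descent closure and refined by
    perturb-and-reclose expansion, antigen binding is scored with a total-energy
    track and an interaction-energy (solvated-interaction-energy style) track
    combined by Boltzmann-weighted ensemble averaging, and candidates are ranked
    by length-stratified median-based consensus Z-scores with Ramachandran,
    hydrogen-bond and curation filters. Includes synthetic fixture generators
    (toy complexes, stem-template libraries, H3 libraries), per-region RMSD/BRMSD
    analysis, sequence identity/similarity, dissociation-constant fold tables and
    retrospective grafting of crystal loop conformations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
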
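Package: leapfs
Title: Literature-Enhanced Automated Prediction of Protein Functional Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein functional sites by combining structure-based
    Dynamics Perturbation Analysis (DPA) with literature mining. DPA decorates
    a protein with surface test points, computes the relative entropy between
    the unperturbed and point-perturbed conformational distributions of an
    anisotropic elastic network model, and clusters high-perturbation points
    into ranked candidate sites. The literature component extracts residue and
    point-mutation mentions from abstracts, grounds them to physical residues
    in linked structures, transfers annotations across multiple sequence
    alignments under fuzzy amino-acid compatibility, and scores sites by
    column conservation and an analytic product-of-uniforms p-value. Includes
    readers for PDB/mmCIF structures, SCOP-style domain definitions,
    MOAD-style ligand validity records and CSA-style catalytic-residue
    records, plus synthetic-data generators so the full pipeline runs without
    any external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    fitdistrplus,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
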
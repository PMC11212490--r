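Package: memsense
Title: Physics-Based Prediction of Peptide-Membrane Interaction and
    Curvature Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative prediction of peptide-membrane interaction from
    amino-acid sequence. A sequence-to-free-energy regressor (an
    attention-based encoder, with an additive linear baseline) estimates the
    relative curvature-sensing free energy of a peptide; a physics layer
    converts it to curvature-dependent membrane-binding free energies and
    binding probabilities, and classifies peptides as non-binders, curvature
    sensors, or membrane binders. A structure-screening module maps
    sensing/binding regions onto protein 3D structures by sliding-window
    scoring combined with solvent-accessible surface area, writing annotated
    PDB files. Includes a synthetic-data generator for training and
    evaluation, and a segment-based classification benchmark (MCC, FDR, FOR).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
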
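Package: ciliacoat
Title: Ciliary Glycocalyx Coat Mapping, Repeat Structure, and Gliding
    Motility Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the scale-like glycoprotein coat of
    Chlamydomonas cilia and its functional consequences. Provides
    membrane contour fitting and distance-transform shell masking of
    tubular membranes in cryo-electron tomograms, rotation-searched
    locally normalized template matching with greedy overlap-exclusion
    filtering of coat particles, segmentation of mucin-like chains into
    structural repeats with Kabsch RMSD matrices, structure-guided
    alignment and conserved-cysteine/disulfide detection, and
    quantification of gliding motility (kymographs, Mann-Whitney U) and
    flow-induced cell detachment (Otsu binarization, occupancy curves,
    Student t tests). Every stage has a matching synthetic-data
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    EBImage,
    bio3d,
    pracma,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
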
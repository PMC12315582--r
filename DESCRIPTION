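Package: qmetric
Title: Q-Score Resolvability Statistics for Cryo-EM Maps and Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-atom Q-scores measure how well each atom of a coordinate
    model is resolved in a 3DEM (cryo-EM) density map, by correlating map
    values sampled radially around the atom with a reference Gaussian
    profile. qmetric computes Q-scores from MRC/CCP4 maps and PDB/mmCIF
    models, aggregates them over residues, nucleotides and ligand
    components, fits an archive-wide cubic regression of mean Q-score
    against reported resolution with mode and 95% enclosure offset curves,
    ranks entries by percentile against an archive (overall and within a
    resolution window), and converts Q-scores to atomic B factors by
    optimizing a scaling factor against the experimental map. Includes a
    synthetic-data generator for toy models, rendered maps and archive
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
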
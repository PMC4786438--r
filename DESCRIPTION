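Package: memscan
Title: Deep Mutational Scanning of Membrane-Protein Insertion and
    Self-Association Energetics
Version: 0.1.0
Authors@R:
    person("memscan", "developers", email = "memscan@example.org",
           role = c("aut", "cre"))
Description: A pipeline for deep-sequencing-based saturation mutagenesis of
    single-pass transmembrane segments: NNS site-saturation library and
    mutagenic primer design, synthetic read/count generation under a known
    Boltzmann selection model, paired-end amplicon variant counting with
    quality filters, conversion of selection coefficients to apparent
    insertion free energies, smoothed per-amino-acid insertion profiles
    over membrane depth with fourth-order polynomial fits, Boltzmann
    amino-acid propensities, atomic-solvation-parameter inference from
    changes in solvent-accessible surface area on ideal helix models, and
    insertion-corrected homodimerization landscapes with structural
    interface filtering of candidate dimer models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
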
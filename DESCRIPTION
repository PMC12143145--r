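Package: orbimine
Title: Gene-Guided Discovery of Orbitides from Transcriptome and LC-MS Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for gene-guided discovery of orbitides (small head-to-tail
    cyclic plant peptides of the Caryophyllaceae type). Mines ribosomal
    precursor-peptide genes from assembled transcript sequences using
    six-frame short-ORF scanning, conserved leader/follower flank profiles
    and the core-peptide rules of the family (5-16 residues, C-terminal Pro
    or Ala); computes exact monoisotopic masses and adduct m/z for cyclic
    and linear peptides; confirms candidates against MS1 peak lists by ppm
    matching and against MS2 spectra by ring-opened b-ion annotation; and
    ranks tailoring-gene candidates by Pearson correlation between tissue
    expression and metabolite abundance. Includes a fully seeded synthetic
    data generator with ground-truth manifests so every stage is testable
    without external downloads, and a single-command discovery pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
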
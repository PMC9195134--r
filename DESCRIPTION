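Package: strepdelim
Title: Genome-Relatedness Thresholds for Streptomyces Species Delineation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares multilocus sequence analysis (MLSA) evolutionary
    distances with whole-genome relatedness indices (ANIm and digital
    DNA-DNA hybridization) across pairs of Streptomyces type strains.
    Ships an 80-pair strain metric table, computes Kimura two-parameter
    distances on concatenated five-gene (atpD, gyrB, recA, rpoB, trpB)
    alignments, calibrates cross-metric exponential regressions with
    threshold inversion, and applies a three-tier species-delineation
    decision rule with dDDH/ANIm fallback and a borderline band that
    defers to polyphasic evidence. Includes seed-deterministic
    simulators for diverged sequence pairs and metric tables with known
    ground truth.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
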
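Package: methdyn
Title: Comparative Analysis of DNA Methylome Reprogramming in Gametes and
    Early Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative whole-genome bisulfite sequencing (WGBS)
    analysis of DNA methylome reprogramming between gametes and early
    embryos across animal species. Reads per-CpG methylation call tables
    (Bismark-style cytosine reports, count-bearing bedGraph), computes
    global and distributional methylation statistics with bisulfite
    non-conversion correction, builds strand-aware TSS metaprofiles,
    segments mosaic methylomes into methylated/unmethylated domains, calls
    differentially methylated promoters (Fisher exact + BH), classifies
    stage dynamics (none/minor/moderate/dramatic, genome-wide demethylation
    flag), and tests gene-set (HOX cluster, homeobox, signaling)
    methylation dynamics and methylation-expression association. Includes a
    calibrated synthetic methylome generator with per-species architecture
    presets (mosaic, sparse, global) and truth labels so every stage of the
    pipeline is testable without sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
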
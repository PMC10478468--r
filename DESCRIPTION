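Package: evohotspot
Title: Comparative Mutation Analysis, Screening Decisions and Monod
    Bioprocess Modelling for Biosensor-Driven Strain Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analytics for chemical-mutagenesis / biosensor-FACS
    strain evolution campaigns in bacteria. Reads a reference genome (FASTA plus
    GFF3 or GenBank annotation) and per-strain variant calls (VCF), assigns each
    variant to a coding sequence, 200 bp promoter window or intergenic space,
    classifies coding effects (synonymous, nonsynonymous, nonsense) and the
    six-class substitution spectrum, applies read-frequency and synonymous-site
    filters, detects mutation hotspot genes across independently evolved strains
    with length-based enrichment and co-mutation statistics, and ranks candidate
    SNPs by hotspot abundance and screen performance. Implements the two-step
    microtiter-plate screen decision logic (control confidence intervals, titer
    and biomass thresholds) and a multi-batch Monod batch-fermentation model with
    shared global parameters, parametric-bootstrap confidence bounds and key
    performance indicators. A fully seeded synthetic-data module generates toy
    genomes, mutagenized strain cohorts with planted hotspots, plate-screen
    tables and noisy batch trajectories so the whole pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
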
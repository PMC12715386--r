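Package: ednasex
Title: Sex-Ratio Estimation from Environmental DNA by Droplet Digital PCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the sex ratio of a population from the relative
    concentrations of a sex-linked common allele and a male-specific allele
    measured by droplet digital PCR (ddPCR) on environmental DNA or mock
    DNA-extract mixtures. Converts per-well droplet counts (or raw droplet
    amplitudes) into Poisson-corrected allele concentrations, pools replicate
    wells into merged "meta-wells" for rare-allele quantification, determines
    limits of detection and quantification from dilution series, and maps
    observed allele ratios onto male-proportion estimates with optional
    biomass correction. A synthetic-data generator simulates individuals,
    eDNA shedding and droplet partitioning so the whole pipeline can be
    exercised and validated without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    car
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
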
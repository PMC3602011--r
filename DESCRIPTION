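Package: trillgauge
Title: Trill Performance, Paternity, and Male Quality Analysis for Birdsong Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for testing whether physically challenging trill traits
    (vocal deviation from an upper-bound performance limit, and trill
    consistency from pairwise spectrogram cross-correlation) signal male
    quality and predict mating and reproductive success in songbirds.
    Covers the full chain from annotated mono audio through per-trill
    acoustic measures, upper-bound regression and orthogonal vocal
    deviation, microsatellite trio-mismatch paternity classification with
    null-allele and mutation allowances, male phenotypic quality
    covariates, and a mixed-model battery with adjusted repeatability,
    within/between-subject decomposition, paired extra-pair versus
    within-pair comparisons, noncentral-t effect-size intervals, and
    table-wise false discovery rate control. A seeded synthetic-data
    generator emulates such field studies (triangular bandwidth-by-rate
    cloud, male-level song repeatability, Mendelian inheritance with null
    alleles, mutation, and extra-pair sires) so every stage is testable
    without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
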
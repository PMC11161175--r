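Package: automixia
Title: Mechanism Inference for Facultative Parthenogenesis from
    Genome-Wide Heterozygosity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for discriminating the
    diploidy-restoration mechanism behind facultative parthenogenesis in
    squamate reptiles. Simulates maternal genomes, meiotic tetrads with
    crossovers, and parthenogenetic offspring under central automixis,
    terminal automixis, or post-meiotic gamete duplication alongside sexual
    controls; calls heterozygous sites from read pileups with a strict
    allele-balance and coverage rule; classifies the mechanism from
    genome-wide and pericentromeric heterozygosity-retention patterns;
    and provides microsatellite parentage exclusion, a population
    heterozygosity-outlier screen based on the generalized extreme
    Studentized deviate (Rosner) test, and mixoploidy quantification from
    erythrocyte counts and DNA-content histograms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
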
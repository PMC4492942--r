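Package: msapdiv
Title: Epigenetic Diversity Analysis of MSAP Band Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of methylation-sensitive amplified polymorphism (MSAP)
    data from paired EcoRI-HpaII and EcoRI-MspI binary band matrices, aimed at
    clonal plant populations. Classifies each sample-by-locus joint band
    pattern into the four isoschizomer methylation states, partitions loci
    into methylation-susceptible and non-methylated sets, and computes
    dominant-marker diversity statistics (band counts, private and locally
    common bands, expected heterozygosity, Shannon diversity), one-level
    analysis of molecular variance with permutation tests on Phi-st,
    Jaccard/UPGMA clustering, distance-matrix subtraction, principal
    coordinates analysis with group dispersion ellipses, and a Bernoulli
    latent-class Gibbs sampler with Evanno delta-K model selection. Includes
    a synthetic-data generator emulating clonal populations whose
    hemi-methylation status varies with an environmental covariate.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    ape,
    vegan,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
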
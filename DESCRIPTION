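Package: snpkin
Title: Likelihood-Ratio Kinship Testing from Dynamically Selected SNPs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pairwise kinship inference for dense SNP data using the
    classical likelihood-ratio framework of forensic relationship testing.
    Markers are selected dynamically per case by a minor-allele-frequency
    filter and a greedy minimum-genetic-distance sweep along sex-averaged
    genetic maps, so that cumulative likelihoods over approximately unlinked
    loci can be multiplied directly.  Joint genotype probabilities are
    conditioned on identity-by-descent coefficients for relationships up to
    second degree, with a transmission mutation/genotyping-error model for
    the parent-child hypothesis.  Includes a pedigree gene-dropping
    simulator (Hardy-Weinberg founders, three-generation families,
    configurable per-allele genotyping error) and an evaluation harness
    (confusion matrices, accuracy, weighted F1, likelihood-ratio margins,
    parameter sweeps) for validating relationship classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
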
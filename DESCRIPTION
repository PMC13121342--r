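Package: poolDUS
Title: Variety Distinctness Testing from Pooled-DNA Allele Frequencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical assessment of distinctness among candidate plant
    varieties (the D of DUS testing) from bulked-DNA SNP genotyping and
    morphophysiological field trials. Reads pooled read counts (TSV or VCF
    with allelic depths), converts them to allele frequencies, applies a
    depth/missing-rate/MAF filtering grid and random-forest imputation, and
    evaluates four molecular distinctness criteria: sequential per-axis ANOVA
    with Fisher's LSD on principal component scores, leave-one-out linear
    discriminant analysis of population pairs, pairwise AMOVA on Nei (1972)
    genetic distances with exhaustive or Monte-Carlo permutation tests, and
    UPGMA clustering with multiscale-bootstrap approximately-unbiased clade
    support. A companion morphophysiological module implements randomized
    complete block ANOVA with the angular transform and protected LSD, and a
    concordance module relates diversity layers by Mantel's test. A synthetic
    data generator with a Balding-Nichols divergence model and binomial
    read-depth sampling emulates tetraploid bulk genotyping designs so every
    criterion can be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    vegan,
    ape,
    jsonlite,
    optparse
Config/testthat/edition: 3
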
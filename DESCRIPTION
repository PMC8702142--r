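Package: forcekin
Title: Forensic SNP Panel Design, Genotype Calling and Linked-Marker Kinship Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for designing and evaluating hybridization-capture SNP panels for
    forensic identification of degraded human remains. Implements the kinship-SNP
    selection cascade (chip intersection, allele-frequency range, genetic-distance
    thinning, LD pruning, population-differentiation and clinical-region filters),
    coverage/allele-balance genotype calling, a multipoint pedigree likelihood engine
    on linked biallelic SNPs (inheritance-vector hidden Markov model) for pairwise,
    missing-person and X-chromosomal likelihood-ratio kinship inference, likelihood-
    ratio distribution simulation studies, naive Bayes and PCA biogeographic ancestry
    prediction, Y-chromosome haplogroup assignment, and phenotype-marker genotype
    encoding. A synthetic-data module generates population allele frequencies,
    pedigree genotypes with recombination over a genetic map, and sequencing
    coverage/allele-count observations, so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
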
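Package: ldpanel
Title: Low-Density SNP Panel Design and Genotype Imputation Accuracy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design of low-density SNP genotyping panels and evaluation of
    genotype imputation accuracy in populations with strong recent founder
    effects, such as the Thoroughbred horse. Implements three tag-SNP
    selection strategies (equidistant in base pairs, equidistant with minor
    allele frequency optimisation by a genetic algorithm, and
    linkage-disequilibrium-unit spacing), construction of LD-unit maps from
    unphased genotypes via a Malecot association model, a diploid
    haplotype-copying hidden Markov model imputation engine with a
    closed-form random-imputation baseline, per-SNP and per-individual
    accuracy metrics with MAF adjustment, and a forward-in-time
    Wright-Fisher simulator of chip-ascertained populations for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
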
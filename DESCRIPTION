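Package: paleoimpute
Title: Simulation and Evaluation of Low-Coverage Ancient Genome Imputation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for assessing genotype imputation of
    low-coverage (ancient) genomes. Simulates phased reference panels with
    diverged, underrepresented populations, diploid targets and trios,
    site-level read counts with deamination-like error on transition sites,
    and binomial coverage downsampling; computes biallelic genotype
    likelihoods and filtered validation calls; imputes with a diploid
    Li-Stephens haplotype-copying hidden Markov model producing genotype
    probabilities, dosages and phased haplotypes; and evaluates results with
    MAF-binned dosage r-squared, per-class discordance, non-reference
    discordance, genotype-probability filtering, trio-based Mendel and
    switch-error rates, pairwise allelic distances, PCA projection shift
    tests, runs-of-homozygosity detection with PLINK-style window semantics,
    and Spearman permutation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    ggplot2,
    generics,
    rlang,
    withr,
    vcfR,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
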
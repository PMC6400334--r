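Package: polyadmix
Title: Polyploid Haplotype Phasing and Admixture Dating for Yeast Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing the admixed, polyploid origin of
    domesticated yeast genomes from short- and long-read variant data:
    ploidy-agnostic greedy phasing of long-read fragments into a variable
    number of haplotypes, allele-balance ploidy classification and
    coverage-based aneuploidy flags, ancestry-diagnostic and group-private
    SNP panels with haplotype painting and switch counting, admixture
    linkage-disequilibrium decay dating in meiotic equivalents, f4
    statistics with block-jackknife standard errors and f4-ratio admixture
    proportions, and molecular-clock divergence arithmetic. A synthetic
    polyploid admixed genome generator provides ground truth for every
    stage, so the full pipeline runs and is tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    vcfR,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
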
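Package: pedassoc
Title: Pedigree-Based Candidate-Gene Association Analysis for Daughter Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Replication-style candidate-gene analysis for half-sib daughter
    designs in dairy cattle. Provides reliability-weighted mixed-model
    single-SNP association on estimated breeding values with a pedigree
    polygenic effect, haplotype trend regression with random polygenic
    effects, EM haplotype-frequency estimation with D-prime confidence
    intervals and Gabriel-style block detection, Hardy-Weinberg and
    Bonferroni screening, allele-substitution variance-explained estimates,
    2^-ddCt relative expression comparison, and a synthetic daughter-design
    data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
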
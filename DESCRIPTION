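Package: SeqAlloc
Title: Sequencing Resource Allocation in Genotyped Pedigreed Populations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Selects focal individuals whose haplotypes collectively represent
    the maximum portion of a population's haplotype diversity, using a greedy
    weighted maximum-coverage search over a windowed haplotype library built
    from phased SNP data, and then allocates a fixed monetary sequencing
    budget across focal families (a focal individual, its parents and
    grandparents) with a differential evolution optimizer so that the
    proportion of population haplotypes phased at the sequence level is
    maximised. Includes a pedigree population simulator with truncation
    selection on true breeding values for generating test populations, and a
    key-ancestors baseline selector based on pedigree-inferred marginal
    genetic contributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), vcfR, optparse, knitr, rmarkdown
Config/testthat/edition: 3
biocViews: Genetics, SNP, Sequencing, ExperimentalDesign
RoxygenNote: 7.3.3
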
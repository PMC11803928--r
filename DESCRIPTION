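Package: fawpopgen
Title: Population Genomics of Fall Armyworm Z-Chromosome Strains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for whole-genome population-genomic analysis of the two
    fall armyworm (Spodoptera frugiperda) Z-chromosome strains (C and R):
    VCF genotype filtering, diagnostic-marker strain calling, windowed
    Weir-Cockerham Fst, nucleotide diversity and Dxy with invariant-site
    denominators, Tajima's D, linkage-disequilibrium decay profiles, a
    permutation test for genomic islands of divergence, composite-likelihood
    and omega-statistic selective-sweep scans, and Patterson-normalised
    principal component analysis. Includes a seeded two-strain cohort
    simulator with Z-linked differentiation, C-strain sub-structure, F1-like
    hybrids, injectable hard sweeps and per-genotype depth/quality noise.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
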
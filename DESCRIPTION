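Package: rohmap
Title: Homozygosity Mapping of Recent-Ancestry Regions from Population
    Haplotype Frequencies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects runs of homozygosity that are likely identical by
    descent from a recent common founder in single patients, groups of
    sharing patients, and affected sib pairs, using only population
    control genotypes. The population frequency of the entire homozygous
    haplotype is evaluated with a first-order Markov chain over pairwise
    haplotype frequencies estimated from controls by an EM algorithm,
    with a rare-haplotype correction for haplotypes unseen in controls.
    Genome-wide empirical significance is assigned by Monte-Carlo null
    distributions built from the best homozygous regions of control
    genomes. Includes a founder-allele inheritance simulator and an
    LD-structured synthetic population generator used for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: SNP, Genetics, VariantDetection, StatisticalMethod
RoxygenNote: 7.3.3
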
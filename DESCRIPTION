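Package: urbansweep
Title: Selective-Sweep Scans and Genotype-Environment Association for
    Paired Urban-Rural Populations
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for multi-population urban-adaptation genomics on phased
    SNP data from paired urban-rural demes: haplotype-homozygosity selection
    statistics (EHH, EHHS, iES, Rsb, nSL, XP-nSL), Weir-Cockerham FST with
    permutation tests, sliding-window percentile outlier detection and
    region merging, latent-factor genotype-environment association with a
    covariance-aware population-frequency model and core-SNP intersection,
    habitat-by-locality effect decomposition, cross-population gene-sharing
    resampling nulls, recombination-rate proxies (windowed LD and intronic
    GC), an urbanisation score from land-cover principal components, and a
    forward Wright-Fisher simulator of paired demes with plantable sweeps
    and polygenic shifts for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    vcfR,
    car,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
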
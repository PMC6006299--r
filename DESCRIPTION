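Package: meiomapr
Title: Crossover Mapping and Recombination Landscape Analysis for
    Low-Coverage Backcross Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers meiotic crossover (CO) positions in backcross (BC1)
    populations genotyped by low-coverage whole-genome sequencing.
    Candidate genotype breakpoints are detected by penalized changepoint
    segmentation of allele frequencies in non-overlapping genomic bins,
    then refined to flanking-marker resolution with a two-state hidden
    Markov model over per-SNP allele depths.  Downstream analyses cover
    sex-specific genetic maps (Haldane distances, Marey tables,
    likelihood-ratio interval tests with multiple-testing corrections),
    crossover hotspot detection with bootstrap representativeness tests,
    and the genomic and chromatin context of crossover sites (nearest-gene
    distances, TSS/TTS metaplots, bootstrap peak-position tests, and
    scaled-region profiles).  A built-in simulator generates BC1
    populations with known crossover ground truth, sparse binomial read
    sampling, polymorphism deserts, structural-polymorphism-like noise,
    planted hotspots, and chromatin tracks, so every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    GenomicRanges,
    IRanges,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
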
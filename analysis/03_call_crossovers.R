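#!/usr/bin/env Rscript
# Stage 3: crossover calling.  Allele frequencies in 200-kbp bins,
# changepoint candidates, windowed HMM refinement (two tau rounds), then
# comparison against the simulator's ground truth.

suppressPackageStartupMessages(library(meiomapr))

mk <- read_markers("results/sim/markers.tsv")
dir.create("results/calls", showWarnings = FALSE, recursive = TRUE)

for (sex in c("male", "female")) {
  flagged <- read.delim(paste0("results/qc/markers_", sex, "_flagged.tsv"))
  mk_pass <- mk[flagged$status == "pass", ]
  rownames(mk_pass) <- NULL
  adm <- read_depth(paste0("results/qc/depth_", sex, "_qc.tsv"), mk_pass)
  calls <- call_crossovers(adm, hmm_config(expected_cos = 4))
  write_co_bed(calls$events, paste0("results/calls/co_", sex, ".bed"))
  write.table(calls$segments, paste0("results/calls/segments_", sex, ".tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  truth <- read.table(paste0("results/sim/truth_", sex, ".bed"),
                      col.names = c("chrom", "start", "pos", "individual"))
  m <- match_crossovers(truth, calls$events)
  message(sprintf(
    "[%s] %d candidates -> %d COs (truth %d); sens %.3f prec %.3f contain %.3f",
    sex, calls$counts["candidates"], nrow(calls$events), m$n_true,
    m$sensitivity, m$precision, m$containment))
  message(sprintf("  per-meiosis estimate: %.1f (simulated rate 8)",
                  cos_per_meiosis(nrow(calls$events), 60)))
  rs <- resolution_summary(calls$events, thresholds = c(2000, 10000))
  hr <- rs[rs$sex != "all", ]
  message(sprintf("  resolution <= 2 kbp: %.0f%%; <= 10 kbp: %.0f%%",
                  100 * rs$fraction[rs$threshold == 2000 & rs$sex == sex],
                  100 * rs$fraction[rs$threshold == 10000 & rs$sex == sex]))
}
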
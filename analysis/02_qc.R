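#!/usr/bin/env Rscript
# Stage 2: marker QC.  Applies the allele-frequency (0.1-0.4), LD
# concordance (median Fisher p < 0.05 in 10-Mbp intervals) and population
# depth filters, and reports the attrition per reason.  The planted
# structural-polymorphism region on chr4 should be removed here.

suppressPackageStartupMessages(library(meiomapr))

mk <- read_markers("results/sim/markers.tsv")
dir.create("results/qc", showWarnings = FALSE, recursive = TRUE)

for (sex in c("male", "female")) {
  adm <- read_depth(paste0("results/sim/depth_", sex, ".tsv"), mk)
  admq <- apply_marker_filters(adm, filter_config())
  qc <- attr(admq, "qc")
  write.table(qc, paste0("results/qc/markers_", sex, "_flagged.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_depth(admq, paste0("results/qc/depth_", sex, "_qc.tsv"))
  tab <- attr(admq, "qc_summary")
  message(sprintf("[%s] %d/%d markers pass (%.1f%%)", sex,
                  nrow(admq$markers), nrow(mk),
                  100 * nrow(admq$markers) / nrow(mk)))
  message("  attrition: ",
          paste(names(tab), tab, sep = "=", collapse = ", "))
  noise <- qc$chrom == "chr4" & qc$pos >= 6e6 & qc$pos <= 6.2e6
  message(sprintf("  planted noise region: %.0f%% of markers removed",
                  100 * mean(qc$status[noise] == "fail")))
}
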
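#!/usr/bin/env Rscript
# Stage 5: crossover hotspots.  5-kbp windows at >= 5-fold the genome
# average per sex, male/female sharing, rate correlation at the union of
# hotspot sites, and the 1000-replicate bootstrap representativeness test.

suppressPackageStartupMessages(library(meiomapr))

chrom_lengths <- rep(10e6, 5)
names(chrom_lengths) <- paste0("chr", 1:5)
n_gametes <- 60
dir.create("results/hotspots", showWarnings = FALSE, recursive = TRUE)

win <- list()
for (sex in c("male", "female")) {
  ev <- read_co_bed(paste0("results/calls/co_", sex, ".bed"))
  win[[sex]] <- window_rates(ev, chrom_lengths, n_gametes)
  hot <- win[[sex]][win[[sex]]$is_hotspot == TRUE, ]
  write.table(hot, paste0("results/hotspots/hotspots_", sex, ".tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("[%s] %d hotspot windows (max fold %.0f)", sex,
                  nrow(hot), suppressWarnings(max(hot$fold, 0))))
}

s <- shared_hotspot_stats(win$male, win$female)
message(sprintf("shared: %d of union %d (%d%%)",
                s$n_shared, s$n_union, s$pct_shared_of_union))

stats <- list(shared = s)
if (s$n_union >= 10) {
  hc <- hotspot_correlation(win$male, win$female)
  b <- bootstrap_correlation(hc$sites, B = 1000, seed = 20260905)
  message(sprintf("male-female rate correlation at %d sites: R = %.3f",
                  hc$n_sites, hc$r))
  message(sprintf("bootstrap: p_count = %.3f, p_z = %.3f (representative if ~0.5)",
                  b$p_count, b$p_z))
  stats$correlation <- list(r = hc$r, n_sites = hc$n_sites,
                            p_count = b$p_count, p_z = b$p_z)
} else {
  message("too few hotspot sites for the correlation bootstrap at this scale")
}
jsonlite::write_json(stats, "results/hotspots/stats.json",
                     auto_unbox = TRUE, digits = NA)
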
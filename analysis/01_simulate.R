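#!/usr/bin/env Rscript
# Stage 1: simulate the study design — two BC1 populations (male and
# female meiosis) over one shared marker map, with sex-specific hotspot
# regions, a polymorphism desert, a structural-polymorphism noise region,
# and two chromatin tracks offset from CO sites.
#
# Population and genome sizes here are a desk-scale rendition of the study
# design (5 chromosomes x 10 Mbp, 60 gametes per sex at 1.5x coverage);
# the acceptance script runs the larger recovery benchmark.

suppressPackageStartupMessages(library(meiomapr))

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(
  chrom_lengths = rep(10e6, 5),
  marker_density = 1,                      # ~1 SNP/kbp
  desert_intervals = data.frame(chrom = "chr2", start = 4e6, end = 5e6),
  coverage_lambda = 1.5, error_eps = 0.01,
  co_per_meiosis_lambda = 8,               # ~4 transmitted COs per gamete
  hotspot_spec = data.frame(
    chrom = c("chr1", "chr1", "chr3"),
    start = c(2.0e6, 7.0e6, 3.0e6),
    end   = c(2.005e6, 7.005e6, 3.005e6),
    fold = 60, sex = c("male", "female", "both")),
  noise_spec = data.frame(chrom = "chr4", start = 6e6, end = 6.2e6,
                          alt_bias = 0.5, cov_mult = 2),
  track_spec = data.frame(name = c("h3k4me3", "nucleosome"),
                          offset = c(-250, 300), jitter_sd = 80),
  seed = 20260901)

mk <- simulate_marker_set(cfg)
write_markers(mk, file.path(out, "markers.tsv"))
message(sprintf("simulated %d markers over %d chromosomes (desert on chr2)",
                nrow(mk), length(cfg$chrom_lengths)))

for (sex in c("male", "female")) {
  g <- simulate_gametes(cfg, mk, 60, sex)
  adm <- simulate_reads(g, cfg)
  write_depth(adm, file.path(out, paste0("depth_", sex, ".tsv")))
  truth_bed <- data.frame(chrom = g$truth$chrom,
                          start = as.integer(g$truth$pos) - 1,
                          end = as.integer(g$truth$pos),
                          individual = g$truth$individual)
  write.table(truth_bed, file.path(out, paste0("truth_", sex, ".bed")),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  message(sprintf("%s population: %d gametes, %d transmitted COs (%.2f/gamete)",
                  sex, 60, nrow(g$truth), nrow(g$truth) / 60))
  if (sex == "male") truth_all <- g$truth else
    truth_all <- rbind(truth_all, g$truth)
}

at <- simulate_annotations_and_tracks(cfg, truth_all)
write_gff3(at$annotations$genes, file.path(out, "genes.gff3"))
for (nm in names(at$tracks))
  write_bedgraph(at$tracks[[nm]], file.path(out, paste0(nm, ".bedgraph")))
message(sprintf("annotations: %d genes, %d TEs; tracks: %s",
                nrow(at$annotations$genes), nrow(at$annotations$tes),
                paste(names(at$tracks), collapse = ", ")))

# the config itself, for downstream stages
cfg_lines <- c(
  paste0("chrom_lengths\t", paste(names(cfg$chrom_lengths),
                                  cfg$chrom_lengths, sep = "=", collapse = ",")),
  paste0("seed\t", cfg$seed))
writeLines(cfg_lines, file.path(out, "config.tsv"))
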
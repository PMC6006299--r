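# End-to-end pipeline glue: simulate -> qc -> call -> map -> hotspots ->
# profiles, with per-stage seeds derived from the global seed so re-running
# any stage from its on-disk inputs is bit-reproducible.

#' Run the full synthetic-to-summary pipeline
#'
#' Simulates male and female BC1 populations from one configuration, applies
#' marker QC, calls crossovers, builds the sex-specific genetic maps and
#' hotspot statistics, and (optionally) the annotation/chromatin profiles.
#' All artifacts can be written under `out_dir`; the returned summary is
#' fully determined by `config` (including its seed).
#'
#' @param config a [sim_config()].
#' @param n_male,n_female population sizes.
#' @param filter_cfg a [filter_config()].
#' @param filter_use which marker filters to apply; the LD screen needs
#'   population sizes in the dozens to have power, so small pilot runs may
#'   restrict to `c("af", "dp")`.
#' @param hmm_cfg an [hmm_config()]; `NULL` derives `expected_cos` from the
#'   configured per-meiosis CO rate.
#' @param with_profiles also simulate annotations/tracks and compute
#'   context profiles.
#' @param out_dir optional output directory for TSV/BED/JSON artifacts.
#' @return list of class `pipeline_result` with elements `male`, `female`
#'   (per-sex call sets and inputs), `map`, `hotspots`, `profiles`,
#'   `summary` (plain machine-readable list).
#' @export
run_pipeline <- function(config, n_male = 50L, n_female = 50L,
                         filter_cfg = filter_config(),
                         filter_use = c("af", "ld", "dp"),
                         hmm_cfg = NULL, with_profiles = TRUE,
                         out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  hmm_cfg <- hmm_cfg %||%
    hmm_config(expected_cos = max(config$co_per_meiosis_lambda / 2, 1))
  markers <- simulate_marker_set(config)

  run_sex <- function(sex, n) {
    g <- simulate_gametes(config, markers, n, sex)
    adm <- simulate_reads(g, config)
    adm_qc <- apply_marker_filters(adm, filter_cfg, use = filter_use)
    calls <- call_crossovers(adm_qc, hmm_cfg)
    list(gametes = g, adm = adm_qc, calls = calls,
         qc = attr(adm_qc, "qc_summary"), n = n)
  }
  male <- run_sex("male", n_male)
  female <- run_sex("female", n_female)

  events <- rbind(male$calls$events, female$calls$events)
  chrom_lengths <- config$chrom_lengths

  map_m <- interval_recombination(male$calls$events, n_male, chrom_lengths)
  map_f <- interval_recombination(female$calls$events, n_female, chrom_lengths)
  tests <- sex_map_tests(map_m, map_f)
  marey_m <- marey_table(map_m)
  marey_f <- marey_table(map_f)

  win_m <- window_rates(male$calls$events, chrom_lengths, n_male)
  win_f <- window_rates(female$calls$events, chrom_lengths, n_female)
  shared <- shared_hotspot_stats(win_m, win_f)
  hs_boot <- NULL
  if (shared$n_union >= 10) {
    sites <- hotspot_correlation(win_m, win_f)
    hs_boot <- bootstrap_correlation(sites$sites, B = 1000L,
                                     seed = derive_seed(config$seed, "hsboot"))
  }

  profiles <- NULL
  if (with_profiles) {
    truth_all <- rbind(male$gametes$truth, female$gametes$truth)
    at <- simulate_annotations_and_tracks(config, truth_all)
    genes <- at$annotations$genes
    dist_g <- distance_to_nearest(events, genes, stranded = TRUE)
    tss <- data.frame(chrom = genes$chrom, pos = genes$tss,
                      strand = genes$strand)
    tss_prof <- anchored_profile(events, tss, chrom_lengths)
    track_peaks <- lapply(at$tracks, function(tr) {
      anchors <- data.frame(chrom = events$chrom, pos = events$midpoint)
      profile_peak(anchored_profile(tr, anchors, chrom_lengths))
    })
    profiles <- list(annotations = at$annotations, tracks = at$tracks,
                     gene_distances = dist_g,
                     frac_within_10kb = fraction_within(dist_g, 10e3),
                     tss_profile = tss_prof, track_peaks = track_peaks)
  }

  summary <- list(
    seed = config$seed,
    n_markers = nrow(markers),
    n_markers_pass = c(male = nrow(male$adm$markers),
                       female = nrow(female$adm$markers)),
    co_count = c(male = nrow(male$calls$events),
                 female = nrow(female$calls$events)),
    cos_per_meiosis = c(male = cos_per_meiosis(nrow(male$calls$events), n_male),
                        female = cos_per_meiosis(nrow(female$calls$events),
                                                 n_female)),
    resolution_2kb = resolution_summary(events)$n[1],
    map_cm_total = c(male = sum(map_m$cm), female = sum(map_f$cm)),
    min_p_bonferroni = suppressWarnings(min(tests$p_bonferroni, na.rm = TRUE)),
    hotspots = shared,
    hotspot_bootstrap = if (!is.null(hs_boot))
      list(r = hs_boot$empirical_r, p_count = hs_boot$p_count,
           p_z = hs_boot$p_z) else NULL,
    frac_within_10kb = if (!is.null(profiles)) profiles$frac_within_10kb
                       else NULL,
    track_peaks = if (!is.null(profiles)) profiles$track_peaks else NULL)

  res <- structure(list(male = male, female = female,
                        map = list(male = map_m, female = map_f,
                                   tests = tests,
                                   marey = list(male = marey_m,
                                                female = marey_f)),
                        hotspots = list(male = win_m, female = win_f,
                                        shared = shared, bootstrap = hs_boot),
                        profiles = profiles, markers = markers,
                        summary = summary),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

#' Write pipeline artifacts to a directory
#'
#' @param res a `pipeline_result`.
#' @param out_dir output directory (created if needed).
#' @export
write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_markers(res$markers, file.path(out_dir, "markers.tsv"))
  for (s in c("male", "female")) {
    write_depth(res[[s]]$adm, file.path(out_dir, paste0("depth_", s, ".tsv")))
    write_co_bed(res[[s]]$calls$events,
                 file.path(out_dir, paste0("co_", s, ".bed")))
    data.table::fwrite(res$map[[s]], file.path(out_dir, paste0("map_", s, ".tsv")),
                       sep = "\t")
    data.table::fwrite(res$map$marey[[s]],
                       file.path(out_dir, paste0("marey_", s, ".tsv")),
                       sep = "\t")
    data.table::fwrite(res$hotspots[[s]][is_hotspot == TRUE],
                       file.path(out_dir, paste0("hotspots_", s, ".tsv")),
                       sep = "\t")
  }
  data.table::fwrite(res$map$tests, file.path(out_dir, "map_sex_tests.tsv"),
                     sep = "\t")
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("pipeline_result (seed ", s$seed, ")\n", sep = "")
  cat("  markers:", s$n_markers, "| pass:",
      paste(names(s$n_markers_pass), s$n_markers_pass, collapse = ", "), "\n")
  cat("  COs:", paste(names(s$co_count), s$co_count, collapse = ", "),
      "| per meiosis:",
      paste(names(s$cos_per_meiosis), s$cos_per_meiosis, collapse = ", "), "\n")
  cat("  hotspots: male", s$hotspots$n_male, "female", s$hotspots$n_female,
      "shared", s$hotspots$n_shared, "\n")
  invisible(x)
}
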
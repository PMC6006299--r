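# Shared in-code fixtures.  Everything is generated programmatically; sizes
# are kept small so the whole suite stays fast.

# hand-built allele-depth matrix from explicit ref/alt matrices
make_adm <- function(ref, alt, pos = NULL, chrom = NULL, chrom_lengths = NULL,
                     sex = "male") {
  nm <- nrow(ref)
  pos <- pos %||% seq(1000, by = 1000, length.out = nm)
  chrom <- chrom %||% rep("chr1", nm)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(split(pos, chrom), function(p) max(p) + 1000,
                            numeric(1))
  }
  markers <- data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
                        status = "pass", stringsAsFactors = FALSE)
  ids <- sprintf("i%03d", seq_len(ncol(ref)))
  colnames(ref) <- ids; colnames(alt) <- ids
  structure(list(markers = markers, individuals = ids,
                 ref = ref, alt = alt, sex = sex,
                 chrom_lengths = chrom_lengths),
            class = "allele_depth_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small default population reused by several tests (one sim, cached)
small_population <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(chrom_lengths = rep(4e6, 2),
                        co_per_meiosis_lambda = 3, seed = 101)
      mk <- simulate_marker_set(cfg)
      g <- simulate_gametes(cfg, mk, 40, "male")
      adm <- simulate_reads(g, cfg)
      cache <<- list(cfg = cfg, markers = mk, gametes = g, adm = adm)
    }
    cache
  }
})

# synthetic event table with given midpoints on one chromosome
make_events <- function(midpoints, chrom = "chr1", individual = NULL,
                        sex = "male", resolution = 1000) {
  n <- length(midpoints)
  data.frame(individual = rep_len(individual %||% sprintf("i%03d", seq_len(n)),
                                  n),
             chrom = rep_len(chrom, n),
             left_bp = midpoints - resolution / 2,
             right_bp = midpoints + resolution / 2,
             midpoint = midpoints, resolution = rep_len(resolution, n),
             sex = rep_len(sex, n), stringsAsFactors = FALSE)
}
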
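# The simulator must reproduce the generative model it claims: Poisson
# marker placement, Poisson CO counts thinned by transmission, hotspot
# intensity folds, Poisson read depths with binomial allele sampling, and
# full determinism under a fixed seed.

test_that("marker counts follow the configured density and avoid deserts", {
  counts <- vapply(1:20, function(s) {
    cfg <- sim_config(chrom_lengths = c(chr1 = 1e6), marker_density = 1,
                      seed = s)
    nrow(simulate_marker_set(cfg))
  }, numeric(1))
  # Poisson(1000): mean of 20 draws within 3 * sqrt(1000/20) of 1000
  expect_lt(abs(mean(counts) - 1000), 3 * sqrt(1000 / 20))

  des <- data.frame(chrom = "chr1", start = 4e5, end = 6e5)
  cfg <- sim_config(chrom_lengths = c(chr1 = 1e6), desert_intervals = des,
                    seed = 3)
  mk <- simulate_marker_set(cfg)
  expect_false(any(mk$pos >= 4e5 & mk$pos <= 6e5))

  # desert covering (almost) the whole chromosome leaves no markers
  all_des <- data.frame(chrom = "chr1", start = 1, end = 1e6 - 1)
  cfg2 <- sim_config(chrom_lengths = c(chr1 = 1e6), desert_intervals = all_des,
                     seed = 3)
  expect_error(simulate_marker_set(cfg2), "no informative markers")
})

test_that("identical configs give bit-identical simulations", {
  cfg <- sim_config(chrom_lengths = rep(2e6, 2), co_per_meiosis_lambda = 4,
                    seed = 11)
  run <- function() {
    mk <- simulate_marker_set(cfg)
    g <- simulate_gametes(cfg, mk, 10, "female")
    adm <- simulate_reads(g, cfg)
    list(mk, g$genotypes, g$truth, adm$ref, adm$alt)
  }
  expect_identical(run(), run())
})

test_that("transmitted CO counts are half the meiotic rate", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 2e6), marker_density = 0.2,
                    co_per_meiosis_lambda = 20, seed = 5)
  mk <- simulate_marker_set(cfg)
  g <- simulate_gametes(cfg, mk, 1000, "male")
  per_gamete <- tabulate(match(g$truth$individual, g$individuals),
                         nbins = 1000)
  # mean transmitted ~ Poisson(10): within 3 SE of 10
  expect_lt(abs(mean(per_gamete) - 10), 3 * sd(per_gamete) / sqrt(1000))
})

test_that("zero CO rate gives single-state gametes", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 1e6), co_per_meiosis_lambda = 0,
                    seed = 6)
  mk <- simulate_marker_set(cfg)
  g <- simulate_gametes(cfg, mk, 20, "male")
  expect_equal(nrow(g$truth), 0)
  expect_true(all(apply(g$genotypes, 2, function(x) length(unique(x))) == 1))
})

test_that("hotspot folds scale local CO density", {
  hs <- data.frame(chrom = "chr1", start = 4e5, end = 5e5, fold = 50)
  # ~1 transmitted CO per gamete so per-gamete interval collisions (which
  # trigger redraws) stay negligible
  cfg <- sim_config(chrom_lengths = c(chr1 = 1e6), marker_density = 0.2,
                    co_per_meiosis_lambda = 2, hotspot_spec = hs, seed = 8)
  mk <- simulate_marker_set(cfg)
  g <- simulate_gametes(cfg, mk, 11000, "male")   # >= 1e4 COs
  expect_gt(nrow(g$truth), 1e4)
  w_in <- 1e5; w_out <- 9e5
  n_in <- sum(g$truth$pos >= 4e5 & g$truth$pos <= 5e5)
  n_out <- nrow(g$truth) - n_in
  ratio <- (n_in / w_in) / (n_out / w_out)
  # expected 50x; allow generous sampling slack
  expect_gt(ratio, 35)
  expect_lt(ratio, 70)
})

test_that("genotype block boundaries equal transmitted COs (conservation)", {
  pop <- small_population()
  g <- pop$gametes
  mk <- pop$markers
  for (j in seq_along(g$individuals)) {
    flips <- 0L
    for (ch in unique(mk$chrom)) {
      geno <- g$genotypes[mk$chrom == ch, j]
      flips <- flips + sum(diff(geno) != 0L)
    }
    truth_n <- sum(g$truth$individual == g$individuals[j])
    expect_identical(flips, as.integer(truth_n))
  }
})

test_that("reads follow the Poisson-binomial sampling model", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 1e6), error_eps = 0,
                    co_per_meiosis_lambda = 0, seed = 9)
  mk <- simulate_marker_set(cfg)
  g <- simulate_gametes(cfg, mk, 20, "male")
  adm <- simulate_reads(g, cfg)
  hom <- g$genotypes == 0L
  expect_true(all(adm$alt[hom] == 0L))       # error-free HOM: never alt

  depth <- adm$ref + adm$alt
  n <- length(depth)
  expect_lt(abs(mean(depth) - 1.5), 3 * sqrt(1.5 / n))

  # high-depth HET markers: alt fraction ~ 1/2 within a binomial CI
  cfg2 <- sim_config(chrom_lengths = c(chr1 = 2e5), coverage_lambda = 30,
                     co_per_meiosis_lambda = 0, seed = 10)
  mk2 <- simulate_marker_set(cfg2)
  g2 <- simulate_gametes(cfg2, mk2, 10, "male")
  adm2 <- simulate_reads(g2, cfg2)
  het <- g2$genotypes == 1L
  tot_alt <- sum(adm2$alt[het]); tot <- sum((adm2$ref + adm2$alt)[het])
  expect_gt(tot, 0)
  expect_lt(abs(tot_alt / tot - 0.5), 3 * sqrt(0.25 / tot))
})

test_that("chromatin tracks put bumps at CO sites plus the offset", {
  truth <- data.frame(chrom = "chr1", pos = c(2e4, 6e4))
  ts <- data.frame(name = c("zero", "shifted"), offset = c(0, -2000),
                   jitter_sd = 0, bump_sd = 150, amplitude = 3,
                   baseline = 1, step = 10)
  cfg <- sim_config(chrom_lengths = c(chr1 = 1e5), track_spec = ts, seed = 12)
  at <- simulate_annotations_and_tracks(cfg, truth)
  v0 <- at$tracks$zero$values$chr1
  peak1 <- (which.max(v0[1:4000]) - 0.5) * 10
  peak2 <- (which.max(v0[4001:10000]) + 4000 - 0.5) * 10
  expect_lt(abs(peak1 - 2e4), 20)
  expect_lt(abs(peak2 - 6e4), 20)
  vs <- at$tracks$shifted$values$chr1
  peak_s <- (which.max(vs[1:4000]) - 0.5) * 10
  expect_lt(abs(peak_s - (2e4 - 2000)), 20)

  # no track_spec -> no tracks; flat baseline when there are no CO sites
  cfg2 <- sim_config(chrom_lengths = c(chr1 = 1e5), track_spec = ts, seed = 13)
  at2 <- simulate_annotations_and_tracks(
    cfg2, data.frame(chrom = character(0), pos = numeric(0)))
  expect_true(all(at2$tracks$zero$values$chr1 == 1))
})
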
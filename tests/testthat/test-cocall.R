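# Crossover inference: binning, changepoint segmentation against
# exhaustive-split oracles, forward-backward against exhaustive path
# enumeration, interval placement, and the per-meiosis arithmetic.

test_that("bin allele frequencies aggregate reads per bin", {
  ref <- matrix(c(8, 3, 0), 3, 1)
  alt <- matrix(c(0, 3, 0), 3, 1)
  adm <- make_adm(ref, alt, pos = c(100e3, 300e3, 500e3),
                  chrom_lengths = c(chr1 = 6e5))
  tr <- bin_allele_frequency(adm, bin_size = 200e3)
  expect_equal(nrow(tr$bins), 3)
  expect_equal(tr$freq[, 1], c(0, 0.5, NA))
  expect_equal(tr$reads[, 1], c(8, 6, 0))
})

test_that("changepoint segmentation matches exhaustive split oracles", {
  # noise-free single step
  y1 <- c(rep(0, 10), rep(0.5, 10))
  expect_equal(changepoint_fit(y1), 10L)
  expect_equal(best_single_split(y1), 10L)
  # constant series: nothing
  expect_length(changepoint_fit(rep(0.3, 25)), 0)
  # noisy single and double steps vs exhaustive search
  set.seed(99)
  for (rep_i in 1:5) {
    k <- sample(5:20, 1)
    y <- c(rep(0, k), rep(0.5, 25 - k)) + rnorm(25, 0, 0.04)
    expect_equal(changepoint_fit(y), best_single_split(y))
  }
  for (rep_i in 1:5) {
    y <- c(rep(0, 12), rep(0.5, 14), rep(0, 12)) + rnorm(38, 0, 0.04)
    expect_equal(changepoint_fit(y), best_two_split(y))
  }
})

test_that("breakpoint detection skips missing bins and flags empty tracks", {
  freq <- matrix(c(0, 0, NA, NA, 0.5, 0.5), 6, 1)
  tr <- structure(list(
    bins = data.table::data.table(chrom = "chr1",
                                  start = seq(1, by = 100, length.out = 6),
                                  end = seq(100, by = 100, length.out = 6)),
    freq = freq, reads = (freq * 0 + 10), individuals = "i1",
    bin_size = 100), class = "bin_freq_track")
  colnames(tr$freq) <- "i1"
  bp <- detect_breakpoints(tr)
  expect_equal(nrow(bp), 1)
  # boundary between last covered bin (2) and next covered bin (5)
  expect_equal(bp$bp, (200 + 401) / 2)

  tr$freq[] <- NA
  expect_warning(bp2 <- detect_breakpoints(tr), "no covered bins")
  expect_equal(nrow(bp2), 0)
})

test_that("forward-backward equals exhaustive path enumeration", {
  cfgs <- 60
  set.seed(123)
  worst <- 0
  for (i in seq_len(cfgs)) {
    n <- sample(2:10, 1)
    depth <- rpois(n, sample(c(0.5, 1.5, 3), 1))
    geno <- cumsum(c(rbinom(1, 1, 0.5), rbinom(n - 1, 1, 0.2))) %% 2
    alt <- rbinom(n, depth, ifelse(geno == 1, 0.5, 0.02))
    pos <- sort(sample.int(1e6, n))
    eps <- runif(1, 0.001, 0.1)
    tau <- 10^runif(1, -8, -4)
    cfg <- hmm_config(error_eps = eps, switch_tau = tau)
    phet <- suppressWarnings(hmm_posterior(alt, depth - alt, pos, cfg))
    ref <- hmm_enum_posterior(alt, depth, pos, eps, tau)
    worst <- max(worst, max(abs(phet - ref)))
  }
  expect_lt(worst, 1e-12)
})

test_that("posteriors are normalized and reduce to the prior without data", {
  cfg <- hmm_config(error_eps = 0.01, switch_tau = 1e-6)
  expect_warning(
    phet <- hmm_posterior(rep(0L, 5), rep(0L, 5), c(1, 10, 100, 1e3, 1e4), cfg),
    "no covered marker")
  expect_equal(unclass(phet), rep(0.5, 5), ignore_attr = TRUE)
  # P(HOM) + P(HET) = 1 is structural: spot-check via the C++ matrix
  r <- meiomapr:::fb_posterior_cpp(c(1L, 0L, 2L), c(2L, 1L, 2L),
                                   c(100, 200, 3000), 0.01, 1e-5)
  expect_lt(max(abs(rowSums(r$posterior) - 1)), 1e-10)
})

test_that("high-depth error-free data localizes the switch exactly", {
  cfg <- hmm_config(error_eps = 0.01, switch_tau = 1e-6, min_posterior = 0.99)
  set.seed(11)
  ok <- 0L
  trials <- 100L
  for (t in seq_len(trials)) {
    n <- 40
    pos <- sort(sample.int(4e4, n))
    k <- sample(10:30, 1)                        # switch after marker k
    geno <- c(rep(0, k), rep(1, n - k))
    depth <- rep(10L, n)
    alt <- as.integer(ifelse(geno == 1, rbinom(n, depth, 0.5), 0))
    alt[geno == 1] <- pmin(pmax(alt[geno == 1], 3L), 7L)  # clearly HET
    phet <- hmm_posterior(alt, depth - alt, pos, cfg)
    dec <- phet > 0.5
    flip <- which(diff(dec) != 0)
    if (length(flip) == 1 && flip == k) ok <- ok + 1L
  }
  expect_identical(ok, trials)
})

test_that("refinement places the CO between flanking informative markers", {
  # dense, error-free, deep coverage: interval = exact flanking gap
  n <- 60
  pos <- seq(1000, by = 1000, length.out = n)
  geno <- c(rep(0, 30), rep(1, 30))
  ref <- matrix(ifelse(geno == 1, 5L, 10L), n, 1)
  alt <- matrix(ifelse(geno == 1, 5L, 0L), n, 1)
  adm <- make_adm(ref, alt, pos = pos, chrom_lengths = c(chr1 = 1e5))
  cand <- data.table::data.table(individual = "i001", chrom = "chr1",
                                 bp = 28000)
  cfg <- hmm_config(error_eps = 0.01, switch_tau = 1e-6)
  ev <- refine_and_call(adm, cand, cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$left_bp, 30000)
  expect_equal(ev$right_bp, 31000)
  expect_equal(ev$resolution, 1000)
  expect_equal(ev$midpoint, 30500)

  # candidate in a uniform region: no CO
  adm_u <- make_adm(matrix(10L, n, 1), matrix(0L, n, 1), pos = pos,
                    chrom_lengths = c(chr1 = 1e5))
  ev_u <- refine_and_call(adm_u, cand, cfg)
  expect_equal(nrow(ev_u), 0)

  # duplicate candidates resolving to the same interval are merged
  cand2 <- data.table::data.table(individual = "i001", chrom = "chr1",
                                  bp = c(28000, 32000))
  ev2 <- refine_and_call(adm, cand2, cfg)
  expect_equal(nrow(ev2), 1)
})

test_that("a CO inside a polymorphism desert spans the desert width", {
  cfg_sim <- sim_config(
    chrom_lengths = c(chr1 = 2e6), marker_density = 2,
    desert_intervals = data.frame(chrom = "chr1", start = 8e5, end = 12e5),
    coverage_lambda = 8, error_eps = 0.005, co_per_meiosis_lambda = 0,
    seed = 55)
  mk <- simulate_marker_set(cfg_sim)
  g <- simulate_gametes(cfg_sim, mk, 1, "male")
  # plant one CO inside the desert by flipping genotypes beyond it
  g$genotypes[mk$pos > 1e6, 1] <- 1L - g$genotypes[mk$pos > 1e6, 1]
  adm <- simulate_reads(g, cfg_sim)
  calls <- call_crossovers(adm, hmm_config(expected_cos = 1))
  expect_equal(nrow(calls$events), 1)
  # flanking markers hug the desert edges: resolution ~ desert width
  expect_gt(calls$events$resolution, 3.9e5)
  expect_lt(calls$events$resolution, 4.3e5)
})

test_that("per-meiosis arithmetic and resolution bookkeeping", {
  expect_equal(cos_per_meiosis(1164, 135), 17.2)
  expect_equal(cos_per_meiosis(1139, 122), 18.7)
  expect_equal(cos_per_meiosis(0, 50), 0.0)
  expect_error(cos_per_meiosis(10, 0), "positive")

  ev <- rbind(make_events(seq(1e4, 5e4, by = 1e4), resolution = 1500),
              make_events(seq(1e5, 2e5, by = 5e4), resolution = 8000,
                          sex = "female"))
  rs <- resolution_summary(ev, thresholds = 2000)
  expect_equal(rs$n[rs$sex == "all"], sum(ev$resolution <= 2000))
  expect_equal(rs$n[rs$sex == "male"], 5)
  expect_equal(rs$n[rs$sex == "female"], 0)
  rs0 <- resolution_summary(make_events(1e4, resolution = 5000),
                            thresholds = 2000)
  expect_equal(rs0$n[1], 0)
})

test_that("higher coverage does not worsen median resolution", {
  med_res <- function(lambda, seed) {
    cfg <- sim_config(chrom_lengths = c(chr1 = 5e6), coverage_lambda = lambda,
                      co_per_meiosis_lambda = 4, seed = seed)
    mk <- simulate_marker_set(cfg)
    g <- simulate_gametes(cfg, mk, 25, "male")
    adm <- simulate_reads(g, cfg)
    calls <- call_crossovers(adm, hmm_config(expected_cos = 2))
    median(calls$events$resolution)
  }
  for (s in c(61, 62)) {
    lo <- med_res(1.5, s)
    hi <- med_res(6, s)
    expect_lte(hi, lo)
  }
})

test_that("structural-polymorphism noise regions yield no crossover calls", {
  ns <- data.frame(chrom = "chr1", start = 2e6, end = 2.2e6, alt_bias = 0.5,
                   cov_mult = 1)
  cfg_sim <- sim_config(chrom_lengths = c(chr1 = 5e6), noise_spec = ns,
                        co_per_meiosis_lambda = 0, seed = 77)
  mk <- simulate_marker_set(cfg_sim)
  g <- simulate_gametes(cfg_sim, mk, 60, "male")
  adm <- simulate_reads(g, cfg_sim)
  admq <- apply_marker_filters(adm)
  # the QC stage removes the spurious-het markers ...
  kept_noise <- sum(admq$markers$pos >= 2e6 & admq$markers$pos <= 2.2e6)
  expect_lt(kept_noise / sum(mk$pos >= 2e6 & mk$pos <= 2.2e6), 0.05)
  # ... so the caller reports no crossovers in a CO-free population
  calls <- call_crossovers(admq, hmm_config(expected_cos = 1,
                                            min_posterior = 0.99))
  expect_equal(nrow(calls$events), 0)
})
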
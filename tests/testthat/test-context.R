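# CO-site context: nearest-feature distances, random-placement enrichment,
# anchored and scaled metaplots, and the bootstrap peak-position test.

test_that("nearest-feature distance follows the sign convention", {
  genes <- data.frame(chrom = "chr1", start = c(1e4, 5e4),
                      end = c(2e4, 6e4), strand = c("+", "-"))
  ev <- make_events(c(15e3, 9.5e3, 20.4e3, 60.5e3, 49.6e3))
  d <- distance_to_nearest(ev, genes, stranded = TRUE)
  expect_equal(d$distance,
               c(0,        # inside first gene
                 -500,     # 500 bp 5' of + gene TSS
                 400,      # 400 bp 3' of + gene
                 -500,     # 500 bp right of - gene = upstream
                 400))     # 400 bp left of - gene = downstream
  # events on unknown chromosomes are skipped with a warning
  ev2 <- rbind(ev, make_events(100, chrom = "chrX"))
  expect_warning(d2 <- distance_to_nearest(ev2, genes), "skipped")
  expect_equal(nrow(d2), 5)
})

test_that("nearest-feature search agrees with the brute-force scan", {
  set.seed(31)
  feats <- do.call(rbind, lapply(c("chr1", "chr2"), function(ch) {
    s <- sort(sample.int(1e6, 30))
    data.frame(chrom = ch, start = s, end = s + sample(500:5000, 30, TRUE),
               strand = sample(c("+", "-"), 30, TRUE))
  }))
  ev <- data.frame(chrom = sample(c("chr1", "chr2"), 100, TRUE),
                   midpoint = runif(100, 1, 1.1e6))
  for (strnd in c(FALSE, TRUE)) {
    d <- distance_to_nearest(ev, feats, stranded = strnd)
    ref <- t(vapply(seq_len(nrow(ev)), function(i)
      brute_nearest(ev$chrom[i], ev$midpoint[i], feats, strnd), numeric(2)))
    expect_equal(d$distance, ref[, 1])
  }
})

test_that("random placement test detects planted gene enrichment", {
  cl <- c(chr1 = 1e6)
  genes <- data.frame(chrom = "chr1",
                      start = seq(1e4, 9.6e5, by = 5e4), strand = "+")
  genes$end <- genes$start + 3000
  # COs planted inside genes
  ev <- make_events(genes$start[1:15] + 1500,
                    individual = sprintf("i%02d", 1:15))
  res <- random_placement_test(ev, genes, cl, n_random = 2000, seed = 4)
  expect_lt(res$p, 1e-3)
  expect_error(random_placement_test(ev, genes, cl, n_random = 0), "positive")
})

test_that("random placement p-values are uniform under the null", {
  cl <- c(chr1 = 2e5)
  genes <- data.frame(chrom = "chr1", start = seq(1e4, 1.8e5, by = 2e4),
                      strand = "+")
  genes$end <- genes$start + 2000
  ps <- vapply(1:100, function(s) {
    ev <- withr::with_seed(s, data.frame(
      chrom = "chr1", midpoint = runif(25, 1, 2e5)))
    random_placement_test(ev, genes, cl, n_random = 400, seed = s + 1000)$p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("anchored density profiles hit planted offsets and conserve counts", {
  cl <- c(chr1 = 1e6)
  anchors <- data.frame(chrom = "chr1", pos = seq(1e4, 9.9e5, by = 2e4),
                        strand = "+")
  ev <- make_events(anchors$pos - 400,
                    individual = sprintf("i%03d", seq_len(nrow(anchors))))
  pr <- anchored_profile(ev, anchors, cl, flank = 2000, bin = 50)
  expect_equal(pr$centers[which.max(pr$value)], -375)   # -400 in bin [-400,-350)
  expect_equal(sum(pr$value), nrow(ev))                 # conservation
  # constant track -> flat profile at the constant
  tr <- structure(list(step = 10,
                       values = list(chr1 = rep(2.5, 1e5))),
                  class = "signal_track")
  pr2 <- anchored_profile(tr, anchors, cl)
  expect_true(all(abs(pr2$value - 2.5) < 1e-12))
})

test_that("anchored profiles are invariant under strand reversal", {
  cl <- c(chr1 = 1e5)
  set.seed(33)
  anchors <- data.frame(chrom = "chr1", pos = sort(sample.int(9e4, 20)) + 5e3,
                        strand = "+")
  # .5 offsets keep midpoints off the bin-edge grid, where half-open
  # binning necessarily breaks the mirror symmetry
  ev <- make_events(rep(anchors$pos, 2) +
                      round(rnorm(40, -300, 200)) + 0.5,
                    individual = sprintf("i%03d", 1:40))
  p_fwd <- anchored_profile(ev, anchors, cl, flank = 1000, bin = 50)
  # mirror the whole coordinate system
  L <- cl[["chr1"]]
  anchors_rev <- transform(anchors, pos = L - pos + 1, strand = "-")
  ev_rev <- ev
  ev_rev$midpoint <- L - ev$midpoint + 1
  p_rev <- anchored_profile(ev_rev, anchors_rev, cl, flank = 1000, bin = 50)
  expect_equal(p_fwd$value, p_rev$value)
})

test_that("signal metaplots recover planted Gaussian bump offsets", {
  ts <- data.frame(name = "mark", offset = 250, jitter_sd = 50)
  cfg <- sim_config(chrom_lengths = c(chr1 = 2e6), track_spec = ts, seed = 41)
  sites <- data.frame(chrom = "chr1",
                      pos = seq(2e4, 1.98e6, by = 1e4))
  at <- simulate_annotations_and_tracks(cfg, sites)
  anchors <- data.frame(chrom = "chr1", pos = sites$pos, strand = "+")
  pr <- anchored_profile(at$tracks$mark, anchors, cfg$chrom_lengths)
  expect_lt(abs(profile_peak(pr) - 250), 50)
})

test_that("bootstrap peak test has power and records all replicates", {
  ts <- data.frame(name = c("a", "b"), offset = c(0, -400), jitter_sd = 60)
  cfg <- sim_config(chrom_lengths = c(chr1 = 2e6), track_spec = ts, seed = 43)
  sites <- data.frame(chrom = "chr1", pos = seq(2e4, 1.98e6, by = 2e4))
  at <- simulate_annotations_and_tracks(cfg, sites)
  anchors <- data.frame(chrom = "chr1", pos = sites$pos, strand = "+")
  res <- profile_peak_test(at$tracks$a, anchors, at$tracks$b, anchors,
                           cfg$chrom_lengths, B = 200, seed = 2)
  expect_length(res$delta_boot, 200)
  expect_lt(res$p_z, 0.01)
  expect_gt(res$delta_obs, 300)
  expect_lt(res$delta_obs, 500)
})

test_that("bootstrap peak test is calibrated under the null", {
  # two independent anchor sets over the same zero-offset track
  ts <- data.frame(name = "a", offset = 0, jitter_sd = 80)
  ps <- vapply(1:12, function(s) {
    cfg <- sim_config(chrom_lengths = c(chr1 = 1e6), track_spec = ts,
                      seed = 100 + s)
    sites <- data.frame(chrom = "chr1", pos = seq(1e4, 9.9e5, by = 5e3))
    at <- simulate_annotations_and_tracks(cfg, sites)
    grp <- rep(1:2, length.out = nrow(sites))
    a1 <- data.frame(chrom = "chr1", pos = sites$pos[grp == 1], strand = "+")
    a2 <- data.frame(chrom = "chr1", pos = sites$pos[grp == 2], strand = "+")
    profile_peak_test(at$tracks$a, a1, at$tracks$a, a2, cfg$chrom_lengths,
                      B = 120, seed = s)$p_z
  }, numeric(1))
  # p should be spread out, not collapsed near 0 or 1
  expect_gt(mean(ps), 0.15)
  expect_gt(sd(ps), 0.05)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("KS distances match the empirical-CDF supremum", {
  set.seed(51)
  a <- rnorm(40); b <- rnorm(40, 1)
  res <- distribution_ks_test(a, b)
  expect_equal(res$D, ks_D_brute(a, b))
  expect_lt(res$p, 0.01)                           # shifted: small p
  same <- distribution_ks_test(a, a)
  expect_equal(same$D, 0)
  expect_error(distribution_ks_test(a[1:5], b), "at least 10")
})

test_that("scaled-region profiles average by fractional overlap", {
  # region of exactly nbins bp with a linear ramp reproduces the ramp
  tr <- structure(list(step = 1, values = list(chr1 = as.numeric(1:100))),
                  class = "signal_track")
  reg <- data.frame(chrom = "chr1", start = 1, end = 100)
  pr <- scaled_region_profile(reg, tr, nbins = 100)
  expect_equal(pr$value, as.numeric(1:100))

  # uniform signal across regions of different lengths stays flat
  tr2 <- structure(list(step = 10, values = list(chr1 = rep(3, 1000))),
                   class = "signal_track")
  regs <- data.frame(chrom = "chr1", start = c(1, 2001), end = c(1500, 9500))
  pr2 <- scaled_region_profile(regs, tr2, nbins = 50)
  expect_true(all(abs(pr2$value - 3) < 1e-9))

  # two-region toy case against hand-computed fractional averages
  tr3 <- structure(list(step = 10, values = list(chr1 = rep(c(1, 2), 50))),
                   class = "signal_track")
  regs3 <- data.frame(chrom = "chr1", start = c(1, 101), end = c(40, 160))
  pr3 <- scaled_region_profile(regs3, tr3, nbins = 2)
  # region 1: bins of 20 bp = [1,20],[21,40] -> means (1.5, 1.5)
  # region 2: bins of 30 bp = [101,130],[131,160]
  #   track over 101..130: 10bp of 1, 10 of 2, 10 of 1 -> 4/3
  #   over 131..160: 10 of 2, 10 of 1, 10 of 2 -> 5/3
  expect_equal(pr3$value, c(mean(c(1.5, 4/3)), mean(c(1.5, 5/3))),
               tolerance = 1e-9)

  # event mode: counts land in the right fractional bins
  ev <- make_events(c(5, 95), individual = c("a", "b"))
  pr4 <- scaled_region_profile(reg, ev, nbins = 10)
  expect_equal(pr4$value[c(1, 10)], c(1, 1))
  expect_equal(sum(pr4$value), 2)
})
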
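# Crossover hotspots: fixed non-overlapping 5-kbp windows whose CO rate is
# at least five-fold the genome average, male/female sharing statistics,
# and the bootstrap representativeness test of the male-female correlation.

#' Per-window crossover rates and hotspot flags
#'
#' Windows are a fixed non-overlapping tiling (sliding windows would
#' inflate shared-site counts).  CO midpoints are counted per window
#' (half-open: a midpoint exactly on a boundary belongs to the right
#' window); the rate is COs per bp per gamete and the fold is the rate over
#' the genome-average rate `total COs / (n_gametes * genome length)`.
#'
#' @param events crossover event table with `chrom` and `midpoint`.
#' @param chrom_lengths named chromosome lengths (bp).
#' @param n_gametes number of gametes in the population.
#' @param window_size window width in bp (default 5 kbp).
#' @param min_fold fold threshold for the hotspot flag (default 5,
#'   inclusive).
#' @return `data.table(chrom, start, end, co_count, rate, fold,
#'   is_hotspot)` tiling the genome.
#' @export
window_rates <- function(events, chrom_lengths, n_gametes,
                         window_size = 5000, min_fold = 5) {
  stopifnot(n_gametes > 0, window_size > 0)
  win <- tile_genome(chrom_lengths, window_size)
  ev <- data.table::as.data.table(events)
  if (nrow(ev)) {
    ev[, wstart := (midpoint %/% window_size) * window_size + 1]
    # midpoint exactly on a boundary (multiple of window_size) falls at the
    # start of the right window under this integer division
    cnt <- ev[, .(co_count = .N), by = .(chrom, wstart)]
    win <- merge(win, cnt, by.x = c("chrom", "start"), by.y = c("chrom", "wstart"),
                 all.x = TRUE)
  } else win[, co_count := 0L]
  win[is.na(co_count), co_count := 0L]
  genome_len <- sum(chrom_lengths)
  avg_rate <- nrow(ev) / (n_gametes * genome_len)
  win[, rate := co_count / (n_gametes * (end - start + 1))]
  win[, fold := if (avg_rate > 0) rate / avg_rate else 0]
  win[, is_hotspot := fold >= min_fold]
  data.table::setorder(win, chrom, start)
  win[]
}

#' Shared-hotspot statistics between two sexes
#'
#' Either pass two window tables from [window_rates()] on the same grid, or
#' the three counts directly.
#'
#' @param male,female window tables, or (`male`, `female`, `shared`) counts
#'   when all three are single numbers.
#' @param shared optional shared count (numeric interface).
#' @return list `n_male`, `n_female`, `n_shared`, `n_union`,
#'   `pct_shared_of_union` (rounded to the nearest integer percent).
#' @export
shared_hotspot_stats <- function(male, female, shared = NULL) {
  if (is.numeric(male) && is.numeric(female) && !is.null(shared)) {
    n_m <- male; n_f <- female; n_s <- shared
  } else {
    if (!identical(male[, .(chrom, start, end)], female[, .(chrom, start, end)]))
      stop("male and female window grids differ")
    n_m <- sum(male$is_hotspot)
    n_f <- sum(female$is_hotspot)
    n_s <- sum(male$is_hotspot & female$is_hotspot)
  }
  n_u <- n_m + n_f - n_s
  list(n_male = n_m, n_female = n_f, n_shared = n_s, n_union = n_u,
       pct_shared_of_union = if (n_u > 0) round(100 * n_s / n_u) else 0)
}

#' Pearson correlation of male and female CO rates at hotspot sites
#'
#' The site set is the union of windows flagged as hotspots in either sex
#' (each site contributing its per-sex rates as computed); optionally
#' restricted to the top fraction of strongest hotspots ranked by
#' `max(male fold, female fold)`.
#'
#' @param male,female window tables from [window_rates()] on the same grid.
#' @param top_frac optional fraction (e.g. 0.1) restricting to the
#'   strongest sites.
#' @return list `r` (Pearson R), `sites` (`data.table` with per-sex rates),
#'   `n_sites`.
#' @export
hotspot_correlation <- function(male, female, top_frac = NULL) {
  stopifnot(nrow(male) == nrow(female))
  sel <- male$is_hotspot | female$is_hotspot
  sites <- data.table::data.table(
    chrom = male$chrom[sel], start = male$start[sel],
    male_rate = male$rate[sel], female_rate = female$rate[sel],
    strength = pmax(male$fold[sel], female$fold[sel]))
  if (!is.null(top_frac)) {
    k <- max(3L, ceiling(top_frac * nrow(sites)))
    sites <- sites[order(-strength)][seq_len(min(k, nrow(sites)))]
  }
  if (nrow(sites) < 3) stop("fewer than 3 hotspot sites")
  if (sd(sites$male_rate) == 0 || sd(sites$female_rate) == 0)
    stop("zero variance in hotspot rates; correlation undefined")
  list(r = cor(sites$male_rate, sites$female_rate),
       sites = sites, n_sites = nrow(sites))
}

#' Bootstrap representativeness test of a hotspot correlation
#'
#' Resamples the hotspot sites with replacement `B` times, recomputing the
#' male-female rate correlation each time.  `p_count` is the frequency of
#' replicate correlations above the empirical value divided by `B`; `p_z`
#' is the matching Z-test tail probability `P(R* > R_emp)` under a normal
#' approximation of the replicate distribution (a representative empirical
#' value sits centrally, giving p near 0.5).  A replicate with zero
#' variance in either vector is redrawn (and counted).
#'
#' @param sites `data.table` with `male_rate` and `female_rate` (e.g. the
#'   `sites` element of [hotspot_correlation()]), at least 10 rows.
#' @param B number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return list of class `bootstrap_result`: `empirical_r`,
#'   `replicate_rs` (length `B`), `p_count`, `p_z`, `n_redrawn`.
#' @export
bootstrap_correlation <- function(sites, B = 1000L, seed = 1L) {
  n <- nrow(sites)
  if (n < 10) stop("need at least 10 sites to bootstrap")
  emp <- cor(sites$male_rate, sites$female_rate)
  withr::with_seed(derive_seed(seed, "hotspot.bootstrap"), {
    rs <- numeric(B)
    redrawn <- 0L
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        mr <- sites$male_rate[idx]; fr <- sites$female_rate[idx]
        if (sd(mr) > 0 && sd(fr) > 0) break
        redrawn <- redrawn + 1L
        if (redrawn > 1000L) stop("degenerate bootstrap: rates have no variance")
      }
      rs[b] <- cor(mr, fr)
    }
    # normal-approximation analogue of p_count: P(R* > empirical R)
    z <- (emp - mean(rs)) / sd(rs)
    structure(list(empirical_r = emp, replicate_rs = rs,
                   p_count = sum(rs > emp) / B,
                   p_z = pnorm(-z), n_redrawn = redrawn),
              class = "bootstrap_result")
  })
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("bootstrap correlation: empirical R =", round(x$empirical_r, 3),
      "| B =", length(x$replicate_rs),
      "| p_count =", x$p_count, "| p_z =", signif(x$p_z, 4), "\n")
  invisible(x)
}
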
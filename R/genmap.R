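# Sex-specific genetic maps: recombination fractions in 1-Mbp intervals,
# Haldane distances, Marey tables, and male-female interval tests with
# multiple-testing corrections.

#' Haldane mapping function
#'
#' Converts a recombination fraction to map distance,
#' d = -50 * ln(1 - 2r) cM (no interference).
#'
#' @param r recombination fraction(s), `0 <= r < 0.5`.
#' @return distance(s) in cM.
#' @export
haldane_cm <- function(r) {
  if (any(r < 0 | r >= 0.5)) stop("r must be in [0, 0.5)")
  -50 * log(1 - 2 * r)
}

#' Per-interval recombination fractions and Haldane distances
#'
#' Each CO is assigned to the fixed interval containing its midpoint
#' (half-open bins); an individual counts as recombinant for an interval if
#' it carries at least one CO midpoint there, so r = recombinants / total.
#' Intervals tile each chromosome even where no marker exists (the
#' supplemental-site convention for polymorphism deserts).
#'
#' @param events crossover event table (needs `individual`, `chrom`,
#'   `midpoint`; a `sex` column is carried through if constant).
#' @param n_total number of individuals genotyped in the population.
#' @param chrom_lengths named chromosome lengths (bp).
#' @param interval_size interval width (bp), default 1 Mbp.
#' @return `data.table(chrom, start, end, n_recombinant, n_total, r, cm)`.
#' @export
interval_recombination <- function(events, n_total, chrom_lengths,
                                   interval_size = 1e6) {
  stopifnot(n_total > 0)
  iv <- tile_genome(chrom_lengths, interval_size)
  ev <- data.table::as.data.table(events)
  if (nrow(ev)) {
    # half-open assignment: a midpoint exactly on a boundary goes right
    ev[, ivstart := (midpoint %/% interval_size) * interval_size + 1]
    cnt <- unique(ev[, .(individual, chrom, ivstart)])[
      , .(n_recombinant = .N), by = .(chrom, ivstart)]
    iv <- merge(iv, cnt, by.x = c("chrom", "start"),
                by.y = c("chrom", "ivstart"), all.x = TRUE)
  } else iv[, n_recombinant := 0L]
  iv[is.na(n_recombinant), n_recombinant := 0L]
  iv[, n_total := n_total]
  iv[, r := n_recombinant / n_total]
  iv[, saturated := r >= 0.5]
  if (any(iv$saturated)) {
    # r >= 0.5 has no finite Haldane distance; saturate at the largest
    # resolvable fraction for this population size (small-sample artifact)
    warning(sum(iv$saturated), " interval(s) with r >= 0.5 were saturated ",
            "at (n - 0.5)/n for the cM conversion")
  }
  iv[, cm := haldane_cm(pmin(r, 0.5 - 0.5 / n_total))]
  data.table::setorder(iv, chrom, start)
  iv[]
}

#' Likelihood-ratio (G) test of equal recombination in two sexes
#'
#' Compares two binomial proportions (recombinant counts out of totals) by
#' the G statistic `2 * sum(O * ln(O/E))` on the 2x2 table, chi-squared
#' with 1 df.
#'
#' @param k1,n1 recombinants and total in population 1 (e.g. male).
#' @param k2,n2 recombinants and total in population 2.
#' @return list with `G` and `p`.
#' @export
sex_interval_lrt <- function(k1, n1, k2, n2) {
  if (k1 > n1 || k2 > n2) stop("recombinant count exceeds total")
  if (n1 <= 0 || n2 <= 0) stop("totals must be positive")
  o <- c(k1, n1 - k1, k2, n2 - k2)
  p_pool <- (k1 + k2) / (n1 + n2)
  e <- c(n1 * p_pool, n1 * (1 - p_pool), n2 * p_pool, n2 * (1 - p_pool))
  nz <- o > 0
  G <- 2 * sum(o[nz] * log(o[nz] / e[nz]))
  list(G = G, p = pchisq(G, df = 1, lower.tail = FALSE))
}

#' Male-female interval tests across a genetic map
#'
#' Runs [sex_interval_lrt()] on every interval and attaches Bonferroni,
#' Benjamini-Hochberg, and Benjamini-Yekutieli adjusted p-values.
#'
#' @param male,female interval tables from [interval_recombination()] on
#'   the same grid.
#' @return `data.table` with per-interval `G`, `p`, `p_bonferroni`,
#'   `p_bh`, `p_by`.
#' @export
sex_map_tests <- function(male, female) {
  stopifnot(nrow(male) == nrow(female),
            all(male$chrom == female$chrom), all(male$start == female$start))
  res <- mapply(function(k1, n1, k2, n2) {
    unlist(sex_interval_lrt(k1, n1, k2, n2))
  }, male$n_recombinant, male$n_total, female$n_recombinant, female$n_total)
  out <- data.table::data.table(
    chrom = male$chrom, start = male$start, end = male$end,
    male_r = male$r, female_r = female$r,
    G = res["G", ], p = res["p", ])
  out[, p_bonferroni := p.adjust(p, "bonferroni")]
  out[, p_bh := p.adjust(p, "BH")]
  out[, p_by := p.adjust(p, "BY")]
  out[]
}

#' Marey table: cumulative genetic vs physical position
#'
#' @param map interval table from [interval_recombination()].
#' @return `data.table(chrom, pos_mbp, cm_cumulative)`, monotone
#'   non-decreasing per chromosome; the endpoint equals the chromosome's
#'   total map length.
#' @export
marey_table <- function(map) {
  m <- data.table::as.data.table(map)
  data.table::setorder(m, chrom, start)
  m[, .(pos_mbp = end / 1e6, cm_cumulative = cumsum(cm)), by = chrom]
}
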
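# Genomic and chromatin context of crossover sites: distances to nearest
# features, anchored metaplots (TSS/TTS/CO-centered), bootstrap
# peak-position tests, and scaled-region profiles.

# track lookup: mean signal over [from, to] bp on one chromosome (closed
# range, bp units); NA outside the chromosome
track_range_mean <- function(track, chrom, from, to) {
  v <- track$values[[chrom]]
  if (is.null(v)) return(NA_real_)
  s <- track$step
  i0 <- max(1L, floor((from - 1) / s) + 1L)
  i1 <- min(length(v), floor((to - 1) / s) + 1L)
  if (i1 < i0) return(NA_real_)
  mean(v[i0:i1])
}

#' Signed distance from each CO midpoint to the nearest feature
#'
#' Distance is 0 when the midpoint lies inside a feature, otherwise the bp
#' gap to the nearest feature edge.  With `stranded = TRUE` the sign is
#' strand-aware: positions upstream of the feature (5' side) are negative.
#' Unstranded features use plain positive gaps with 0 inside.
#'
#' @param events crossover event table with `chrom` and `midpoint`.
#' @param features `data.frame(chrom, start, end[, strand])`.
#' @param stranded use the strand-aware sign convention.
#' @return `data.table` of the events with `distance` and
#'   `nearest_feature` (row index into `features`); events on chromosomes
#'   absent from the annotation are dropped with a warning.
#' @export
distance_to_nearest <- function(events, features, stranded = FALSE) {
  ev <- data.table::as.data.table(events)
  known <- ev$chrom %in% unique(features$chrom)
  if (!all(known)) {
    warning(sum(!known), " event(s) on chromosomes absent from the ",
            "annotation were skipped")
    ev <- ev[known]
  }
  ev[, distance := NA_real_]
  ev[, nearest_feature := NA_integer_]
  for (ch in unique(ev$chrom)) {
    fidx <- which(features$chrom == ch)
    fs <- features[fidx, , drop = FALSE]
    ord <- order(fs$start)
    fs <- fs[ord, , drop = FALSE]
    fidx <- fidx[ord]
    erows <- which(ev$chrom == ch)
    m <- ev$midpoint[erows]
    # candidate features: the one starting at/before m and its neighbors
    i <- findInterval(m, fs$start)
    best_d <- rep(Inf, length(m))
    best_j <- rep(NA_integer_, length(m))
    for (off in -1:1) {
      j <- i + off
      valid <- j >= 1 & j <= nrow(fs)
      gap <- rep(Inf, length(m))
      jj <- j[valid]
      mm <- m[valid]
      g <- ifelse(mm < fs$start[jj], fs$start[jj] - mm,
                  ifelse(mm > fs$end[jj], mm - fs$end[jj], 0))
      gap[valid] <- g
      upd <- gap < best_d
      best_d[upd] <- gap[upd]
      best_j[upd] <- j[upd]
    }
    sgn <- rep(1, length(m))
    if (stranded && !is.null(fs$strand)) {
      left <- m < fs$start[best_j]
      right <- m > fs$end[best_j]
      minus <- fs$strand[best_j] == "-"
      # upstream (5' side) is negative: left of a + feature, right of a -
      sgn[left & !minus] <- -1
      sgn[right & minus] <- -1
    }
    ev$distance[erows] <- sgn * best_d
    ev$nearest_feature[erows] <- fidx[best_j]
  }
  ev[]
}

#' Fraction of COs within a distance of a feature, and the proximal genes
#'
#' @param distances output of [distance_to_nearest()].
#' @param threshold bp threshold (default 10 kbp).
#' @return fraction of events with `|distance| <= threshold`.
#' @export
fraction_within <- function(distances, threshold = 10e3) {
  mean(abs(distances$distance) <= threshold)
}

#' Unique genes near high-resolution crossovers
#'
#' @param events crossover events (with `resolution` if
#'   `max_resolution` is used).
#' @param genes gene table with `gene_id`.
#' @param threshold bp distance threshold (default 10 kbp).
#' @param max_resolution optional cap on event resolution (e.g. 2000 bp to
#'   restrict to precisely mapped COs).
#' @return character vector of gene ids.
#' @export
co_proximal_genes <- function(events, genes, threshold = 10e3,
                              max_resolution = NULL) {
  ev <- events
  if (!is.null(max_resolution)) ev <- ev[ev$resolution <= max_resolution, ]
  d <- distance_to_nearest(ev, genes)
  hit <- !is.na(d$distance) & abs(d$distance) <= threshold
  unique(genes$gene_id[d$nearest_feature[hit]])
}

#' Test CO-feature proximity against random placement
#'
#' Places `n_random` midpoints uniformly over the genome and compares the
#' observed |distance-to-nearest-feature| distribution against the random
#' one with a two-sided Mann-Whitney-Wilcoxon test.
#'
#' @param events crossover event table.
#' @param features feature table as in [distance_to_nearest()].
#' @param chrom_lengths named chromosome lengths (bp).
#' @param n_random number of random midpoints (> 0).
#' @param seed integer seed.
#' @return list `p`, `observed` and `random` |distance| vectors.
#' @export
random_placement_test <- function(events, features, chrom_lengths,
                                  n_random, seed = 1L) {
  if (n_random <= 0) stop("n_random must be positive")
  obs <- abs(distance_to_nearest(events, features)$distance)
  rnd <- withr::with_seed(derive_seed(seed, "random.placement"), {
    ch <- sample(names(chrom_lengths), n_random, replace = TRUE,
                 prob = chrom_lengths / sum(chrom_lengths))
    data.frame(chrom = ch,
               midpoint = floor(runif(n_random, 1, chrom_lengths[ch] + 1)),
               stringsAsFactors = FALSE)
  })
  rdist <- abs(distance_to_nearest(rnd, features)$distance)
  p <- suppressWarnings(wilcox.test(obs, rdist)$p.value)
  list(p = p, observed = obs, random = rdist)
}

# per-anchor contribution matrix for an anchored profile:
# rows = anchors, cols = relative bins; NA where truncated at a chromosome
# edge.  x is a signal_track (mean signal per bin) or an event table
# (CO midpoint counts per bin).
anchor_matrix <- function(x, anchors, flank, bin, chrom_lengths) {
  nb <- as.integer(2 * flank / bin)
  stopifnot(nb >= 1)
  n <- nrow(anchors)
  M <- matrix(NA_real_, n, nb)
  strand <- anchors$strand %||% rep("+", n)
  is_track <- inherits(x, "signal_track")
  if (!is_track) {
    ev <- data.table::as.data.table(x)
    pos_by_chrom <- split(ev$midpoint, ev$chrom)
    pos_by_chrom <- lapply(pos_by_chrom, sort)
  }
  for (a in seq_len(n)) {
    ch <- anchors$chrom[a]
    p <- anchors$pos[a]
    L <- chrom_lengths[[ch]]
    if (is.null(L)) next
    lo <- p - flank + (seq_len(nb) - 1) * bin    # bin left edges, rel coords
    hi <- lo + bin - 1
    inside <- lo >= 1 & hi <= L
    if (is_track) {
      vals <- rep(NA_real_, nb)
      for (j in which(inside))
        vals[j] <- track_range_mean(x, ch, lo[j], hi[j])
    } else {
      mp <- pos_by_chrom[[ch]]
      vals <- rep(NA_real_, nb)
      if (!is.null(mp)) {
        # half-open bins [lo, lo + bin)
        cnt <- findInterval(lo + bin - 1e-9, mp) - findInterval(lo - 1e-9, mp)
        vals[inside] <- cnt[inside]
      } else vals[inside] <- 0
    }
    if (strand[a] == "-") vals <- rev(vals)
    M[a, ] <- vals
  }
  M
}

#' Anchored metaplot profile
#'
#' Aggregates either CO midpoints (density mode) or a chromatin signal
#' track (signal mode) in fixed relative bins around a set of anchors
#' (TSS, TTS, or CO midpoints), flipping minus-strand anchors so that
#' negative coordinates are always upstream.  Bins truncated at a
#' chromosome edge are dropped from that anchor's contribution and the
#' per-bin contributor count is reported.
#'
#' @param x a `signal_track`, or an event table with `chrom` and
#'   `midpoint`.
#' @param anchors `data.frame(chrom, pos[, strand])`.
#' @param chrom_lengths named chromosome lengths (bp).
#' @param flank half-width of the window (bp, default 2 kbp).
#' @param bin bin width (bp, default 50).
#' @return object of class `co_profile`: `centers` (relative bp),
#'   `value` (summed CO count per bin in density mode; mean signal in
#'   signal mode), `n` (contributing anchors per bin), `mode`, plus the
#'   per-anchor matrix as attribute `per_anchor`.
#' @export
anchored_profile <- function(x, anchors, chrom_lengths, flank = 2000,
                             bin = 50) {
  stopifnot(nrow(anchors) >= 1, flank > 0, bin > 0, 2 * flank %% bin == 0)
  M <- anchor_matrix(x, anchors, flank, bin, chrom_lengths)
  mode <- if (inherits(x, "signal_track")) "signal" else "density"
  value <- if (mode == "signal") colMeans(M, na.rm = TRUE)
           else colSums(M, na.rm = TRUE)
  structure(list(centers = -flank + (seq_len(ncol(M)) - 0.5) * bin,
                 value = value, n = colSums(!is.na(M)),
                 mode = mode, bin = bin, flank = flank),
            per_anchor = M, class = "co_profile")
}

#' @export
print.co_profile <- function(x, ...) {
  cat("co_profile (", x$mode, "): ", length(x$centers), " bins of ",
      x$bin, " bp, peak at ", round(profile_peak(x), 1), " bp\n", sep = "")
  invisible(x)
}

# moving-average smoothing (window w bins, shrunk at the edges)
smooth_ma <- function(y, w = 3L) {
  if (w <= 1L) return(y)
  h <- (w - 1L) %/% 2L
  n <- length(y)
  vapply(seq_len(n), function(i) {
    idx <- max(1L, i - h):min(n, i + h)
    mean(y[idx], na.rm = TRUE)
  }, numeric(1))
}

#' Peak position of a profile
#'
#' Argmax of the 3-bin moving-average smoothed profile (leftmost on exact
#' ties), refined by parabolic interpolation through the argmax and its
#' neighbors so that peak positions are continuous rather than quantized
#' to the bin grid.
#'
#' @param profile a `co_profile`, or a numeric vector with `centers`.
#' @param smooth moving-average window in bins (default 3; 1 = raw argmax).
#' @param interpolate logical; parabolic sub-bin refinement.
#' @param centers bin centers when `profile` is a plain vector.
#' @return peak position in profile coordinates (bp).
#' @export
profile_peak <- function(profile, smooth = 3L, interpolate = TRUE,
                         centers = NULL) {
  if (inherits(profile, "co_profile")) {
    y <- profile$value
    centers <- profile$centers
  } else y <- profile
  stopifnot(length(y) == length(centers))
  ys <- smooth_ma(y, smooth)
  i <- which.max(ys)                       # leftmost argmax on ties
  pk <- centers[i]
  if (interpolate && i > 1L && i < length(ys)) {
    denom <- ys[i - 1] - 2 * ys[i] + ys[i + 1]
    if (is.finite(denom) && denom < 0) {
      off <- 0.5 * (ys[i - 1] - ys[i + 1]) / denom
      off <- max(-0.5, min(0.5, off))
      pk <- pk + off * (centers[2] - centers[1])
    }
  }
  pk
}

#' Bootstrap test of a peak-position difference between two profiles
#'
#' Resamples each group's anchors with replacement `B` times, recomputes
#' the smoothed profile peak per replicate, and applies a two-sided Z-test
#' to the replicate peak-difference distribution against zero.
#'
#' @param x_a,x_b data for the two groups (each a `signal_track` or event
#'   table, as in [anchored_profile()]).
#' @param anchors_a,anchors_b anchor tables for the two groups.
#' @param chrom_lengths named chromosome lengths (bp).
#' @param flank,bin,smooth profile parameters.
#' @param B bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return list `delta_obs` (observed peak difference, a minus b, bp),
#'   `delta_boot` (length `B`), `p_z`, `peak_a`, `peak_b`.
#' @export
profile_peak_test <- function(x_a, anchors_a, x_b, anchors_b, chrom_lengths,
                              flank = 2000, bin = 50, smooth = 3L,
                              B = 1000L, seed = 1L) {
  pa <- anchored_profile(x_a, anchors_a, chrom_lengths, flank, bin)
  pb <- anchored_profile(x_b, anchors_b, chrom_lengths, flank, bin)
  Ma <- attr(pa, "per_anchor")
  Mb <- attr(pb, "per_anchor")
  centers <- pa$centers
  peak_of <- function(M, idx) {
    v <- colMeans(M[idx, , drop = FALSE], na.rm = TRUE)
    profile_peak(v, smooth = smooth, centers = centers)
  }
  peak_a <- profile_peak(pa, smooth = smooth)
  peak_b <- profile_peak(pb, smooth = smooth)
  withr::with_seed(derive_seed(seed, "peak.bootstrap"), {
    delta <- numeric(B)
    na <- nrow(Ma); nb_ <- nrow(Mb)
    for (b in seq_len(B)) {
      delta[b] <- peak_of(Ma, sample.int(na, na, replace = TRUE)) -
                  peak_of(Mb, sample.int(nb_, nb_, replace = TRUE))
    }
    sdd <- sd(delta)
    z <- if (sdd > 0) mean(delta) / sdd else Inf * sign(mean(delta))
    list(delta_obs = peak_a - peak_b, delta_boot = delta,
         p_z = if (is.finite(z)) 2 * pnorm(-abs(z))
               else if (mean(delta) == 0) 1 else 0,
         peak_a = peak_a, peak_b = peak_b)
  })
}

#' Two-sample Kolmogorov-Smirnov test of CO position distributions
#'
#' @param a,b numeric vectors of relative CO positions (at least 10 each).
#' @return list `D`, `p`.
#' @export
distribution_ks_test <- function(a, b) {
  if (length(a) < 10 || length(b) < 10)
    stop("need at least 10 positions per sample")
  kt <- suppressWarnings(ks.test(a, b))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Scaled-region profile
#'
#' Maps each region to the unit interval and averages the signal (or counts
#' CO midpoints) in `nbins` equal fractional bins; regions contribute with
#' equal weight regardless of physical length.  Signal averaging uses exact
#' fractional overlap of track bins via the cumulative integral, so regions
#' shorter than `nbins` bp are interpolated (and flagged).
#'
#' @param regions `data.frame(chrom, start, end[, strand])`; minus-strand
#'   regions are flipped.
#' @param x a `signal_track` or event table with `chrom`, `midpoint`.
#' @param nbins number of fractional bins (default 100; e.g. 30 for
#'   nucleosome tracks).
#' @return a `co_profile` with `centers` in region fractions (0..1);
#'   attribute `short_regions` counts regions shorter than `nbins` bp.
#' @export
scaled_region_profile <- function(regions, x, nbins = 100L) {
  stopifnot(nrow(regions) >= 1, nbins >= 1)
  is_track <- inherits(x, "signal_track")
  if (!is_track) ev <- data.table::as.data.table(x)
  M <- matrix(NA_real_, nrow(regions), nbins)
  short <- 0L
  for (i in seq_len(nrow(regions))) {
    ch <- regions$chrom[i]
    s <- regions$start[i]; e <- regions$end[i]
    L <- e - s + 1
    if (L < nbins) short <- short + 1L
    if (is_track) {
      v <- x$values[[ch]]
      if (is.null(v)) next
      step <- x$step
      # cumulative integral of the piecewise-constant track (bp units)
      grid <- seq(0, length(v)) * step
      cum <- c(0, cumsum(v) * step)
      edges <- s - 1 + (0:nbins) * L / nbins
      Iv <- stats::approx(grid, cum, xout = pmin(pmax(edges, 0), max(grid)),
                          rule = 2)$y
      M[i, ] <- diff(Iv) / (L / nbins)
    } else {
      mp <- ev$midpoint[ev$chrom == ch & ev$midpoint >= s & ev$midpoint <= e]
      frac <- (mp - s) / L
      M[i, ] <- tabulate(pmin(floor(frac * nbins) + 1L, nbins), nbins)
    }
    if (!is.null(regions$strand) && regions$strand[i] == "-")
      M[i, ] <- rev(M[i, ])
  }
  structure(list(centers = (seq_len(nbins) - 0.5) / nbins,
                 value = colMeans(M, na.rm = TRUE),
                 n = colSums(!is.na(M)),
                 mode = if (is_track) "scaled_signal" else "scaled_density",
                 bin = 1 / nbins, flank = NA),
            per_anchor = M, short_regions = short, class = "co_profile")
}
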
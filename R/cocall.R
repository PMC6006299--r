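# Crossover inference: per-individual allele frequencies in non-overlapping
# 200-kbp bins, penalized changepoint segmentation for candidate genotype
# breakpoints, then a two-state HMM over all SNPs in a 10-Mbp window
# centered on each candidate to place the CO between flanking markers.

#' HMM configuration for CO refinement
#'
#' @param window width (bp) of the marker window centered on each candidate
#'   breakpoint (default 10 Mbp).
#' @param error_eps emission miscall rate: probability that a read at a HOM
#'   marker reports the alternate allele.
#' @param switch_tau per-bp state-switch intensity; the transition
#'   probability over an inter-marker gap of d bp is
#'   `0.5 * (1 - exp(-2 * switch_tau * d))`.  `NULL` derives it from
#'   `expected_cos` over the genome length (a genome-wide cM/Mbp prior) and
#'   one round of re-estimation from the first call set.
#' @param expected_cos expected transmitted COs per gamete used for the
#'   `switch_tau` prior.
#' @param min_posterior posterior confidence required of the flanking
#'   markers that anchor a reported CO interval, and of the decoded
#'   segments on both sides of a state flip.
#' @return object of class `hmm_config`.
#' @export
hmm_config <- function(window = 10e6, error_eps = 0.01, switch_tau = NULL,
                       expected_cos = 10, min_posterior = 0.99) {
  stopifnot(window > 0, error_eps >= 0, error_eps < 0.5,
            is.null(switch_tau) || (switch_tau > 0 && switch_tau < 0.5),
            min_posterior > 0.5, min_posterior < 1)
  structure(list(window = window, error_eps = error_eps,
                 switch_tau = switch_tau, expected_cos = expected_cos,
                 min_posterior = min_posterior),
            class = "hmm_config")
}

#' Allele frequency in non-overlapping genomic bins
#'
#' Per individual, chromosome and bin: f = sum(alt)/(sum(alt)+sum(ref)) over
#' contained markers; `NA` where the bin has no reads.
#'
#' @param adm an `allele_depth_matrix` (markers should already be QC'd).
#' @param bin_size bin width in bp (default 200 kbp).
#' @return list of class `bin_freq_track`: `bins` (`data.table` chrom,
#'   start, end), `freq` and `reads` (bins x individuals matrices),
#'   `individuals`, `bin_size`.
#' @export
bin_allele_frequency <- function(adm, bin_size = 200e3) {
  stopifnot(bin_size > 0)
  if (nrow(adm$markers) == 0)
    stop("allele-depth matrix has no markers (did QC remove them all?)")
  bins <- tile_genome(adm$chrom_lengths, bin_size)
  bins[, id := .I]
  key <- paste0(bins$chrom, ":", bins$start)
  mkey <- paste0(adm$markers$chrom, ":",
                 ((adm$markers$pos - 1) %/% bin_size) * bin_size + 1)
  bid <- match(mkey, key)
  galt <- rowsum(adm$alt, bid, reorder = TRUE)
  gref <- rowsum(adm$ref, bid, reorder = TRUE)
  freq <- matrix(NA_real_, nrow(bins), length(adm$individuals),
                 dimnames = list(NULL, adm$individuals))
  reads <- matrix(0, nrow(bins), length(adm$individuals),
                  dimnames = list(NULL, adm$individuals))
  rows <- as.integer(rownames(galt))
  tot <- galt + gref
  freq[rows, ] <- ifelse(tot > 0, galt / tot, NA_real_)
  reads[rows, ] <- tot
  structure(list(bins = bins, freq = freq, reads = reads,
                 individuals = adm$individuals, bin_size = bin_size),
            class = "bin_freq_track")
}

#' Penalized least-squares changepoint segmentation
#'
#' Fits a piecewise-constant mean to a numeric series by exact dynamic
#' programming (optimal partitioning), minimizing residual sum of squares
#' plus `penalty` per changepoint — the same objective the mean-shift
#' family of segmentation methods optimizes, but solved exactly and
#' deterministically.
#'
#' @param y numeric series (no NAs).
#' @param penalty per-changepoint penalty; `NULL` uses a BIC-type default
#'   `3 * sigma^2 * log(n)` with sigma estimated robustly from successive
#'   differences.
#' @return integer vector of changepoint indices `k` meaning a mean shift
#'   between `y[k]` and `y[k+1]` (empty if none).
#' @export
changepoint_fit <- function(y, penalty = NULL) {
  n <- length(y)
  if (n < 2) return(integer(0))
  if (is.null(penalty)) {
    sigma <- mad(diff(y)) / sqrt(2)
    sigma <- max(sigma, 1e-3)      # floor so noise-free steps are found
    penalty <- 3 * sigma^2 * log(n)
  }
  cs <- c(0, cumsum(y))
  cs2 <- c(0, cumsum(y^2))
  rss <- function(i, j) {  # segment y[i..j]
    s <- cs[j + 1] - cs[i]
    (cs2[j + 1] - cs2[i]) - s * s / (j - i + 1)
  }
  F <- c(-penalty, rep(Inf, n))
  last <- integer(n)
  for (t in seq_len(n)) {
    s <- seq_len(t)
    cand <- F[s] + penalty +
      (cs2[t + 1] - cs2[s]) - (cs[t + 1] - cs[s])^2 / (t - s + 1)
    best <- which.min(cand)
    F[t + 1] <- cand[best]
    last[t] <- best - 1L            # previous changepoint index
  }
  cps <- integer(0)
  t <- last[n]
  while (t > 0) { cps <- c(t, cps); t <- last[t] }
  cps
}

#' Detect candidate genotype breakpoints from a bin-frequency track
#'
#' Missing bins are skipped; a changepoint between consecutive non-missing
#' bins is reported at the genomic boundary between them.
#'
#' @param track a `bin_freq_track`.
#' @param individuals subset of individuals (default all).
#' @param penalty passed to [changepoint_fit()].
#' @return `data.table(individual, chrom, bp)` of candidate breakpoints.
#' @export
detect_breakpoints <- function(track, individuals = NULL, penalty = NULL) {
  individuals <- individuals %||% track$individuals
  chroms <- unique(track$bins$chrom)
  out <- list()
  for (ind in individuals) {
    fr <- track$freq[, ind]
    for (ch in chroms) {
      idx <- which(track$bins$chrom == ch)
      ok <- idx[!is.na(fr[idx])]
      if (length(ok) < 2) {
        if (length(ok) == 0)
          warning("no covered bins for ", ind, " on ", ch)
        next
      }
      cps <- changepoint_fit(fr[ok], penalty)
      if (length(cps)) {
        # boundary between non-missing bin k and the next non-missing bin
        bp <- (track$bins$end[ok[cps]] + track$bins$start[ok[cps + 1L]]) / 2
        out[[length(out) + 1L]] <-
          data.table::data.table(individual = ind, chrom = ch, bp = bp)
      }
    }
  }
  if (length(out)) data.table::rbindlist(out)
  else data.table::data.table(individual = character(0),
                              chrom = character(0), bp = numeric(0))
}

#' Posterior genotype probabilities from a two-state HMM
#'
#' Forward-backward over HOM/HET states with binomial read emissions
#' (`p_alt = error_eps` for HOM, 0.5 for HET; zero-depth markers emit
#' likelihood 1 in both states) and distance-scaled transitions.  Returns
#' per-marker `P(HET)`; `P(HOM) + P(HET) = 1` by construction.
#'
#' @param alt,ref integer read counts at the window's markers (one
#'   individual).
#' @param pos marker positions (bp, increasing).
#' @param cfg an [hmm_config()]; `switch_tau` must be resolved (numeric).
#' @return numeric vector of `P(HET)` with attribute `loglik`.
#' @export
hmm_posterior <- function(alt, ref, pos, cfg) {
  stopifnot(length(alt) == length(ref), length(alt) == length(pos),
            length(alt) >= 1, !is.unsorted(pos),
            is.numeric(cfg$switch_tau))
  depth <- alt + ref
  if (all(depth == 0))
    warning("window has no covered marker; posterior equals the prior")
  r <- fb_posterior_cpp(as.integer(alt), as.integer(depth),
                        as.numeric(pos), cfg$error_eps, cfg$switch_tau)
  structure(r$posterior[, 2], loglik = r$loglik)
}

resolve_tau <- function(cfg, genome_length) {
  cfg$switch_tau %||% max(cfg$expected_cos / genome_length, 1e-12)
}

# Refinement of one candidate window for one individual.  Returns CO rows
# (possibly several if the window holds several flips) or NULL.
refine_window <- function(alt, ref, pos, cfg) {
  phet <- hmm_posterior(alt, ref, pos, cfg)
  covered <- which(alt + ref > 0L)
  if (length(covered) < 2) return(NULL)
  informative <- abs(phet[covered] - 0.5) > 1e-9   # exact ties anchor nothing
  cv <- covered[informative]
  if (length(cv) < 2) return(NULL)
  pi_ <- phet[cv]
  st <- pi_ > 0.5                      # TRUE = HET
  flips <- which(diff(st) != 0L)
  if (!length(flips)) return(NULL)
  out <- list()
  bounds <- c(0L, flips, length(st))   # flip-delimited runs of st
  for (k in seq_along(flips)) {
    f <- flips[k]
    left_state <- st[f]
    # nearest markers on each side confidently decoded in their state
    conf_left <- if (left_state) pi_ >= cfg$min_posterior
                 else pi_ <= 1 - cfg$min_posterior
    conf_right <- if (left_state) pi_ <= 1 - cfg$min_posterior
                  else pi_ >= cfg$min_posterior
    li <- which(conf_left[seq_len(f)])
    ri <- which(conf_right[(f + 1L):length(st)])
    if (!length(li) || !length(ri)) next   # uncertain segment: no call
    left_idx <- cv[max(li)]
    right_idx <- cv[f + min(ri)]
    seg_l <- (bounds[k] + 1L):f
    seg_r <- (f + 1L):bounds[k + 2L]
    out[[length(out) + 1L]] <- data.frame(
      left_bp = pos[left_idx], right_bp = pos[right_idx],
      left_state = ifelse(left_state, "HET", "HOM"),
      mean_post_left = mean(if (left_state) pi_[seg_l] else 1 - pi_[seg_l]),
      mean_post_right = mean(if (left_state) 1 - pi_[seg_r] else pi_[seg_r]),
      stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Refine candidate breakpoints into crossover events
#'
#' For each candidate, all SNPs in the `cfg$window` region centered on it
#' are decoded by [hmm_posterior()]; a CO is placed at each posterior state
#' flip, reported as the interval between the nearest covered flanking
#' markers whose posterior reaches `min_posterior` for their decoded state
#' (conservative anchoring: weakly informative boundary markers widen the
#' interval instead of misplacing it).  Candidates whose window decodes to
#' a single state are dropped; duplicate calls from overlapping windows are
#' merged.
#'
#' @param adm QC'd `allele_depth_matrix`.
#' @param candidates `data.table(individual, chrom, bp)` from
#'   [detect_breakpoints()].
#' @param cfg an [hmm_config()].
#' @return `data.table` of crossover events: `individual`, `chrom`,
#'   `left_bp`, `right_bp` (flanking marker positions), `midpoint`,
#'   `resolution` (`right_bp - left_bp`), `left_state`, `sex`.
#' @export
refine_and_call <- function(adm, candidates, cfg = hmm_config()) {
  cfg$switch_tau <- resolve_tau(cfg, sum(adm$chrom_lengths))
  mk <- adm$markers
  out <- list()
  if (nrow(candidates)) {
    cand <- data.table::as.data.table(candidates)
    data.table::setorder(cand, individual, chrom, bp)
    for (ind in unique(cand$individual)) {
      jcol <- match(ind, adm$individuals)
      for (ch in unique(cand$chrom[cand$individual == ind])) {
        rows <- which(mk$chrom == ch)
        pos <- mk$pos[rows]
        alt <- adm$alt[rows, jcol]
        ref <- adm$ref[rows, jcol]
        bps <- cand$bp[cand$individual == ind & cand$chrom == ch]
        for (b in bps) {
          w <- which(pos >= b - cfg$window / 2 & pos <= b + cfg$window / 2)
          if (length(w) < 2) next
          res <- refine_window(alt[w], ref[w], pos[w], cfg)
          if (!is.null(res)) {
            res$individual <- ind
            res$chrom <- ch
            out[[length(out) + 1L]] <- res
          }
        }
      }
    }
  }
  if (!length(out))
    return(data.table::data.table(individual = character(0),
                                  chrom = character(0), left_bp = numeric(0),
                                  right_bp = numeric(0), midpoint = numeric(0),
                                  resolution = numeric(0),
                                  left_state = character(0),
                                  sex = character(0)))
  ev <- data.table::rbindlist(out)
  ev <- unique(ev, by = c("individual", "chrom", "left_bp", "right_bp"))
  ev[, midpoint := (left_bp + right_bp) / 2]
  ev[, resolution := right_bp - left_bp]
  ev[, sex := adm$sex %||% NA_character_]
  data.table::setorder(ev, individual, chrom, left_bp)
  ev[, .(individual, chrom, left_bp, right_bp, midpoint, resolution,
         left_state, sex)]
}

#' Call crossovers for a whole population
#'
#' The full inference chain: bin allele frequencies, detect candidate
#' breakpoints by changepoint segmentation, refine with the windowed HMM,
#' then re-estimate `switch_tau` from the first call set and refine once
#' more (two rounds total, breaking the circularity between the transition
#' prior and the call count).
#'
#' @param adm QC'd `allele_depth_matrix`.
#' @param cfg an [hmm_config()].
#' @param bin_size segmentation bin width (bp).
#' @param iterations number of HMM rounds (default 2).
#' @return list of class `co_callset`: `events` (see [refine_and_call()]),
#'   `segments` (per individual/chromosome alternating HOM/HET runs),
#'   `candidates`, `tau` (final switch intensity), `counts` per stage.
#' @export
call_crossovers <- function(adm, cfg = hmm_config(), bin_size = 200e3,
                            iterations = 2L) {
  track <- bin_allele_frequency(adm, bin_size)
  candidates <- detect_breakpoints(track)
  genome_len <- sum(adm$chrom_lengths)
  n_ind <- length(adm$individuals)
  cfg$switch_tau <- resolve_tau(cfg, genome_len)
  events <- refine_and_call(adm, candidates, cfg)
  if (iterations > 1L) {
    for (i in seq_len(iterations - 1L)) {
      rate <- nrow(events) / n_ind / genome_len
      cfg$switch_tau <- max(rate, 1e-12)
      events <- refine_and_call(adm, candidates, cfg)
    }
  }
  segments <- build_segments(adm, events, track)
  structure(list(events = events, segments = segments,
                 candidates = candidates, tau = cfg$switch_tau,
                 counts = c(candidates = nrow(candidates),
                            events = nrow(events))),
            class = "co_callset")
}

# Chromosome partition into alternating HOM/HET runs bounded by the called
# COs; state orientation comes from each CO's decoded flip, chromosomes
# without calls take the state suggested by their mean bin frequency.
build_segments <- function(adm, events, track) {
  out <- list()
  chroms <- names(adm$chrom_lengths)
  for (ind in adm$individuals) {
    for (ch in chroms) {
      L <- adm$chrom_lengths[[ch]]
      ev <- events[events$individual == ind & events$chrom == ch, ]
      if (nrow(ev) == 0) {
        bidx <- track$bins$chrom == ch
        f <- mean(track$freq[bidx, ind], na.rm = TRUE)
        st <- if (is.finite(f) && f > 0.25) "HET" else "HOM"
        out[[length(out) + 1L]] <- data.frame(
          individual = ind, chrom = ch, start = 1, end = L,
          state = st, stringsAsFactors = FALSE)
      } else {
        bounds <- c(1, ev$midpoint, L)
        states <- character(nrow(ev) + 1L)
        states[1] <- ev$left_state[1]
        for (k in seq_len(nrow(ev)))
          states[k + 1L] <- if (ev$left_state[k] == "HET") "HOM" else "HET"
        out[[length(out) + 1L]] <- data.frame(
          individual = ind, chrom = ch,
          start = head(bounds, -1), end = tail(bounds, -1),
          state = states, stringsAsFactors = FALSE)
      }
    }
  }
  data.table::rbindlist(out)
}

#' Crossovers per meiosis from a gamete count
#'
#' A BC1 gamete carries on average half of a meiosis's crossovers, so the
#' per-meiosis estimate is `2 * total_cos / n_individuals`.
#'
#' @param total_cos total COs observed across the population.
#' @param n_individuals number of gametes genotyped.
#' @param digits decimals for the display rounding (default 1).
#' @return numeric estimate rounded to `digits`.
#' @export
cos_per_meiosis <- function(total_cos, n_individuals, digits = 1) {
  if (n_individuals <= 0) stop("n_individuals must be positive")
  round(2 * total_cos / n_individuals, digits)
}

#' Resolution bookkeeping for crossover events
#'
#' Counts COs mapped to within the given interval-width thresholds,
#' overall and per sex.
#'
#' @param events crossover event table with `resolution` and `sex` columns.
#' @param thresholds resolution thresholds in bp (default 2 kbp).
#' @return `data.frame(threshold, sex, n, fraction)`; `sex == "all"` rows
#'   aggregate both sexes.
#' @export
resolution_summary <- function(events, thresholds = 2000) {
  stopifnot(nrow(events) > 0)
  sexes <- unique(c("all", as.character(events$sex)))
  out <- list()
  for (th in thresholds) {
    for (s in sexes) {
      sel <- if (s == "all") rep(TRUE, nrow(events)) else events$sex == s
      n_tot <- sum(sel)
      n <- sum(events$resolution[sel] <= th)
      out[[length(out) + 1L]] <- data.frame(
        threshold = th, sex = s, n = n,
        fraction = if (n_tot > 0) n / n_tot else NA_real_)
    }
  }
  do.call(rbind, out)
}
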
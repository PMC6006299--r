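# Recovery evaluation of called crossovers against simulator ground truth.

#' Match called crossover events to true crossover positions
#'
#' Per individual and chromosome, called events are greedily matched 1:1 to
#' true COs by midpoint distance (closest pairs first) within
#' `max_distance`.  Sensitivity is reported both overall and restricted to
#' "isolated" true COs (at least `isolation` bp from any other true CO of
#' the same gamete) — adjacent COs can share a segmentation bin pair and
#' are not individually resolvable.  Containment is the fraction of matched
#' detections whose flanking-marker interval contains the true position.
#'
#' @param truth `data.frame(individual, chrom, pos)` of true transmitted
#'   COs (the `truth` of a `gamete_set`).
#' @param events called crossover event table.
#' @param max_distance maximum midpoint-to-truth distance for a match
#'   (default 200 kbp, one segmentation bin).
#' @param isolation distance defining isolated true COs (default 1 Mbp).
#' @return list: `sensitivity` (isolated), `sensitivity_all`, `precision`,
#'   `containment`, `n_true`, `n_true_isolated`, `n_called`, `n_matched`.
#' @export
match_crossovers <- function(truth, events, max_distance = 2e5,
                             isolation = 1e6) {
  tr <- data.table::as.data.table(truth)
  ev <- data.table::as.data.table(events)
  tr[, matched := FALSE]
  tr[, contained := FALSE]
  ev[, matched := FALSE]
  if (nrow(tr) && nrow(ev)) {
    for (key_i in unique(paste0(tr$individual, "\r", tr$chrom))) {
      ti <- which(paste0(tr$individual, "\r", tr$chrom) == key_i)
      ei <- which(paste0(ev$individual, "\r", ev$chrom) == key_i)
      if (!length(ei)) next
      pairs <- expand.grid(t = ti, e = ei)
      pairs$d <- abs(tr$pos[pairs$t] - ev$midpoint[pairs$e])
      pairs <- pairs[pairs$d <= max_distance, , drop = FALSE]
      pairs <- pairs[order(pairs$d), , drop = FALSE]
      used_t <- integer(0); used_e <- integer(0)
      for (k in seq_len(nrow(pairs))) {
        t <- pairs$t[k]; e <- pairs$e[k]
        if (t %in% used_t || e %in% used_e) next
        used_t <- c(used_t, t); used_e <- c(used_e, e)
        tr$matched[t] <- TRUE
        ev$matched[e] <- TRUE
        tr$contained[t] <- tr$pos[t] >= ev$left_bp[e] &
          tr$pos[t] <= ev$right_bp[e]
      }
    }
  }
  iso <- rep(TRUE, nrow(tr))
  if (nrow(tr) > 1) {
    for (i in seq_len(nrow(tr))) {
      same <- tr$individual == tr$individual[i] & tr$chrom == tr$chrom[i]
      gaps <- abs(tr$pos[same] - tr$pos[i])
      iso[i] <- all(gaps[gaps > 0] >= isolation)
    }
  }
  n_matched <- sum(tr$matched)
  list(sensitivity = if (any(iso)) mean(tr$matched[iso]) else NA_real_,
       sensitivity_all = if (nrow(tr)) mean(tr$matched) else NA_real_,
       precision = if (nrow(ev)) mean(ev$matched) else NA_real_,
       containment = if (n_matched) mean(tr$contained[tr$matched])
                     else NA_real_,
       n_true = nrow(tr), n_true_isolated = sum(iso),
       n_called = nrow(ev), n_matched = n_matched)
}
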
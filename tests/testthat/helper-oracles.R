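# Independent oracles used to freeze expected values: these deliberately
# share no code with the implementation paths they check.

# Exhaustive-path posterior for the two-state HMM: enumerate all 2^n state
# sequences, accumulate joint probabilities, and marginalize per marker.
# Emissions and transitions mirror the model definition but are computed
# directly, without forward-backward.
hmm_enum_posterior <- function(alt, depth, pos, eps, tau) {
  n <- length(alt)
  emis <- function(i, s) {
    d <- depth[i]; a <- alt[i]
    if (d == 0) return(1)
    if (s == 0) eps^a * (1 - eps)^(d - a) else 0.5^d
  }
  trans <- function(d, same) {
    sw <- 0.5 * (1 - exp(-2 * tau * d))
    if (same) 1 - sw else sw
  }
  states <- as.matrix(expand.grid(rep(list(0:1), n)))
  joint <- apply(states, 1, function(s) {
    p <- 0.5 * emis(1, s[1])
    if (n > 1) for (i in 2:n)
      p <- p * trans(pos[i] - pos[i - 1], s[i] == s[i - 1]) * emis(i, s[i])
    p
  })
  phet <- vapply(seq_len(n), function(i)
    sum(joint[states[, i] == 1]) / sum(joint), numeric(1))
  phet
}

# brute-force signed nearest-feature distance for one event
brute_nearest <- function(chrom, mid, features, stranded = FALSE) {
  fs <- features[features$chrom == chrom, , drop = FALSE]
  if (nrow(fs) == 0) return(c(NA_real_, NA_integer_))
  gaps <- vapply(seq_len(nrow(fs)), function(i) {
    if (mid < fs$start[i]) fs$start[i] - mid
    else if (mid > fs$end[i]) mid - fs$end[i]
    else 0
  }, numeric(1))
  j <- which.min(gaps)
  d <- gaps[j]
  if (stranded && !is.null(fs$strand)) {
    if (mid < fs$start[j] && fs$strand[j] == "+") d <- -d
    if (mid > fs$end[j] && fs$strand[j] == "-") d <- -d
  }
  c(d, which(features$chrom == chrom)[j])
}

# KS statistic as the sup over the empirical CDF difference
ks_D_brute <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(vapply(grid, function(g) mean(a <= g) - mean(b <= g), numeric(1))))
}

# Pearson correlation from the textbook sum formula
pearson_brute <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# G statistic from the direct 2 * sum(O * ln(O/E)) formula
g_stat_brute <- function(k1, n1, k2, n2) {
  o <- c(k1, n1 - k1, k2, n2 - k2)
  p <- (k1 + k2) / (n1 + n2)
  e <- c(n1 * p, n1 * (1 - p), n2 * p, n2 * (1 - p))
  keep <- o > 0
  2 * sum(o[keep] * log(o[keep] / e[keep]))
}

# best single-split / two-split segmentations by exhaustive search
best_single_split <- function(y) {
  n <- length(y)
  rss <- function(v) sum((v - mean(v))^2)
  costs <- vapply(1:(n - 1), function(k) rss(y[1:k]) + rss(y[(k + 1):n]),
                  numeric(1))
  which.min(costs)
}
best_two_split <- function(y) {
  n <- length(y)
  rss <- function(v) sum((v - mean(v))^2)
  best <- c(NA, NA); bc <- Inf
  for (k1 in 1:(n - 2)) for (k2 in (k1 + 1):(n - 1)) {
    cc <- rss(y[1:k1]) + rss(y[(k1 + 1):k2]) + rss(y[(k2 + 1):n])
    if (cc < bc) { bc <- cc; best <- c(k1, k2) }
  }
  best
}
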
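# SNP retention filters applied to the allele-depth matrix before CO
# inference: population allele frequency, local linkage-disequilibrium
# concordance, and population-summed depth (a copy-number proxy).

#' Filter configuration for marker QC
#'
#' @param af_min,af_max closed bounds on the population alt-read frequency;
#'   in a BC1 the expectation is ~0.25 (half the individuals HET), so SNPs
#'   outside 0.1--0.4 are suspect.
#' @param ld_interval width (bp) of the genomic intervals within which the
#'   LD concordance test looks for neighbors.
#' @param ld_alpha a marker is kept iff the median of its neighbor-pair
#'   Fisher-exact p-values is below this level (true linked markers are
#'   strongly associated; structural-polymorphism noise is not).
#' @param ld_k number of nearest neighbor markers tested.
#' @param dp_min,dp_max closed bounds on population-summed depth; `NULL`
#'   defaults to `dp_rel * mean depth`, scaling the filter to the
#'   experiment's own coverage.
#' @param dp_rel relative bounds used when `dp_min`/`dp_max` are `NULL`.
#' @return object of class `filter_config`.
#' @export
filter_config <- function(af_min = 0.1, af_max = 0.4,
                          ld_interval = 10e6, ld_alpha = 0.05, ld_k = 20L,
                          dp_min = NULL, dp_max = NULL,
                          dp_rel = c(0.5, 1.5)) {
  stopifnot(af_min >= 0, af_min < af_max, af_max <= 1,
            ld_interval > 0, ld_alpha > 0, ld_alpha < 1, ld_k >= 1,
            length(dp_rel) == 2, dp_rel[1] < dp_rel[2])
  structure(list(af_min = af_min, af_max = af_max,
                 ld_interval = ld_interval, ld_alpha = ld_alpha,
                 ld_k = as.integer(ld_k),
                 dp_min = dp_min, dp_max = dp_max, dp_rel = dp_rel),
            class = "filter_config")
}

#' Allele-frequency filter
#'
#' The population alt-read frequency of each marker,
#' f = sum(alt) / (sum(alt) + sum(ref)), must lie in the closed interval
#' `[af_min, af_max]`.  Markers with no reads at all are passed through
#' flagged `"no-data"`.
#'
#' @param adm an `allele_depth_matrix`.
#' @param cfg a [filter_config()].
#' @return logical pass vector with attributes `freq` and `reason`
#'   (`NA`, `"af"`, or `"no-data"`).
#' @export
filter_allele_frequency <- function(adm, cfg = filter_config()) {
  tot_alt <- rowSums(adm$alt)
  tot <- tot_alt + rowSums(adm$ref)
  f <- ifelse(tot > 0, tot_alt / tot, NA_real_)
  pass <- is.na(f) | (f >= cfg$af_min & f <= cfg$af_max)
  reason <- rep(NA_character_, length(f))
  reason[!pass] <- "af"
  reason[is.na(f)] <- "no-data"
  structure(pass, freq = f, reason = reason)
}

# hard genotype calls used ONLY by the LD concordance screen: any alt read
# => HET, only ref reads => HOM, no reads => missing.  Biased at low
# coverage but adequate for an association screen; CO inference never uses
# hard calls.
hard_calls <- function(adm) {
  calls <- matrix(-1L, nrow(adm$alt), ncol(adm$alt))
  calls[adm$alt > 0L] <- 1L
  calls[adm$alt == 0L & adm$ref > 0L] <- 0L
  calls
}

#' Linkage-disequilibrium concordance filter
#'
#' Within fixed genomic intervals (default 10 Mbp), each marker's hard
#' genotype calls are tested for association against its `ld_k` nearest
#' neighbors by Fisher's exact test; the marker is kept iff the median
#' p-value is below `ld_alpha`.  Genuine SNPs travel with their neighbors
#' (tiny p); spurious heterozygosity from structural polymorphism segregates
#' independently (median p near 0.5).  Markers alone in an interval, or with
#' no evaluable pair, are kept by convention (with a warning when a whole
#' interval is unevaluable).
#'
#' @inheritParams filter_allele_frequency
#' @return logical pass vector with attributes `median_p` and `reason`.
#' @export
filter_ld <- function(adm, cfg = filter_config()) {
  calls <- hard_calls(adm)
  chrom_id <- as.integer(factor(adm$markers$chrom,
                                levels = unique(adm$markers$chrom)))
  ivl <- chrom_id * 10000000L + as.integer((adm$markers$pos - 1) %/% cfg$ld_interval)
  medp <- ld_median_p_cpp(calls, ivl, cfg$ld_k)
  if (anyNA(medp)) {
    na_iv <- unique(ivl[is.na(medp)])
    all_na <- vapply(na_iv, function(v) all(is.na(medp[ivl == v])), logical(1))
    if (any(all_na))
      warning(sum(all_na), " interval(s) had no evaluable marker pairs; ",
              "their markers are kept")
  }
  pass <- is.na(medp) | medp < cfg$ld_alpha
  reason <- rep(NA_character_, length(pass))
  reason[!pass] <- "ld"
  structure(pass, median_p = medp, reason = reason)
}

#' Population-depth filter
#'
#' Markers whose population-summed depth falls outside `[dp_min, dp_max]`
#' (closed interval) are removed; depth far above expectation marks
#' copy-number differences between the parental genomes, far below marks
#' poorly accessible sequence.
#'
#' @inheritParams filter_allele_frequency
#' @return logical pass vector with attributes `depth`, `bounds`, `reason`.
#' @export
filter_depth <- function(adm, cfg = filter_config()) {
  dp <- rowSums(adm$ref) + rowSums(adm$alt)
  dp_min <- cfg$dp_min %||% (cfg$dp_rel[1] * mean(dp))
  dp_max <- cfg$dp_max %||% (cfg$dp_rel[2] * mean(dp))
  pass <- dp >= dp_min & dp <= dp_max
  reason <- rep(NA_character_, length(pass))
  reason[!pass] <- "dp"
  structure(pass, depth = dp, bounds = c(dp_min, dp_max), reason = reason)
}

#' Apply all marker filters
#'
#' Filters are independent and composable: a marker fails if any filter
#' fails, and all failure reasons are preserved.
#'
#' @inheritParams filter_allele_frequency
#' @param use character subset of `c("af", "ld", "dp")`.
#' @return the `allele_depth_matrix` restricted to passing markers, with a
#'   `qc` attribute: `data.frame(chrom, pos, status, reason)` for every
#'   input marker plus a per-reason count summary.
#' @export
apply_marker_filters <- function(adm, cfg = filter_config(),
                                 use = c("af", "ld", "dp")) {
  use <- match.arg(use, several.ok = TRUE)
  res <- list()
  if ("af" %in% use) res$af <- filter_allele_frequency(adm, cfg)
  if ("dp" %in% use) res$dp <- filter_depth(adm, cfg)
  if ("ld" %in% use) res$ld <- filter_ld(adm, cfg)
  pass <- Reduce(`&`, lapply(res, as.logical), rep(TRUE, nrow(adm$markers)))
  reasons <- vapply(seq_len(nrow(adm$markers)), function(i) {
    r <- unlist(lapply(res, function(x) attr(x, "reason")[i]))
    r <- r[!is.na(r) & r != "no-data"]
    if (length(r)) paste(r, collapse = ";") else NA_character_
  }, character(1))
  qc <- data.frame(chrom = adm$markers$chrom, pos = adm$markers$pos,
                   status = ifelse(pass, "pass", "fail"),
                   reason = reasons, stringsAsFactors = FALSE)
  out <- adm
  out$markers <- adm$markers[pass, , drop = FALSE]
  rownames(out$markers) <- NULL
  out$ref <- adm$ref[pass, , drop = FALSE]
  out$alt <- adm$alt[pass, , drop = FALSE]
  attr(out, "qc") <- qc
  attr(out, "qc_summary") <- table(ifelse(is.na(reasons), "pass", reasons))
  out
}
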
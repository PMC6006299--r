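# Synthetic BC1 populations with known crossover ground truth.
#
# The generator emulates the study design the package targets: a backcross
# population in which every individual carries one recombinant gamete, each
# marker is homozygous-parental (HOM) or heterozygous (HET) at expectation
# 50:50, and genotyping consists of very sparse reads (~1.5x) over a dense
# SNP map interrupted by polymorphism deserts and structural-polymorphism
# noise.

#' Simulation configuration for a synthetic BC1 experiment
#'
#' @param chrom_lengths numeric vector of chromosome lengths in bp
#'   (named, or auto-named `chr1..chrN`).
#' @param marker_density mean SNP markers per kbp.
#' @param desert_intervals optional `data.frame(chrom, start, end)` of
#'   polymorphism deserts containing no markers.
#' @param coverage_lambda mean reads per marker per individual (Poisson).
#' @param error_eps per-read miscall probability (alt read at a HOM marker).
#' @param co_per_meiosis_lambda mean crossovers per meiosis per genome; each
#'   CO is transmitted to the sampled gamete with probability 1/2.
#' @param obligate_co logical; force at least one CO per chromosome per
#'   meiosis.
#' @param hotspot_spec optional `data.frame(chrom, start, end, fold, sex)` of
#'   CO-intensity multipliers; `sex` may be `"male"`, `"female"` or `"both"`
#'   (missing column = both sexes).
#' @param noise_spec optional `data.frame(chrom, start, end, alt_bias,
#'   cov_mult)` of clustered spurious-heterozygosity regions mimicking
#'   structural polymorphism: for every individual, markers inside emit alt
#'   reads with probability `alt_bias` and coverage is scaled by `cov_mult`
#'   (default 1).
#' @param track_spec optional `data.frame(name, offset, amplitude, bump_sd,
#'   jitter_sd, baseline, step)` describing chromatin tracks whose Gaussian
#'   bumps sit at (CO site + `offset` + jitter) bp.  Only `name` and
#'   `offset` are required.
#' @param interference_shape optional gamma shape for renewal-process CO
#'   spacing (crossover interference); `NULL` (default) places COs
#'   independently, which matches the no-interference analysis model.
#' @param seed integer; together with the stage label it fully determines
#'   every simulated output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(chrom_lengths = rep(20e6, 10),
                       marker_density = 1,
                       desert_intervals = NULL,
                       coverage_lambda = 1.5,
                       error_eps = 0.01,
                       co_per_meiosis_lambda = 20,
                       obligate_co = FALSE,
                       hotspot_spec = NULL,
                       noise_spec = NULL,
                       track_spec = NULL,
                       interference_shape = NULL,
                       seed = 1L) {
  stopifnot(length(chrom_lengths) >= 1, all(chrom_lengths > 0),
            marker_density > 0,
            coverage_lambda > 0,
            error_eps >= 0, error_eps < 0.5,
            co_per_meiosis_lambda >= 0,
            is.logical(obligate_co), length(obligate_co) == 1L)
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  if (!is.null(hotspot_spec)) {
    stopifnot(all(c("chrom", "start", "end", "fold") %in% names(hotspot_spec)),
              all(hotspot_spec$fold >= 0),
              all(hotspot_spec$end > hotspot_spec$start))
    if (is.null(hotspot_spec$sex)) hotspot_spec$sex <- "both"
  }
  if (!is.null(noise_spec)) {
    stopifnot(all(c("chrom", "start", "end", "alt_bias") %in% names(noise_spec)),
              all(noise_spec$alt_bias >= 0 & noise_spec$alt_bias <= 1))
    if (is.null(noise_spec$cov_mult)) noise_spec$cov_mult <- 1
  }
  if (!is.null(track_spec)) {
    stopifnot(all(c("name", "offset") %in% names(track_spec)))
    defaults <- list(amplitude = 2, bump_sd = 150, jitter_sd = 100,
                     baseline = 1, step = 10)
    for (f in names(defaults))
      if (is.null(track_spec[[f]])) track_spec[[f]] <- defaults[[f]]
  }
  structure(list(chrom_lengths = chrom_lengths,
                 marker_density = marker_density,
                 desert_intervals = desert_intervals,
                 coverage_lambda = coverage_lambda,
                 error_eps = error_eps,
                 co_per_meiosis_lambda = co_per_meiosis_lambda,
                 obligate_co = obligate_co,
                 hotspot_spec = hotspot_spec,
                 noise_spec = noise_spec,
                 track_spec = track_spec,
                 interference_shape = interference_shape,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("BC1 simulation config:", length(x$chrom_lengths), "chromosomes,",
      format(sum(x$chrom_lengths), big.mark = ","), "bp genome\n")
  cat("  marker density", x$marker_density, "/kbp; coverage",
      x$coverage_lambda, "x; error", x$error_eps,
      "; COs/meiosis", x$co_per_meiosis_lambda, "\n")
  invisible(x)
}

# which rows of an interval data.frame contain each position (chrom, pos)
in_intervals <- function(chrom, pos, intervals) {
  hit <- rep(FALSE, length(pos))
  if (is.null(intervals) || nrow(intervals) == 0L) return(hit)
  for (i in seq_len(nrow(intervals))) {
    hit <- hit | (chrom == intervals$chrom[i] &
                  pos >= intervals$start[i] & pos <= intervals$end[i])
  }
  hit
}

#' Simulate an ordered SNP marker set
#'
#' Marker counts per chromosome are Poisson with mean `density * length`,
#' positions uniform, then markers falling in polymorphism deserts are
#' removed (deserts emulate regions lacking polymorphism between the
#' parents, e.g. selective sweeps).
#'
#' @param config a [sim_config()].
#' @return `data.frame` with columns `chrom`, `pos` (1-based, strictly
#'   increasing within chromosome), `ref`, `alt`, `status` (`"pass"`).
#' @export
simulate_marker_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_stage_seed(config$seed, "markers", {
    nts <- c("A", "C", "G", "T")
    out <- lapply(names(config$chrom_lengths), function(ch) {
      L <- config$chrom_lengths[[ch]]
      n <- rpois(1L, config$marker_density * L / 1000)
      pos <- sort(unique(sample.int(L, min(n, L), replace = FALSE)))
      keep <- !in_intervals(rep(ch, length(pos)), pos, config$desert_intervals)
      pos <- pos[keep]
      if (length(pos) == 0L)
        stop("chromosome ", ch, " has no informative markers ",
             "(deserts cover all sampled positions)")
      ref <- sample(nts, length(pos), replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(nts, r), 1L), "")
      data.frame(chrom = ch, pos = pos, ref = ref, alt = unname(alt),
                 status = "pass", stringsAsFactors = FALSE)
    })
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}

# piecewise-constant CO intensity for one chromosome: base 1 multiplied by
# hotspot folds for the given sex; returns breaks and per-piece weights
co_intensity_pieces <- function(L, hotspots) {
  if (is.null(hotspots) || nrow(hotspots) == 0L)
    return(list(breaks = c(0, L), fold = 1))
  cuts <- sort(unique(c(0, L, pmax(0, hotspots$start - 1), pmin(L, hotspots$end))))
  mid <- (head(cuts, -1) + tail(cuts, -1)) / 2
  fold <- rep(1, length(mid))
  for (i in seq_len(nrow(hotspots))) {
    inside <- mid > (hotspots$start[i] - 1) & mid <= hotspots$end[i]
    fold[inside] <- fold[inside] * hotspots$fold[i]
  }
  list(breaks = cuts, fold = fold)
}

# draw n CO positions from the piecewise intensity
draw_co_positions <- function(n, pieces) {
  if (n == 0L) return(numeric(0))
  w <- pmax(pieces$fold, 0) * diff(pieces$breaks)
  if (all(w == 0)) return(numeric(0))
  piece <- sample.int(length(w), n, replace = TRUE, prob = w)
  runif(n, pieces$breaks[piece], pieces$breaks[piece + 1L])
}

#' Simulate gametes of a BC1 population
#'
#' Each individual derives from one meiosis of the F1 hybrid.  The number of
#' COs per meiosis is Poisson(`co_per_meiosis_lambda`), apportioned to
#' chromosomes by physical length (optionally forced >= 1 per chromosome);
#' each CO is transmitted to the sampled gamete with probability 1/2 (two of
#' the four chromatids are involved in any one CO).  CO positions follow a
#' base-uniform intensity multiplied by hotspot folds.  A gamete is a
#' sequence of alternating HOM/HET marker blocks whose boundaries are
#' exactly the transmitted COs; at most one transmitted CO is placed per
#' inter-marker interval (a double CO inside one interval would be invisible
#' at marker resolution, so positions are redrawn on collision).
#'
#' @param config a [sim_config()].
#' @param markers marker table from [simulate_marker_set()].
#' @param n_individuals population size.
#' @param sex `"male"` or `"female"` (selects the matching `hotspot_spec`
#'   rows and the RNG stream).
#' @return A list of class `gamete_set`: `genotypes` (integer matrix,
#'   markers x individuals, 0 = HOM, 1 = HET), `truth` (`data.frame`
#'   `individual`, `chrom`, `pos` of transmitted COs), `markers`, `sex`,
#'   `individuals`.
#' @export
simulate_gametes <- function(config, markers, n_individuals,
                             sex = c("male", "female")) {
  stopifnot(inherits(config, "sim_config"), nrow(markers) > 0,
            n_individuals >= 1)
  sex <- match.arg(sex)
  hs <- config$hotspot_spec
  if (!is.null(hs)) hs <- hs[hs$sex %in% c(sex, "both"), , drop = FALSE]
  chroms <- names(config$chrom_lengths)
  Ltot <- sum(config$chrom_lengths)
  pieces <- lapply(chroms, function(ch)
    co_intensity_pieces(config$chrom_lengths[[ch]],
                        if (is.null(hs)) NULL else hs[hs$chrom == ch, , drop = FALSE]))
  names(pieces) <- chroms
  mpos <- split(markers$pos, factor(markers$chrom, levels = chroms))
  ids <- sprintf("%s_%03d", substr(sex, 1, 1), seq_len(n_individuals))

  with_stage_seed(config$seed, paste0("gametes.", sex), {
    geno <- matrix(0L, nrow = nrow(markers), ncol = n_individuals,
                   dimnames = list(NULL, ids))
    truth <- vector("list", n_individuals)
    row_off <- c(0L, cumsum(vapply(chroms, function(ch)
      length(mpos[[ch]]), integer(1))))
    names(row_off) <- c(chroms, "end")[seq_along(row_off)]
    for (j in seq_len(n_individuals)) {
      tlist <- list()
      for (ci in seq_along(chroms)) {
        ch <- chroms[ci]
        L <- config$chrom_lengths[[ch]]
        pos_m <- mpos[[ch]]
        n_mei <- if (!is.null(config$interference_shape)) {
          NA_integer_  # renewal process decides
        } else rpois(1L, config$co_per_meiosis_lambda * L / Ltot)
        if (!is.null(config$interference_shape)) {
          # gamma-renewal spacing in intensity scale (interference)
          rate <- config$co_per_meiosis_lambda * L / Ltot / L
          nu <- config$interference_shape
          gaps <- rgamma(64L, shape = nu, rate = nu * rate)
          cum <- cumsum(gaps)
          co_mei <- cum[cum < L]
          n_mei <- length(co_mei)
        } else {
          if (config$obligate_co && n_mei == 0L) n_mei <- 1L
          co_mei <- draw_co_positions(n_mei, pieces[[ch]])
        }
        keep <- runif(length(co_mei)) < 0.5   # transmission to this gamete
        co <- co_mei[keep]
        # anchor each CO in a distinct inter-marker interval
        used <- integer(0)
        placed <- numeric(0)
        for (p in co) {
          for (try in 1:200) {
            iv <- findInterval(p, pos_m)
            if (iv >= 1L && iv < length(pos_m) && !(iv %in% used)) break
            p <- draw_co_positions(1L, pieces[[ch]])
          }
          iv <- findInterval(p, pos_m)
          if (iv >= 1L && iv < length(pos_m) && !(iv %in% used)) {
            used <- c(used, iv)
            placed <- c(placed, p)
          }
        }
        placed <- sort(placed)
        start_state <- rbinom(1L, 1L, 0.5)
        g <- (start_state + findInterval(pos_m, placed)) %% 2L
        geno[(row_off[ci] + 1L):(row_off[ci] + length(pos_m)), j] <- as.integer(g)
        if (length(placed))
          tlist[[ch]] <- data.frame(individual = ids[j], chrom = ch,
                                    pos = placed, stringsAsFactors = FALSE)
      }
      truth[[j]] <- if (length(tlist)) do.call(rbind, tlist) else NULL
    }
    truth <- truth[!vapply(truth, is.null, logical(1))]
    truth <- if (length(truth))
      do.call(rbind, c(truth, list(make.row.names = FALSE)))
    else data.frame(individual = character(0), chrom = character(0),
                    pos = numeric(0))
    structure(list(genotypes = geno, truth = truth, markers = markers,
                   sex = sex, individuals = ids,
                   chrom_lengths = config$chrom_lengths),
              class = "gamete_set")
  })
}

#' Simulate sparse sequencing reads over a gamete set
#'
#' Per marker per individual, read depth is Poisson(`coverage_lambda`); each
#' read reports the alternate allele with probability `error_eps` at HOM
#' markers and 1/2 at HET markers.  Markers inside `noise_spec` regions emit
#' alt reads with probability `alt_bias` for every individual (structural
#' polymorphism between the parental genomes shows up this way in real
#' alignments) and have their coverage scaled by `cov_mult`.
#'
#' @param gametes a `gamete_set` from [simulate_gametes()].
#' @param config the same [sim_config()].
#' @return An `allele_depth_matrix`: list with `markers`, `individuals`,
#'   integer matrices `ref` and `alt` (markers x individuals), and `sex`.
#' @export
simulate_reads <- function(gametes, config) {
  stopifnot(inherits(gametes, "gamete_set"), inherits(config, "sim_config"))
  markers <- gametes$markers
  nm <- nrow(markers)
  ni <- length(gametes$individuals)
  noisy <- in_intervals(markers$chrom, markers$pos, config$noise_spec)
  lam <- rep(config$coverage_lambda, nm)
  bias <- rep(NA_real_, nm)
  if (any(noisy)) {
    ns <- config$noise_spec
    for (i in seq_len(nrow(ns))) {
      idx <- markers$chrom == ns$chrom[i] &
        markers$pos >= ns$start[i] & markers$pos <= ns$end[i]
      lam[idx] <- lam[idx] * ns$cov_mult[i]
      bias[idx] <- ns$alt_bias[i]
    }
  }
  with_stage_seed(config$seed, paste0("reads.", gametes$sex), {
    ref <- matrix(0L, nm, ni, dimnames = list(NULL, gametes$individuals))
    alt <- ref
    for (j in seq_len(ni)) {
      depth <- rpois(nm, lam)
      p <- ifelse(gametes$genotypes[, j] == 1L, 0.5, config$error_eps)
      p[noisy] <- bias[noisy]
      a <- rbinom(nm, depth, p)
      alt[, j] <- a
      ref[, j] <- depth - a
    }
    structure(list(markers = markers, individuals = gametes$individuals,
                   ref = ref, alt = alt, sex = gametes$sex,
                   chrom_lengths = gametes$chrom_lengths),
              class = "allele_depth_matrix")
  })
}

#' @export
print.allele_depth_matrix <- function(x, ...) {
  cat("allele_depth_matrix:", nrow(x$markers), "markers x",
      length(x$individuals), "individuals (", x$sex, ")\n")
  cat("  mean depth", round(mean(x$ref + x$alt), 3), "\n")
  invisible(x)
}

#' Simulate gene/TE annotations and chromatin signal tracks
#'
#' Gene and TE models are placed uniformly (non-overlapping within each
#' class) with random strands.  Each requested track is a constant baseline
#' plus Gaussian bumps centered at (CO site + `offset` + jitter), emulating
#' chromatin marks such as H3K4me3 that sit at a reproducible displacement
#' from crossover sites.
#'
#' @param config a [sim_config()] whose `track_spec` describes the tracks.
#' @param truth `data.frame(chrom, pos)` of CO sites (e.g. the `truth` of a
#'   `gamete_set`; duplicated sites are used once).
#' @param genes_per_mbp,gene_length,tes_per_mbp,te_length densities and
#'   sizes of the annotation models.
#' @return list with `annotations` (list `genes`, `tes`, `regions`) and
#'   `tracks` (named list of `signal_track` objects).
#' @export
simulate_annotations_and_tracks <- function(config, truth,
                                            genes_per_mbp = 20,
                                            gene_length = 3000,
                                            tes_per_mbp = 10,
                                            te_length = 2000) {
  stopifnot(inherits(config, "sim_config"))
  sites <- unique(truth[, c("chrom", "pos")])
  with_stage_seed(config$seed, "annotations", {
    place <- function(per_mbp, len) {
      out <- lapply(names(config$chrom_lengths), function(ch) {
        L <- config$chrom_lengths[[ch]]
        n <- max(1L, rpois(1L, per_mbp * L / 1e6))
        start <- sort(sample.int(max(1L, L - len), n, replace = TRUE))
        keep <- c(TRUE, diff(start) > len)   # enforce non-overlap
        start <- start[keep]
        data.frame(chrom = ch, start = start, end = start + len - 1,
                   strand = sample(c("+", "-"), length(start), replace = TRUE),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, c(out, list(make.row.names = FALSE)))
    }
    genes <- place(genes_per_mbp, gene_length)
    genes$gene_id <- sprintf("gene%05d", seq_len(nrow(genes)))
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
    genes$tts <- ifelse(genes$strand == "+", genes$end, genes$start)
    tes <- place(tes_per_mbp, te_length)
    te_strip <- tes[, c("chrom", "start", "end")]
    ends <- do.call(rbind, lapply(names(config$chrom_lengths), function(ch) {
      L <- config$chrom_lengths[[ch]]
      w <- round(0.05 * L)
      data.frame(label = c("chrom_start", "chrom_end"), chrom = ch,
                 start = c(1, L - w + 1), end = c(w, L),
                 stringsAsFactors = FALSE)
    }))
    tracks <- list()
    ts <- config$track_spec
    if (!is.null(ts)) {
      for (i in seq_len(nrow(ts))) {
        tracks[[ts$name[i]]] <- make_bump_track(
          config$chrom_lengths, sites,
          offset = ts$offset[i], amplitude = ts$amplitude[i],
          bump_sd = ts$bump_sd[i], jitter_sd = ts$jitter_sd[i],
          baseline = ts$baseline[i], step = ts$step[i])
      }
    }
    list(annotations = list(genes = genes, tes = te_strip, regions = ends),
         tracks = tracks)
  })
}

# constant baseline + Gaussian bumps at site + offset + N(0, jitter_sd)
make_bump_track <- function(chrom_lengths, sites, offset, amplitude,
                            bump_sd, jitter_sd, baseline, step) {
  values <- lapply(names(chrom_lengths), function(ch) {
    nb <- ceiling(chrom_lengths[[ch]] / step)
    v <- rep(as.numeric(baseline), nb)
    s <- sites$pos[sites$chrom == ch]
    if (length(s)) {
      centers <- s + offset + rnorm(length(s), 0, jitter_sd)
      half <- ceiling(4 * bump_sd / step)
      for (cpos in centers) {
        cb <- floor(cpos / step) + 1
        idx <- max(1, cb - half):min(nb, cb + half)
        x <- (idx - 0.5) * step           # bin centers in bp
        v[idx] <- v[idx] + amplitude * exp(-(x - cpos)^2 / (2 * bump_sd^2))
      }
    }
    v
  })
  names(values) <- names(chrom_lengths)
  structure(list(step = step, values = values), class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("signal_track: step", x$step, "bp,", length(x$values), "chromosomes\n")
  invisible(x)
}
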
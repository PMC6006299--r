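#' Derive a stage-specific seed from a global seed
#'
#' Every stochastic operation in the package draws its seed deterministically
#' from a global seed and a short stage label, so that re-running one stage
#' from its on-disk inputs reproduces its outputs bit for bit.
#'
#' @param seed integer global seed.
#' @param stage character label of the stage (e.g. `"gametes.male"`).
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(stage) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * (31 ^ (seq_along(utf8ToInt(as.character(stage))) %% 8)))
  as.integer((abs(seed) * 7919 + h) %% .Machine$integer.max)
}

# run expr under a derived seed without disturbing the caller's RNG state
with_stage_seed <- function(seed, stage, expr) {
  withr::with_seed(derive_seed(seed, stage), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tile a genome into fixed-width half-open windows
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param width window width in bp.
#' @return `data.table` with columns `chrom`, `start`, `end` (1-based,
#'   `end` inclusive; the last window is truncated at the chromosome end).
#' @export
tile_genome <- function(chrom_lengths, width) {
  stopifnot(width > 0, all(chrom_lengths > 0))
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq(1, L, by = width)
    data.table::data.table(chrom = ch, start = starts,
                           end = pmin(starts + width - 1, L))
  })
  data.table::rbindlist(out)
}

# named chromosome length vector from a config or marker table
chrom_length_vec <- function(x) {
  if (inherits(x, "sim_config")) return(x$chrom_lengths)
  stop("cannot extract chromosome lengths from ", class(x)[1])
}
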
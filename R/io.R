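# Readers and writers for the pipeline's on-disk formats.  Internal
# coordinates are 1-based positions; BED output is converted to 0-based
# half-open at this boundary and back on reading.  GFF3 and bedGraph go
# through rtracklayer.

#' Write / read a marker table (TSV)
#'
#' Columns: chrom, pos (1-based), ref, alt, status.
#' @param markers marker table.
#' @param path file path.
#' @export
write_markers <- function(markers, path) {
  data.table::fwrite(markers, path, sep = "\t")
  invisible(path)
}

#' @rdname write_markers
#' @export
read_markers <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' Write / read an allele-depth matrix (long TSV)
#'
#' Only nonzero-depth cells are stored (`individual`, `chrom`, `pos`,
#' `ref_depth`, `alt_depth`); chromosome lengths, the individual roster and
#' the sex label travel in `#`-prefixed header lines so the round trip is
#' exact.
#'
#' @param adm an `allele_depth_matrix`.
#' @param path file path.
#' @export
write_depth <- function(adm, path) {
  hdr <- c(
    paste0("#chrom_lengths\t",
           paste(names(adm$chrom_lengths), adm$chrom_lengths,
                 sep = "=", collapse = ",")),
    paste0("#individuals\t", paste(adm$individuals, collapse = ",")),
    paste0("#sex\t", adm$sex %||% "NA"))
  nz <- which(adm$ref + adm$alt > 0L, arr.ind = TRUE)
  dt <- data.table::data.table(
    individual = adm$individuals[nz[, 2]],
    chrom = adm$markers$chrom[nz[, 1]],
    pos = adm$markers$pos[nz[, 1]],
    ref_depth = adm$ref[nz],
    alt_depth = adm$alt[nz])
  data.table::setorder(dt, individual, chrom, pos)
  writeLines(hdr, path)
  data.table::fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_depth
#' @param markers the marker table the matrix is indexed by.
#' @export
read_depth <- function(path, markers) {
  hdr <- readLines(path, n = 3L)
  parse_kv <- function(line) {
    kv <- strsplit(sub("^[^\t]*\t", "", line), ",", fixed = TRUE)[[1]]
    parts <- strsplit(kv, "=", fixed = TRUE)
    stats::setNames(as.numeric(vapply(parts, `[`, "", 2)),
                    vapply(parts, `[`, "", 1))
  }
  chrom_lengths <- parse_kv(hdr[1])
  individuals <- strsplit(sub("^[^\t]*\t", "", hdr[2]), ",")[[1]]
  sex <- sub("^[^\t]*\t", "", hdr[3])
  dt <- data.table::fread(path, sep = "\t", skip = 3L)
  nm <- nrow(markers); ni <- length(individuals)
  ref <- matrix(0L, nm, ni, dimnames = list(NULL, individuals))
  alt <- ref
  mi <- match(paste0(dt$chrom, ":", dt$pos),
              paste0(markers$chrom, ":", markers$pos))
  ji <- match(dt$individual, individuals)
  if (anyNA(mi) || anyNA(ji))
    stop("depth file refers to markers or individuals not in the roster")
  ref[cbind(mi, ji)] <- dt$ref_depth
  alt[cbind(mi, ji)] <- dt$alt_depth
  structure(list(markers = markers, individuals = individuals,
                 ref = ref, alt = alt,
                 sex = if (sex == "NA") NULL else sex,
                 chrom_lengths = chrom_lengths),
            class = "allele_depth_matrix")
}

#' Write / read crossover events as BED
#'
#' BED columns: chrom, left_bp - 1, right_bp (0-based half-open),
#' individual, resolution, sex — the flanking-marker interval of each CO.
#'
#' @param events crossover event table.
#' @param path file path.
#' @export
write_co_bed <- function(events, path) {
  dt <- data.table::data.table(
    chrom = events$chrom, start = as.integer(events$left_bp - 1),
    end = as.integer(events$right_bp), individual = events$individual,
    resolution = events$resolution, sex = events$sex)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_co_bed
#' @export
read_co_bed <- function(path) {
  dt <- data.table::fread(path, sep = "\t",
                          col.names = c("chrom", "start", "end", "individual",
                                        "resolution", "sex"))
  bad <- which(dt$end <= dt$start)
  if (length(bad))
    stop("malformed BED interval at line ", bad[1], ": end <= start")
  data.table::data.table(
    individual = dt$individual, chrom = dt$chrom,
    left_bp = dt$start + 1, right_bp = as.numeric(dt$end),
    midpoint = (dt$start + 1 + dt$end) / 2,
    resolution = dt$resolution, sex = dt$sex)
}

#' Write / read gene annotations as GFF3
#'
#' 1-based closed coordinates per the GFF3 standard, via rtracklayer.
#'
#' @param genes gene table (`chrom`, `start`, `end`, `strand`, `gene_id`).
#' @param path file path.
#' @export
write_gff3 <- function(genes, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required for GFF3 I/O")
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required for GFF3 I/O")
  gr <- rtracklayer::import(path, format = "gff3")
  g <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr),
                  end = GenomicRanges::end(gr),
                  strand = as.character(GenomicRanges::strand(gr)),
                  gene_id = gr$ID, stringsAsFactors = FALSE)
  g$tss <- ifelse(g$strand == "+", g$start, g$end)
  g$tts <- ifelse(g$strand == "+", g$end, g$start)
  g
}

#' Write / read a signal track as bedGraph
#'
#' Fixed-step bins are emitted as 0-based half-open bedGraph intervals;
#' reading refuses overlapping intervals and requires a uniform step.
#'
#' @param track a `signal_track`.
#' @param path file path.
#' @export
write_bedgraph <- function(track, path) {
  rows <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    data.table::data.table(chrom = ch,
                           start = (seq_along(v) - 1L) * track$step,
                           end = seq_along(v) * track$step,
                           value = v)
  })
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  dt <- data.table::fread(path, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"))
  data.table::setorder(dt, chrom, start)
  ov <- dt[, any(start[-1] < end[-.N]), by = chrom]$V1
  if (any(ov)) stop("bedGraph has overlapping intervals")
  steps <- unique(dt$end - dt$start)
  if (length(unique(steps)) > 1 && !all(diff(sort(steps)) == 0)) {
    # allow a truncated final bin per chromosome
    main <- as.integer(names(sort(table(dt$end - dt$start),
                                  decreasing = TRUE))[1])
  } else main <- steps[1]
  values <- lapply(split(dt, dt$chrom), function(d) d$value)
  structure(list(step = main, values = values), class = "signal_track")
}
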
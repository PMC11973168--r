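#' Binned coverage track
#'
#' Per-chromosome vectors of non-negative values at a fixed bin size, plus the
#' normalization state. RPKM values relate to raw counts by
#' `rpkm = raw * 1e9 / (bin_size * total_mapped_reads)` (reads per kilobase of
#' bin per million mapped reads).
#'
#' @param values named list of numeric vectors, one per chromosome; vector
#'   length must be `ceiling(chrom_length / bin_size)`.
#' @param bin_size bin width in bp.
#' @param chrom_lengths named integer vector of chromosome lengths in bp.
#' @param normalization `"raw"` or `"RPKM"`.
#' @param total_mapped_reads total mapped reads backing the track.
#' @return an object of class `coverage_track`.
#' @export
coverage_track <- function(values, bin_size, chrom_lengths,
                           normalization = c("raw", "RPKM"),
                           total_mapped_reads = NA_real_) {
  normalization <- match.arg(normalization)
  stopifnot(is.list(values), length(values) > 0, bin_size >= 1)
  if (is.null(names(values)) || anyDuplicated(names(values)))
    stop("coverage values must be a uniquely named list per chromosome")
  if (!setequal(names(values), names(chrom_lengths)))
    stop("values and chrom_lengths must name the same chromosomes")
  for (chr in names(values)) {
    v <- values[[chr]]
    expect_len <- ceiling(chrom_lengths[[chr]] / bin_size)
    if (length(v) != expect_len)
      stop("chromosome ", chr, ": expected ", expect_len, " bins, got ", length(v))
    if (any(v < 0)) stop("negative coverage on ", chr)
  }
  structure(list(values = values, bin_size = as.integer(bin_size),
                 chrom_lengths = chrom_lengths,
                 normalization = normalization,
                 total_mapped_reads = total_mapped_reads),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track: %d chrom(s), bin %d bp, %s, total mapped %s>\n",
              length(x$values), x$bin_size, x$normalization,
              format(x$total_mapped_reads, big.mark = ",")))
  invisible(x)
}

#' Convert a raw track to RPKM
#'
#' @param track a raw `coverage_track` with known `total_mapped_reads`.
#' @return an RPKM-normalized `coverage_track`.
#' @export
normalize_rpkm <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  if (track$normalization != "raw") stop("track is already normalized")
  tm <- track$total_mapped_reads
  if (is.na(tm) || tm <= 0) stop("total_mapped_reads must be > 0 for RPKM")
  f <- 1e9 / (track$bin_size * tm)
  track$values <- lapply(track$values, function(v) v * f)
  track$normalization <- "RPKM"
  track
}

#' Convert an RPKM track back to raw counts
#' @param track an RPKM `coverage_track`.
#' @return the raw `coverage_track`.
#' @export
denormalize_rpkm <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  if (track$normalization != "RPKM") stop("track is not RPKM-normalized")
  f <- 1e9 / (track$bin_size * track$total_mapped_reads)
  track$values <- lapply(track$values, function(v) v / f)
  track$normalization <- "raw"
  track
}

#' Build a coverage track from read placements
#'
#' Bins read start positions (each read contributes one count at its start
#' bin), so with `bin_size = 1` the bin sum equals the number of reads.
#'
#' @param placements a read-placement table (see [read_placements()]).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param bin_size bin width in bp (default 1).
#' @return a raw `coverage_track`.
#' @export
track_from_placements <- function(placements, chrom_lengths, bin_size = 1L) {
  placements <- data.table::as.data.table(placements)
  vals <- lapply(names(chrom_lengths), function(chr) {
    nb <- ceiling(chrom_lengths[[chr]] / bin_size)
    v <- numeric(nb)
    st <- placements[chrom == chr, start]
    if (length(st)) {
      idx <- floor(st / bin_size) + 1L
      idx <- idx[idx >= 1L & idx <= nb]
      tab <- tabulate(idx, nbins = nb)
      v <- as.numeric(tab)
    }
    v
  })
  names(vals) <- names(chrom_lengths)
  coverage_track(vals, bin_size, chrom_lengths, "raw",
                 total_mapped_reads = nrow(placements))
}
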
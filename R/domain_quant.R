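#' Coverage over a set of regions
#'
#' multicov-style counting: for placements, the raw value is the number of
#' reads overlapping the region by at least 1 bp; for a `coverage_track`, the
#' sum of bin values overlapping the region. RPKM fields are filled when the
#' mapped-read total is known.
#'
#' @param x a placement table or a `coverage_track`.
#' @param regions interval table (chrom, start, end, optional name).
#' @param total_mapped total mapped reads for RPKM; taken from the track when
#'   `x` is a `coverage_track`.
#' @param sample_id replicate label stamped on the rows.
#' @return data.table with `region`, `chrom`, `start`, `end`, `raw`,
#'   `rpkm`, `rpkm_per_kb`.
#' @export
region_coverage <- function(x, regions, total_mapped = NULL,
                            sample_id = "rep1") {
  rg <- as_interval_table(regions)
  if (!"name" %in% names(rg))
    rg$name <- sprintf("region%03d", seq_len(nrow(rg)))
  if (!nrow(rg))
    return(data.table::data.table(region = character(), chrom = character(),
                                  start = numeric(), end = numeric(),
                                  raw = numeric(), rpkm = numeric(),
                                  rpkm_per_kb = numeric(),
                                  sample_id = character()))
  if (inherits(x, "coverage_track")) {
    unknown <- setdiff(unique(rg$chrom), names(x$values))
    if (length(unknown)) stop("region on unknown chromosome: ",
                              paste(unknown, collapse = ", "))
    if (is.null(total_mapped)) total_mapped <- x$total_mapped_reads
    raw <- vapply(seq_len(nrow(rg)), function(i) {
      v <- x$values[[rg$chrom[i]]]
      b0 <- floor(rg$start[i] / x$bin_size) + 1L
      b1 <- ceiling(rg$end[i] / x$bin_size)
      sum(v[b0:min(b1, length(v))])
    }, numeric(1))
  } else {
    dt <- data.table::as.data.table(x)
    if (is.null(total_mapped)) total_mapped <- nrow(dt)
    raw <- vapply(seq_len(nrow(rg)), function(i)
      sum(dt$chrom == rg$chrom[i] & dt$start < rg$end[i] &
            dt$end > rg$start[i]), numeric(1))
  }
  len <- rg$end - rg$start
  rpkm <- if (!is.null(total_mapped) && !is.na(total_mapped) && total_mapped > 0)
    raw * 1e9 / (len * total_mapped) else NA_real_
  data.table::data.table(region = rg$name, chrom = rg$chrom, start = rg$start,
                         end = rg$end, raw = raw, rpkm = rpkm,
                         rpkm_per_kb = rpkm / (len / 1000),
                         sample_id = sample_id)
}

#' Inside/outside domain coverage ratio
#'
#' The sub-TAD enrichment statistic: coverage density inside the domain
#' divided by coverage density in a nearby control region, each normalized by
#' region length so unequal region sizes are comparable:
#' `ratio = (inside / inside_length) / (outside / outside_length)`. With
#' several replicates, per-replicate ratios plus mean and sd are reported.
#'
#' @param x a `coverage_track`, a placement table, or a list of either (one
#'   per replicate).
#' @param inside,outside [gi()] intervals (e.g. the convergent-CTCF-flanked
#'   domain and a size-matched region outside it).
#' @return list with `per_replicate` (data.table: `sample_id`, `inside`,
#'   `outside`, `ratio`, `undefined`), `mean` and `sd`. Zero outside
#'   coverage flags the replicate `undefined` (ratio `NA`).
#' @export
coverage_ratio <- function(x, inside, outside) {
  stopifnot(inherits(inside, "genomic_interval"),
            inherits(outside, "genomic_interval"))
  reps <- if (inherits(x, "coverage_track") || is.data.frame(x)) list(rep1 = x)
          else x
  if (is.null(names(reps)))
    names(reps) <- sprintf("rep%d", seq_along(reps))
  regions <- data.table::data.table(
    chrom = c(inside$chrom, outside$chrom),
    start = c(inside$start, outside$start),
    end = c(inside$end, outside$end),
    name = c("inside", "outside"))
  rows <- lapply(names(reps), function(nm) {
    cv <- region_coverage(reps[[nm]], regions, sample_id = nm)
    ins <- cv$raw[cv$region == "inside"] / interval_length(inside)
    out <- cv$raw[cv$region == "outside"] / interval_length(outside)
    data.table::data.table(sample_id = nm,
                           inside = cv$raw[cv$region == "inside"],
                           outside = cv$raw[cv$region == "outside"],
                           ratio = if (out == 0) NA_real_ else ins / out,
                           undefined = out == 0)
  })
  pr <- data.table::rbindlist(rows)
  list(per_replicate = pr,
       mean = mean(pr$ratio, na.rm = TRUE),
       sd = stats::sd(pr$ratio, na.rm = TRUE))
}

#' Threshold peak caller
#'
#' Deterministic stand-in for ML peak calling: bins exceeding `m` times the
#' genome-wide median bin value are merged when at most `gap` bp apart, and
#' resulting intervals shorter than `min_width` bp are dropped. On a
#' zero-median track (mostly empty genome) the threshold degenerates to 0 and
#' every nonzero bin is peak material, which keeps the caller idempotent on
#' its own rasterized output.
#'
#' @param track a `coverage_track`.
#' @param m threshold multiplier over the genome-wide median (default 5;
#'   must be > 1).
#' @param gap merge distance in bp (default 200).
#' @param min_width minimum peak width in bp (default 150).
#' @return interval table of peaks (possibly empty).
#' @export
call_peaks <- function(track, m = 5, gap = 200, min_width = 150) {
  stopifnot(inherits(track, "coverage_track"), m > 1)
  allv <- unlist(track$values, use.names = FALSE)
  if (!length(allv) || all(allv == 0))
    return(data.table::data.table(chrom = character(), start = numeric(),
                                  end = numeric()))
  thr <- m * stats::median(allv)
  bs <- track$bin_size
  out <- lapply(names(track$values), function(chr) {
    v <- track$values[[chr]]
    hot <- which(v > thr)
    if (!length(hot)) return(NULL)
    iv <- IRanges::reduce(IRanges::IRanges(start = hot, end = hot),
                          min.gapwidth = floor(gap / bs) + 1L)
    data.table::data.table(chrom = chr,
                           start = (BiocGenerics::start(iv) - 1) * bs,
                           end = pmin(BiocGenerics::end(iv) * bs,
                                      track$chrom_lengths[[chr]]))
  })
  pk <- data.table::rbindlist(out)
  if (!nrow(pk)) return(data.table::data.table(chrom = character(),
                                               start = numeric(), end = numeric()))
  pk[pk$end - pk$start >= min_width]
}

#' Rule-based cis-regulatory element classification
#'
#' Simplified rank-rule classifier over mean signals at a site (deliberately
#' transparent, no ML): (1) CTCF alone when both H3K4me3 and H3K4me1 are
#' below threshold and CTCF above; (2) promoter when H3K4me3 >= H3K4me1 and
#' above threshold, `+CTCF` when CTCF also above; (3) enhancer when
#' H3K4me1 > H3K4me3 and above threshold, `+CTCF` likewise; (4) otherwise
#' unclassified.
#'
#' @param signals named numeric vector (or 1-row data.frame) with mean RPKM
#'   over the site for `H3K4me3`, `H3K4me1`, `H3K27ac`, `CTCF`.
#' @param threshold enrichment threshold applied to each mark (default 1).
#' @return one of `"promoter"`, `"enhancer"`, `"CTCF"`, `"promoter+CTCF"`,
#'   `"enhancer+CTCF"`, `"unclassified"`.
#' @export
classify_cre <- function(signals, threshold = 1) {
  sig <- unlist(signals)
  req <- c("H3K4me3", "H3K4me1", "H3K27ac", "CTCF")
  miss <- setdiff(req, names(sig))
  if (length(miss)) stop("missing signals: ", paste(miss, collapse = ", "))
  if (any(sig[req] < 0)) stop("negative signal")
  k3 <- sig[["H3K4me3"]]; k1 <- sig[["H3K4me1"]]; ct <- sig[["CTCF"]]
  ctcf_bound <- ct > threshold
  if (k3 <= threshold && k1 <= threshold)
    return(if (ctcf_bound) "CTCF" else "unclassified")
  if (k3 >= k1) {
    if (k3 > threshold) return(if (ctcf_bound) "promoter+CTCF" else "promoter")
  } else {
    if (k1 > threshold) return(if (ctcf_bound) "enhancer+CTCF" else "enhancer")
  }
  "unclassified"
}

#' Neutral-criteria bundle for the activatable-region scan
#'
#' @param compartments A-compartment interval table.
#' @param exclusion_tracks named list of `coverage_track`s to exclude signal
#'   from (repressive marks, open chromatin, active marks).
#' @param genes gene-annotation interval table (always excluded).
#' @param signal_threshold per-track bin-value threshold above which a bin is
#'   masked (single value or named per track).
#' @param merge_distance padding/merging distance in bp around masked bins.
#' @param min_length minimum candidate-region length in bp.
#' @return an object of class `neutral_criteria`.
#' @export
neutral_criteria <- function(compartments, exclusion_tracks = list(),
                             genes = NULL, signal_threshold = 0,
                             merge_distance = 1000, min_length = 1e5) {
  stopifnot(min_length > 0, merge_distance >= 0, all(signal_threshold >= 0))
  structure(list(compartments = as_interval_table(compartments),
                 exclusion_tracks = exclusion_tracks,
                 genes = if (is.null(genes)) NULL else as_interval_table(genes),
                 signal_threshold = signal_threshold,
                 merge_distance = merge_distance,
                 min_length = min_length),
            class = "neutral_criteria")
}

#' Scan for neutral but activatable regions
#'
#' Builds an exclusion mask as the union of (bins above each track's
#' threshold, padded by the merge distance) and the gene annotations, then
#' subtracts it from the A-compartment intervals restricted to one
#' chromosome. Maximal residual intervals at least `min_length` bp long are
#' returned sorted by length, longest first.
#'
#' @param criteria a [neutral_criteria()] bundle.
#' @param chromosome chromosome to restrict the scan to (the X-chromosome
#'   restriction of the original design is one such choice).
#' @return interval table of candidate neutral regions (possibly empty, with
#'   a warning when no A-compartment interval lies on the chromosome).
#' @export
scan_neutral_regions <- function(criteria, chromosome) {
  stopifnot(inherits(criteria, "neutral_criteria"))
  comp <- criteria$compartments[criteria$compartments$chrom == chromosome]
  if (!nrow(comp)) {
    warning("no A-compartment intervals on ", chromosome)
    return(data.table::data.table(chrom = character(), start = numeric(),
                                  end = numeric()))
  }
  comp_ir <- IRanges::reduce(IRanges::IRanges(comp$start + 1, comp$end))
  mask_list <- list()
  thr_for <- function(nm) {
    th <- criteria$signal_threshold
    if (length(th) > 1L && !is.null(names(th)) && nm %in% names(th)) th[[nm]]
    else th[[1]]
  }
  for (nm in names(criteria$exclusion_tracks)) {
    tr <- criteria$exclusion_tracks[[nm]]
    stopifnot(inherits(tr, "coverage_track"))
    if (!chromosome %in% names(tr$values)) next
    v <- tr$values[[chromosome]]
    hot <- which(v > thr_for(nm))
    if (!length(hot)) next
    bs <- tr$bin_size
    iv <- IRanges::IRanges(start = (hot - 1L) * bs + 1L, end = hot * bs)
    iv <- IRanges::reduce(iv + criteria$merge_distance)
    mask_list[[length(mask_list) + 1L]] <- iv
  }
  if (!is.null(criteria$genes)) {
    g <- criteria$genes[criteria$genes$chrom == chromosome]
    if (nrow(g))
      mask_list[[length(mask_list) + 1L]] <-
        IRanges::IRanges(g$start + 1, g$end)
  }
  cand <- if (length(mask_list)) {
    mask <- IRanges::reduce(do.call(c, mask_list))
    BiocGenerics::setdiff(comp_ir, mask)
  } else comp_ir
  cand <- cand[IRanges::width(cand) >= criteria$min_length]
  out <- data.table::data.table(chrom = chromosome,
                                start = BiocGenerics::start(cand) - 1,
                                end = BiocGenerics::end(cand))
  out[order(-(out$end - out$start))]
}
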
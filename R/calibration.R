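#' Spike-in down-sampling factors
#'
#' For each sample the raw factor is
#' `1 / (total spike-in ChIP reads) * (total spike-in Input reads / total
#' target Input reads)`; the bulk coefficient `alpha = 1 / max(raw)` then
#' rescales the set so the largest final factor equals exactly 1. The
#' Input-ratio term is what corrects for minor variation in spike-in cell
#' mixing between replicates; target-ChIP depth does not enter.
#'
#' @param totals data.frame with one row per sample and columns `sample_id`,
#'   `total_reads_spikein_chip`, `total_reads_spikein_input`,
#'   `total_reads_target_input` (a `total_reads_target_chip` column is
#'   tolerated and ignored).
#' @return an object of class `calibration_set`: the per-sample table with
#'   `raw_factor` and `final_factor` columns, plus `alpha`.
#' @export
compute_downsampling_factors <- function(totals) {
  dt <- data.table::as.data.table(totals)
  req <- c("sample_id", "total_reads_spikein_chip",
           "total_reads_spikein_input", "total_reads_target_input")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stop("totals table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!nrow(dt)) stop("empty totals table")
  bad <- dt$total_reads_spikein_chip <= 0 | dt$total_reads_target_input <= 0
  if (any(bad))
    stop("undefined factor (zero spike-in ChIP or target Input reads) for ",
         "sample(s): ", paste(dt$sample_id[bad], collapse = ", "))
  dt$raw_factor <- (1 / dt$total_reads_spikein_chip) *
    (dt$total_reads_spikein_input / dt$total_reads_target_input)
  alpha <- 1 / max(dt$raw_factor)
  dt$final_factor <- alpha * dt$raw_factor
  # ties at the max all map to exactly 1
  dt$final_factor[dt$raw_factor == max(dt$raw_factor)] <- 1
  structure(list(samples = dt, alpha = alpha), class = "calibration_set")
}

#' @export
print.calibration_set <- function(x, ...) {
  cat(sprintf("<calibration_set: %d sample(s), alpha = %.6g>\n",
              nrow(x$samples), x$alpha))
  print(x$samples[, c("sample_id", "raw_factor", "final_factor")])
  invisible(x)
}

#' Randomly subsample reads by a down-sampling factor
#'
#' Each read is kept independently with probability `factor` under a seeded
#' generator (streaming Bernoulli semantics); `exact = TRUE` instead keeps
#' exactly `round(factor * n)` reads chosen uniformly. The sample holding the
#' maximum factor (1) keeps all reads either way.
#'
#' @param placements read-placement table.
#' @param factor keep probability in `(0, 1]`.
#' @param seed random seed.
#' @param exact use exact-count draw instead of per-read Bernoulli.
#' @return the subsampled placement table.
#' @export
subsample_reads <- function(placements, factor, seed = 1L, exact = FALSE) {
  if (factor <= 0 || factor > 1) stop("factor must lie in (0, 1]")
  dt <- data.table::as.data.table(placements)
  if (factor == 1 || !nrow(dt)) return(dt)
  set.seed(seed)
  if (exact) {
    k <- round(factor * nrow(dt))
    dt[sort(sample.int(nrow(dt), k)), ]
  } else {
    dt[stats::runif(nrow(dt)) < factor, ]
  }
}

#' Diagnose spike-in mixing ratios across replicates
#'
#' The Input-ratio term of the down-sampling factor already performs the
#' mixing correction; this diagnostic reports each sample's
#' spike-in/target Input ratio and flags samples deviating from the cohort
#' median by more than `flag_threshold` (fractional, default 0.5).
#'
#' @param totals totals table as in [compute_downsampling_factors()].
#' @param flag_threshold fractional deviation from the cohort median that
#'   triggers a flag.
#' @return data.table with `sample_id`, `mixing_ratio`, `cohort_median`,
#'   `flagged`; a single-sample set is never flagged (no cohort).
#' @export
input_correction <- function(totals, flag_threshold = 0.5) {
  dt <- data.table::as.data.table(totals)
  ratio <- dt$total_reads_spikein_input / dt$total_reads_target_input
  med <- stats::median(ratio)
  flagged <- if (nrow(dt) < 2) rep(FALSE, nrow(dt))
             else abs(ratio - med) / med > flag_threshold
  data.table::data.table(sample_id = dt$sample_id, mixing_ratio = ratio,
                         cohort_median = med, flagged = flagged)
}

#' RPKM coverage track from read placements
#'
#' Builds a binned raw track from the placements (start-position binning) and
#' converts it to reads-per-kilobase-per-million-mapped:
#' `value = raw * 1e9 / (bin_size * total_mapped)`.
#'
#' @param placements read-placement table.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param bin_size bin width in bp (default 1, the single-bp convention).
#' @return an RPKM `coverage_track`.
#' @export
rpkm_track <- function(placements, chrom_lengths, bin_size = 1L) {
  dt <- data.table::as.data.table(placements)
  if (!nrow(dt)) stop("zero mapped reads: RPKM undefined")
  raw <- track_from_placements(dt, chrom_lengths, bin_size = bin_size)
  normalize_rpkm(raw)
}
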
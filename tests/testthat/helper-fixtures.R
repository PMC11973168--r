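# shared fixture builders; everything is generated in code, no stored data

random_genome <- function(len = 1000, chrom = "chr1", seed = 1) {
  set.seed(seed)
  genome_sequence(stats::setNames(
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    chrom))
}

# flat coverage track with optional hot blocks (list of c(start, end, value))
flat_track <- function(chrom_len = 1e5, bin_size = 100, base = 0,
                       blocks = list(), chrom = "chr1") {
  nb <- ceiling(chrom_len / bin_size)
  v <- rep(base, nb)
  for (b in blocks) {
    i0 <- floor(b[1] / bin_size) + 1
    i1 <- ceiling(b[2] / bin_size)
    v[i0:i1] <- b[3]
  }
  coverage_track(stats::setNames(list(v), chrom), bin_size,
                 stats::setNames(chrom_len, chrom),
                 total_mapped_reads = sum(v))
}

# a consensus PWM: probability `p` on the consensus base per column
consensus_pwm <- function(consensus, id = "cons", p = 0.97) {
  bases <- c("A", "C", "G", "T")
  cols <- strsplit(consensus, "")[[1]]
  mat <- vapply(cols, function(b) {
    v <- rep((1 - p) / 3, 4); v[match(b, bases)] <- p; v
  }, numeric(4))
  pwm(id = id, mat = matrix(mat, nrow = 4))
}

# haplotype-count rows in one call
hc <- function(c1, c2, id = "v1", assay = "ATAC", donor = "donor1",
               zeroed = FALSE, in_peak = TRUE) {
  data.table::data.table(variant_id = id, assay = assay, donor = donor,
                         count_hap1 = as.integer(c1),
                         count_hap2 = as.integer(c2),
                         zeroed = zeroed, in_peak = in_peak)
}

# placement rows from start/end vectors on one chromosome
mk_placements <- function(starts, ends, chrom = "chr1", genome = "target",
                          source = "target") {
  data.table::data.table(read_id = sprintf("r%04d", seq_along(starts)),
                         genome = genome, chrom = chrom,
                         start = as.integer(starts), end = as.integer(ends),
                         mate_start = NA_integer_, mate_end = NA_integer_,
                         source = source)
}
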
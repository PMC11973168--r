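test_that("region coverage counts >= 1 bp overlaps, multicov-style", {
  regions <- data.table::data.table(chrom = "chr1", start = 100L, end = 200L,
                                    name = "r1")
  pl <- mk_placements(c(110, 140, 160, 199, 30, 250),
                      c(160, 190, 195, 260, 101, 300))
  cv <- region_coverage(pl, regions)
  expect_equal(cv$raw, 5)   # three inside + two straddling by >= 1 bp
  expect_equal(nrow(region_coverage(pl, regions[0])), 0L)
  tr <- flat_track(chrom_len = 1000, bin_size = 10, base = 2)
  expect_equal(region_coverage(tr, regions)$raw, 2 * 10)
  expect_error(region_coverage(tr, data.frame(chrom = "chrZ", start = 0,
                                              end = 10)), "unknown chromosome")
})

test_that("coverage ratio is length-normalized and depth-scale invariant", {
  inside <- gi("chr1", 10000, 70000)    # 60 kb
  outside <- gi("chr1", 80000, 95000)   # 15 kb, deliberately size-mismatched
  uni <- flat_track(chrom_len = 1e5, bin_size = 100, base = 4)
  r <- coverage_ratio(uni, inside, outside)
  expect_equal(r$per_replicate$ratio, 1)
  # scaling the whole track by a constant leaves the ratio unchanged
  sc <- uni; sc$values$chr1 <- sc$values$chr1 * 17
  expect_equal(coverage_ratio(sc, inside, outside)$per_replicate$ratio, 1)
  # inside empty -> ratio 0; outside empty -> undefined, flagged
  z <- flat_track(chrom_len = 1e5, bin_size = 100, base = 0,
                  blocks = list(c(80000, 95000, 3)))
  expect_equal(coverage_ratio(z, inside, outside)$per_replicate$ratio, 0)
  z2 <- flat_track(chrom_len = 1e5, bin_size = 100, base = 0,
                   blocks = list(c(10000, 70000, 3)))
  rr <- coverage_ratio(z2, inside, outside)$per_replicate
  expect_true(is.na(rr$ratio)); expect_true(rr$undefined)
})

test_that("a planted 6-fold enrichment is recovered within 10%", {
  set.seed(6)
  mk_rep <- function(seed) {
    set.seed(seed)
    nb <- 2000  # 100 bp bins over 200 kb
    v <- rpois(nb, 50)
    ins <- 101:700   # 60 kb inside-domain block
    v[ins] <- rpois(length(ins), 300)
    coverage_track(list(chr1 = v), 100, c(chr1 = 2e5),
                   total_mapped_reads = sum(v))
  }
  inside <- gi("chr1", 10000, 70000)
  outside <- gi("chr1", 100000, 160000)
  reps <- lapply(1:3, mk_rep)
  r <- coverage_ratio(reps, inside, outside)
  expect_equal(nrow(r$per_replicate), 3L)
  expect_lt(abs(r$mean - 6) / 6, 0.10)
  # no enrichment: per-replicate ratios straddle 1 within sampling noise
  null_reps <- lapply(11:13, function(s) {
    set.seed(s); coverage_track(list(chr1 = rpois(2000, 50)), 100,
                                c(chr1 = 2e5),
                                total_mapped_reads = NA_real_)
  })
  rn <- coverage_ratio(null_reps, inside, outside)
  se <- rn$sd / sqrt(3)
  expect_true(abs(rn$mean - 1) <= 3 * max(se, 0.01))
})

test_that("threshold peak caller merges, filters and is idempotent", {
  expect_equal(nrow(call_peaks(flat_track(base = 1))), 0L)  # flat: no peaks
  # single hot block becomes one peak covering the block
  tr <- flat_track(chrom_len = 1e5, bin_size = 50, base = 1,
                   blocks = list(c(20000, 20500, 100)))
  pk <- call_peaks(tr, m = 5, gap = 200, min_width = 100)
  expect_equal(nrow(pk), 1L)
  expect_lte(pk$start, 20000); expect_gte(pk$end, 20500)
  # blocks 50 bp apart merge at gap = 100
  tr2 <- flat_track(chrom_len = 1e5, bin_size = 50, base = 1,
                    blocks = list(c(30000, 30300, 100), c(30350, 30650, 100)))
  expect_equal(nrow(call_peaks(tr2, m = 5, gap = 100, min_width = 100)), 1L)
  expect_equal(nrow(call_peaks(tr2, m = 5, gap = 10, min_width = 100)), 2L)
  # narrow blips below min_width are dropped
  tr3 <- flat_track(chrom_len = 1e5, bin_size = 50, base = 1,
                    blocks = list(c(40000, 40050, 100)))
  expect_equal(nrow(call_peaks(tr3, m = 5, gap = 10, min_width = 150)), 0L)
  # idempotence: rasterizing called peaks and re-calling returns them
  pk2 <- call_peaks(tr2, m = 5, gap = 100, min_width = 100)
  rast <- flat_track(chrom_len = 1e5, bin_size = 50, base = 0,
                     blocks = lapply(seq_len(nrow(pk2)), function(i)
                       c(pk2$start[i], pk2$end[i], 10)))
  pk3 <- call_peaks(rast, m = 5, gap = 100, min_width = 100)
  expect_equal(pk3$start, pk2$start)
  expect_equal(pk3$end, pk2$end)
})

test_that("rule-based CRE classification follows the rank rules", {
  cls <- function(k3, k1, ctcf, thr = 1)
    classify_cre(c(H3K4me3 = k3, H3K4me1 = k1, H3K27ac = 0, CTCF = ctcf),
                 threshold = thr)
  expect_equal(cls(10, 2, 0), "promoter")
  expect_equal(cls(1, 8, 5, thr = 2), "enhancer+CTCF")
  expect_equal(cls(0, 0, 0), "unclassified")
  expect_equal(cls(0.5, 0.2, 6), "CTCF")
  expect_equal(cls(4, 9, 0.5), "enhancer")
  expect_equal(cls(9, 4, 3), "promoter+CTCF")
  expect_equal(cls(9, 9, 0), "promoter")        # K4me3 >= K4me1 tie -> promoter
  expect_error(cls(-1, 0, 0), "negative")
  expect_error(classify_cre(c(H3K4me3 = 1, H3K4me1 = 1)), "missing signals")
})

test_that("neutral-region scan subtracts masked signal from A compartments", {
  chrom_len <- 1e6
  # A compartment covers [0, 600k); B elsewhere
  comp <- data.table::data.table(chrom = "chrX", start = 0L, end = 600000L)
  mk_tr <- function(blocks) flat_track(chrom_len = chrom_len, bin_size = 1000,
                                       base = 0, blocks = blocks,
                                       chrom = "chrX")
  genes <- data.table::data.table(chrom = "chrX", start = 450000L,
                                  end = 470000L)
  # signal everywhere except a planted 120 kb clean gap at [200k, 320k)
  tracks <- list(
    H3K9me3 = mk_tr(list(c(0, 200000, 5))),
    ATAC = mk_tr(list(c(320000, 430000, 5))),
    H3K4me1 = mk_tr(list(c(480000, 600000, 5))))
  crit <- neutral_criteria(comp, tracks, genes, signal_threshold = 1,
                           merge_distance = 0, min_length = 1e5)
  out <- scan_neutral_regions(crit, "chrX")
  expect_equal(nrow(out), 1L)
  expect_equal(out$start, 200000)
  expect_equal(out$end, 320000)
  # brute-force bin-scan oracle: longest clean run inside the A compartment
  bin <- 1000
  masked <- rep(FALSE, chrom_len / bin)
  for (tr in tracks) masked <- masked | tr$values$chrX > 1
  masked[(genes$start / bin + 1):(genes$end / bin)] <- TRUE
  inA <- seq_len(chrom_len / bin) <= 600000 / bin
  runs <- rle(!masked & inA)
  expect_equal(max(runs$lengths[runs$values]) * bin, out$end - out$start)
  # a 90 kb gap fails the 100 kb minimum
  crit90 <- neutral_criteria(comp, c(tracks, list(
    extra = mk_tr(list(c(290000, 320000, 5))))), genes,
    signal_threshold = 1, merge_distance = 0, min_length = 1e5)
  expect_equal(nrow(scan_neutral_regions(crit90, "chrX")), 0L)
  # full mask -> empty; wrong chromosome -> warning
  critfull <- neutral_criteria(comp, list(all = mk_tr(list(c(0, 1e6, 9)))),
                               NULL, signal_threshold = 1, min_length = 1e5)
  expect_equal(nrow(scan_neutral_regions(critfull, "chrX")), 0L)
  expect_warning(scan_neutral_regions(crit, "chr7"), "no A-compartment")
})

test_that("neutral regions never overlap exclusions and stay inside A", {
  set.seed(13)
  chrom_len <- 5e5
  comp <- data.table::data.table(chrom = "chrX",
                                 start = c(0L, 300000L),
                                 end = c(250000L, 500000L))
  for (rep in 1:5) {
    v <- numeric(chrom_len / 1000)
    hot <- sample(length(v), 150)
    v[hot] <- runif(150, 2, 10)
    tr <- coverage_track(list(chrX = v), 1000, c(chrX = chrom_len))
    crit <- neutral_criteria(comp, list(sig = tr), NULL,
                             signal_threshold = 1, merge_distance = 500,
                             min_length = 5000)
    out <- scan_neutral_regions(crit, "chrX")
    if (!nrow(out)) next
    for (i in seq_len(nrow(out))) {
      bins <- (floor(out$start[i] / 1000) + 1):(ceiling(out$end[i] / 1000))
      expect_true(all(v[bins] <= 1))
      expect_true(any(out$start[i] >= comp$start & out$end[i] <= comp$end))
    }
  }
})
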
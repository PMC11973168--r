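test_that("haplotype counting tallies reads per allele inside peaks", {
  vars <- data.table::data.table(chrom = "chr1", pos = c(100L, 500L, 900L),
                                 id = c("v1", "v2", "v3"),
                                 ref = "A", alt = "C",
                                 gt1 = c(0L, 0L, 1L), gt2 = c(1L, 1L, 1L),
                                 phased = TRUE, het = c(TRUE, TRUE, FALSE))
  peaks <- data.table::data.table(chrom = "chr1", start = 50L, end = 200L)
  p1 <- mk_placements(rep(60, 12), rep(160, 12))  # 12 reads over pos 100
  p2 <- mk_placements(rep(70, 8), rep(170, 8))    #  8 reads over pos 100
  cnt <- count_haplotype_reads(list(hap1 = p1, hap2 = p2), vars, peaks,
                               assay = "ATAC", donor = "donor1")
  expect_equal(nrow(cnt), 2L)          # homozygous v3 yields no record
  expect_equal(cnt[cnt$variant_id == "v1", count_hap1], 12L)
  expect_equal(cnt[cnt$variant_id == "v1", count_hap2], 8L)
  expect_true(cnt[cnt$variant_id == "v1", in_peak])
  expect_false(cnt[cnt$variant_id == "v2", in_peak])  # outside all peaks
  # unphased hets are skipped with a log
  vars$phased[1] <- FALSE
  expect_warning(cnt2 <- count_haplotype_reads(list(hap1 = p1, hap2 = p2),
                                               vars, peaks), "unphased")
  expect_false("v1" %in% cnt2$variant_id)
})

test_that("bias zeroing applies the tau depth-discrepancy rule", {
  counts <- rbind(hc(50, 50, id = "a"), hc(60, 5, id = "b"), hc(0, 0, id = "c"),
                  hc(30, 30, id = "d"))
  depths <- data.table::data.table(
    variant_id = c("a", "b", "c", "d"),
    depth_ref = c(100, 60, 0, 0),
    depth_hap1 = c(100, 100, 0, 30),
    depth_hap2 = c(102, 10, 0, 30))
  z <- zero_bias_sites(counts, depths, tau = 0.2)
  expect_false(z[z$variant_id == "a", zeroed])   # within tolerance
  expect_true(z[z$variant_id == "b", zeroed])    # 100 vs 10 discordant
  expect_equal(z[z$variant_id == "b", count_hap1], 0L)
  expect_true(z[z$variant_id == "c", zeroed])    # all-zero site
  expect_true(z[z$variant_id == "d", zeroed])    # reference dropout
  expect_error(zero_bias_sites(counts, depths, tau = 0), "tau")
  expect_error(zero_bias_sites(counts, depths, tau = 1.5), "tau")
})

test_that("exact binomial skew test matches closed forms and conventions", {
  r <- skew_test(hc(10, 10))
  expect_equal(r$s, 0.5)
  expect_equal(r$p_value, 1)
  expect_equal(r$direction, "none")
  r2 <- skew_test(hc(20, 0))
  expect_equal(r2$p_value, 2 * 0.5^20, tolerance = 1e-12)
  expect_equal(r2$direction, "up")
  r3 <- skew_test(hc(0, 20))
  expect_equal(r3$direction, "down")
  r0 <- skew_test(hc(0, 0))
  expect_true(is.na(r0$p_value))
  expect_equal(r0$direction, "none")
})

test_that("binomial skew p equals the stats::binom.test oracle for all n <= 30", {
  for (n in 1:30) {
    counts <- hc(0:n, n - 0:n, id = sprintf("v%d", 0:n))
    got <- skew_test(counts)$p_value
    want <- vapply(0:n, function(k) stats::binom.test(k, n, 0.5)$p.value,
                   numeric(1))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("beta-binomial variant is more conservative under overdispersion", {
  p_bin <- skew_test(hc(30, 10))$p_value
  p_bb <- skew_test(hc(30, 10), method = "betabinomial", rho = 0.2)$p_value
  expect_gt(p_bb, p_bin)
  # beta-binomial pmf sums to 1 (sanity of the hand-rolled density)
  pmf <- skewdomain:::.betabinom_pmf(0.2)
  expect_equal(sum(pmf(0:40, 40)), 1, tolerance = 1e-9)
  expect_error(skew_test(hc(5, 5), method = "betabinomial", rho = 2), "rho")
})

test_that("type-I error is controlled at the discrete-conservative level", {
  set.seed(404)
  n_var <- 10000
  tot <- rpois(n_var, 100)
  c1 <- rbinom(n_var, tot, 0.5)
  res <- skew_test(hc(c1, tot - c1, id = sprintf("v%d", 1:n_var)))
  rate <- mean(res$p_value < 0.05, na.rm = TRUE)
  expect_lte(rate, 0.055)
  expect_gte(rate, 0.035)
})

test_that("rejection rate grows with imbalance and depth", {
  set.seed(99)
  n_var <- 2000
  rates <- matrix(NA_real_, 3, 3)
  ratios <- c(1, 2, 4); depths <- c(20, 100, 500)
  for (i in seq_along(ratios)) for (j in seq_along(depths)) {
    pr <- ratios[i] / (1 + ratios[i])
    tot <- rpois(n_var, depths[j])
    c1 <- rbinom(n_var, tot, pr)
    res <- skew_test(hc(c1, tot - c1, id = sprintf("v%d", 1:n_var)))
    rates[i, j] <- mean(res$p_value < 0.05, na.rm = TRUE)
  }
  slack <- 0.015  # Monte-Carlo jitter at the null corner
  expect_true(all(diff(rates[, 2]) > -slack))  # more imbalance, more power
  expect_true(all(diff(rates[2, ]) > -slack))  # more depth, more power
  expect_gt(rates[3, 3], 0.99)
})

test_that("consistent skew requires direction agreement across observations", {
  res <- rbind(
    skew_test(hc(40, 0, id = "v1", donor = "donor1")),
    skew_test(hc(35, 2, id = "v1", donor = "donor2")),
    skew_test(hc(40, 0, id = "v2", donor = "donor1")),
    skew_test(hc(0, 38, id = "v2", donor = "donor2")),
    skew_test(hc(11, 9, id = "v3", donor = "donor1")))
  keep <- consistent_skew_variants(res)
  expect_equal(keep$variant_id, "v1")       # v2 mixed, v3 never significant
  expect_equal(keep$direction, "up")
  expect_equal(keep$n_support, 2L)
})

test_that("extreme-region selection enforces het significance and class mix", {
  gt <- data.table::data.table(
    variant_id = rep(c("v1", "v2", "v3"), each = 3),
    donor = rep(c("donor1", "donor2", "donor3"), 3),
    genotype = c("hom_ref", "het", "hom_alt",
                 "hom_ref", "het", "hom_alt",
                 "hom_ref", "hom_ref", "hom_ref"))
  res <- rbind(skew_test(hc(40, 0, id = "v1", donor = "donor2")),
               skew_test(hc(12, 8, id = "v2", donor = "donor2")),
               skew_test(hc(40, 0, id = "v3", donor = "donor2")))
  # check the closed-form anchors behind the fixture
  expect_lt(res$p_value[res$variant_id == "v1"], 1e-4)     # ~1.8e-12
  expect_gt(res$p_value[res$variant_id == "v2"], 0.4)      # ~0.50
  sel <- select_extreme_regions(res, gt, p_threshold = 1e-4)
  expect_equal(sel$variant_id, "v1")
  expect_error(select_extreme_regions(res, gt[gt$donor == "donor1"]),
               "2 donors")
})

test_that("genotype-group meta-analysis reproduces the paired-t closed form", {
  mk_cov <- function(region, genotype, value)
    data.table::data.table(region = region, donor = "d", genotype = genotype,
                           raw_count = value, total_mapped = 1e9,
                           region_length = 1000)
  # identical groups: t = 0, p = 1
  cov0 <- rbind(mk_cov(c("r1", "r2"), "hom_ref", c(5, 7)),
                mk_cov(c("r1", "r2"), "hom_alt", c(5, 7)))
  m0 <- genotype_group_meta(cov0)
  expect_equal(m0$tests$t, 0)
  expect_equal(m0$tests$p_value, 1)
  # A = (1,2,3), B = (2,4,3): |t| = sqrt(3), df 2, p ~ 0.2254
  covt <- rbind(mk_cov(c("r1", "r2", "r3"), "hom_ref", c(1, 2, 3)),
                mk_cov(c("r1", "r2", "r3"), "hom_alt", c(2, 4, 3)))
  mt <- genotype_group_meta(covt)
  expect_equal(abs(mt$tests$t), sqrt(3), tolerance = 1e-9)
  expect_equal(mt$tests$df, 2)
  expect_equal(mt$tests$p_value, 2 * stats::pt(-sqrt(3), 2), tolerance = 1e-9)
  expect_equal(mt$tests$p_value, 0.2254, tolerance = 1e-3)
  # single pair: undefined
  cov1 <- rbind(mk_cov("r1", "hom_ref", 5), mk_cov("r1", "hom_alt", 6))
  expect_equal(genotype_group_meta(cov1)$tests$note, "undefined")
  # normalization: RPKM further divided by region length in kb
  covn <- mk_cov("r1", "het", 100)
  vn <- genotype_group_meta(covn)$region_values$value
  expect_equal(vn, (100 * 1e9 / (1000 * 1e9)) / (1000 / 1000))
})

test_that("meta-analysis on the simulated cohort orders genotype groups", {
  cfg <- synthetic_config(kappa = 50, damage_factor = 0, depth = 100,
                          seed = 77)
  co <- simulate_skew_cohort(n_regions = 51, config = cfg)
  mt <- genotype_group_meta(co$coverage)
  gm <- stats::setNames(mt$group_means$mean_value, mt$group_means$genotype)
  expect_gt(gm[["hom_ref"]], gm[["het"]])
  expect_gt(gm[["het"]], gm[["hom_alt"]])
  t_extreme <- mt$tests[(mt$tests$class_a == "hom_ref" &
                           mt$tests$class_b == "hom_alt") |
                          (mt$tests$class_a == "hom_alt" &
                             mt$tests$class_b == "hom_ref"), ]
  expect_lte(t_extreme$p_value, 0.05)
  expect_equal(t_extreme$n_pairs, 51L)
})

test_that("cross-assay skew correlation has the right fixed points", {
  s <- seq(0.1, 0.9, length.out = 20)
  ra <- data.table::data.table(variant_id = sprintf("v%d", 1:20), s = s)
  rb <- data.table::data.table(variant_id = sprintf("v%d", 1:20), s = s)
  expect_equal(cross_assay_skew_correlation(ra, rb, n_boot = 50)$rho, 1)
  rb2 <- data.table::data.table(variant_id = sprintf("v%d", 1:20), s = 1 - s)
  expect_equal(cross_assay_skew_correlation(ra, rb2, n_boot = 50)$rho, -1)
  expect_error(cross_assay_skew_correlation(ra[1:2], rb[1:2]), "fewer than 3")
})

test_that("coupled simulation yields positive cross-assay correlation; null does not", {
  sim_skews <- function(kappa, seed) {
    set.seed(seed)
    n <- 200; d <- 100
    a1 <- runif(n); a2 <- runif(n)
    atac1 <- rpois(n, d * a1); atac2 <- rpois(n, d * a2)
    r1 <- rpois(n, 10 + kappa * a1); r2 <- rpois(n, 10 + kappa * a2)
    list(a = data.table::data.table(variant_id = sprintf("v%d", 1:n),
                                    s = atac1 / pmax(atac1 + atac2, 1)),
         b = data.table::data.table(variant_id = sprintf("v%d", 1:n),
                                    s = r1 / pmax(r1 + r2, 1)))
  }
  # kappa > 0: CI excludes zero
  sk <- sim_skews(50, 1)
  cc <- cross_assay_skew_correlation(sk$a, sk$b, n_boot = 500, seed = 2)
  expect_gt(cc$ci[1], 0)
  # kappa = 0: the 95% CI covers zero in >= 90% of replicate worlds
  cover <- 0; n_rep <- 30
  for (i in 1:n_rep) {
    sk0 <- sim_skews(0, 100 + i)
    cc0 <- cross_assay_skew_correlation(sk0$a, sk0$b, n_boot = 200,
                                        seed = 200 + i)
    if (cc0$ci[1] <= 0 && cc0$ci[2] >= 0) cover <- cover + 1
  }
  expect_gte(cover / n_rep, 0.9)
})
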
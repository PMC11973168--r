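#' Haplotype-resolved read counting at phased heterozygous variants
#'
#' Tallies, for every phased heterozygous variant inside a peak, the reads
#' assigned to each haplotype (pileup-style overlap of the variant position).
#' Variants outside all peaks are kept with `in_peak = FALSE` and excluded
#' from testing downstream; homozygous or unphased variants yield no record.
#'
#' Placements must be split by alignment target: counting uses the `hap1` and
#' `hap2` tables, whose coordinates are assumed comparable at SNV sites
#' (length-preserving variants; for indel-carrying haplotypes map positions
#' first with [map_position()]).
#'
#' @param placements named list of placement tables for alignment targets
#'   `hap1` and `hap2` (a `reference` table, when present, is only used by
#'   [zero_bias_sites()] depth bookkeeping).
#' @param variants phased variant table (see [read_phased_vcf()]).
#' @param peaks peak interval table (chrom, start, end).
#' @param assay assay label stamped on the output.
#' @param donor donor label stamped on the output.
#' @return data.table of haplotype counts: `variant_id`, `assay`, `donor`,
#'   `count_hap1`, `count_hap2`, `zeroed`, `in_peak`.
#' @export
count_haplotype_reads <- function(placements, variants, peaks,
                                  assay = "ATAC", donor = "donor1") {
  stopifnot(is.list(placements), all(c("hap1", "hap2") %in% names(placements)))
  vars <- data.table::as.data.table(variants)
  unphased <- vars$het & !vars$phased
  if (any(unphased)) {
    warning("skipping ", sum(unphased), " unphased heterozygous variant(s)")
  }
  vars <- vars[vars$het & vars$phased]
  if (!nrow(vars))
    return(data.table::data.table(variant_id = character(), assay = character(),
                                  donor = character(), count_hap1 = integer(),
                                  count_hap2 = integer(), zeroed = logical(),
                                  in_peak = logical()))
  pk <- as_interval_table(peaks)
  in_peak <- vapply(seq_len(nrow(vars)), function(i) {
    any(pk$chrom == vars$chrom[i] & pk$start <= vars$pos[i] &
          vars$pos[i] < pk$end)
  }, logical(1))
  count_at <- function(tbl, chr, p) {
    dt <- data.table::as.data.table(tbl)
    sum(dt$chrom == chr & dt$start <= p & p < dt$end)
  }
  c1 <- vapply(seq_len(nrow(vars)), function(i)
    count_at(placements$hap1, vars$chrom[i], vars$pos[i]), numeric(1))
  c2 <- vapply(seq_len(nrow(vars)), function(i)
    count_at(placements$hap2, vars$chrom[i], vars$pos[i]), numeric(1))
  data.table::data.table(variant_id = vars$id, assay = assay, donor = donor,
                         count_hap1 = as.integer(c1), count_hap2 = as.integer(c2),
                         zeroed = FALSE, in_peak = in_peak)
}

#' Zero out variant sites with alignment-bias discrepancies
#'
#' A site is zeroed (both allele counts set to 0, `zeroed = TRUE`) when the
#' total pileup depth at the site differs between the two personalized-genome
#' alignments by more than a fraction `tau` of their mean, or when the
#' reference alignment sees no reads while a personalized alignment does.
#' All-zero sites are zeroed trivially.
#'
#' @param counts haplotype-count table (from [count_haplotype_reads()]).
#' @param depths data.frame with `variant_id`, `depth_ref`, `depth_hap1`,
#'   `depth_hap2` — total site depth under each alignment target.
#' @param tau tolerance fraction in `(0, 1]` (default 0.2).
#' @return the count table with `zeroed` flags applied and zeroed counts set
#'   to 0.
#' @export
zero_bias_sites <- function(counts, depths, tau = 0.2) {
  if (tau <= 0 || tau > 1) stop("tau must lie in (0, 1]")
  cnt <- data.table::as.data.table(counts)
  dep <- data.table::as.data.table(depths)
  req <- c("variant_id", "depth_ref", "depth_hap1", "depth_hap2")
  stopifnot(all(req %in% names(dep)))
  m <- merge(cnt, dep, by = "variant_id", all.x = TRUE, sort = FALSE)
  d1 <- m$depth_hap1; d2 <- m$depth_hap2; dr <- m$depth_ref
  mid <- (d1 + d2) / 2
  discordant <- ifelse(mid > 0, abs(d1 - d2) > tau * mid, FALSE)
  ref_dropout <- dr == 0 & (d1 > 0 | d2 > 0)
  all_zero <- d1 == 0 & d2 == 0
  zero <- discordant | ref_dropout | all_zero
  zero[is.na(zero)] <- FALSE
  cnt$zeroed <- cnt$zeroed | zero
  cnt$count_hap1[cnt$zeroed] <- 0L
  cnt$count_hap2[cnt$zeroed] <- 0L
  cnt
}

# exact two-sided p under the <=-probability summation convention
.twosided_discrete_p <- function(k, n, pmf) {
  probs <- pmf(0:n, n)
  sum(probs[probs <= probs[k + 1L] * (1 + 1e-7)])
}

.binom_pmf <- function(x, n) stats::dbinom(x, n, 0.5)

.betabinom_pmf <- function(rho) {
  a <- (1 / rho - 1) / 2  # symmetric Beta(a, a) mixing, mean 0.5
  function(x, n) exp(lchoose(n, x) + lbeta(x + a, n - x + a) - lbeta(a, a))
}

#' Exact allelic skew test
#'
#' Tests, per site, the null of no allelic skew: `count_hap1 ~
#' Binomial(n_total, 0.5)`. The two-sided p-value sums the probabilities of
#' all outcomes no more likely than the observed one (ties included), so the
#' discrete test is conservative. The beta-binomial variant inflates the
#' variance with overdispersion `rho` (symmetric Beta mixing), for
#' assay/sample combinations with extra-binomial noise.
#'
#' Sign convention: the skew fraction `s = count_hap1 / n_total`, with hap1
#' carrying the reference allele after phasing normalization; direction
#' `"up"` means reference-haplotype excess.
#'
#' @param counts haplotype-count table; zeroed rows and `n_total = 0` rows
#'   get an undefined result (`p = NA`, direction `"none"`).
#' @param method `"binomial"` (default) or `"betabinomial"`.
#' @param rho beta-binomial overdispersion in `(0, 1)`.
#' @param alpha significance level used to call the `direction` field.
#' @return data.table of skew results: input ids, `n_total`, `s`, `p_value`,
#'   `direction` in `{"up", "down", "none"}`.
#' @export
skew_test <- function(counts, method = c("binomial", "betabinomial"),
                      rho = 0.1, alpha = 0.05) {
  method <- match.arg(method)
  if (method == "betabinomial" && (rho <= 0 || rho >= 1))
    stop("rho must lie strictly between 0 and 1")
  cnt <- data.table::as.data.table(counts)
  pmf <- if (method == "binomial") .binom_pmf else .betabinom_pmf(rho)
  n <- cnt$count_hap1 + cnt$count_hap2
  s <- ifelse(n > 0, cnt$count_hap1 / n, NA_real_)
  usable <- n > 0 & !cnt$zeroed
  p <- rep(NA_real_, nrow(cnt))
  if (any(usable)) {
    p[usable] <- vapply(which(usable), function(i)
      .twosided_discrete_p(cnt$count_hap1[i], n[i], pmf), numeric(1))
    p[usable] <- pmin(p[usable], 1)
  }
  direction <- rep("none", nrow(cnt))
  sig <- usable & !is.na(p) & p < alpha
  direction[sig & s > 0.5] <- "up"
  direction[sig & s < 0.5] <- "down"
  out <- data.table::copy(cnt)
  out$n_total <- as.integer(n)
  out$s <- s
  out$p_value <- p
  out$direction <- direction
  out
}

#' Variants with consistent skew direction across donors/phase blocks
#'
#' Keeps variants whose significant skew direction agrees across every donor
#' and phase block where it was observed; variants with mixed significant
#' directions, or significant nowhere, are dropped.
#'
#' @param results skew-result table (from [skew_test()]), possibly spanning
#'   several donors.
#' @param alpha significance level defining "observed skew".
#' @return data.table with `variant_id`, consistent `direction` and the
#'   number of supporting observations.
#' @export
consistent_skew_variants <- function(results, alpha = 0.05) {
  res <- data.table::as.data.table(results)
  sig <- res[!is.na(res$p_value) & res$p_value < alpha &
               res$direction %in% c("up", "down")]
  if (!nrow(sig))
    return(data.table::data.table(variant_id = character(),
                                  direction = character(), n_support = integer()))
  agg <- sig[, list(n_dir = length(unique(direction)),
                    direction = direction[1], n_support = .N),
             by = "variant_id"]
  agg[agg$n_dir == 1L, c("variant_id", "direction", "n_support"), with = FALSE]
}

#' Select extreme-skew regions across a genotype-stratified cohort
#'
#' Implements the stringent screen behind the meta-analysis: a candidate
#' region (peak with a causal variant) is selected when its ATAC skew is
#' significant at `p < p_threshold` in every heterozygous donor (at least
#' one required) and the donors span at least two distinct genotype classes.
#'
#' @param skew_results skew-result table with `variant_id`, `donor`,
#'   `p_value`.
#' @param genotypes data.frame with `variant_id`, `donor`, `genotype` in
#'   `{"hom_ref", "het", "hom_alt"}`.
#' @param p_threshold significance threshold (default 1e-4, the stringent
#'   screen value).
#' @return data.table of selected variants: `variant_id`, `n_het`,
#'   `n_classes`, `max_het_p`.
#' @export
select_extreme_regions <- function(skew_results, genotypes,
                                   p_threshold = 1e-4) {
  res <- data.table::as.data.table(skew_results)
  gt <- data.table::as.data.table(genotypes)
  stopifnot(all(c("variant_id", "donor", "genotype") %in% names(gt)))
  if (length(unique(gt$donor)) < 2) stop("need at least 2 donors")
  m <- merge(gt, res[, c("variant_id", "donor", "p_value"), with = FALSE],
             by = c("variant_id", "donor"), all.x = TRUE)
  sel <- m[, {
    het_p <- p_value[genotype == "het"]
    n_het <- sum(genotype == "het")
    list(n_het = n_het,
         n_classes = length(unique(genotype)),
         max_het_p = if (n_het) suppressWarnings(max(het_p)) else NA_real_,
         pass = n_het >= 1L && length(unique(genotype)) >= 2L &&
           all(!is.na(het_p)) && all(het_p < p_threshold))
  }, by = "variant_id"]
  sel[sel$pass == TRUE, c("variant_id", "n_het", "n_classes", "max_het_p"),
      with = FALSE]
}

#' Genotype-group meta-analysis with paired t-tests
#'
#' Normalizes each region's coverage to RPKM and further divides by region
#' length in kb, averages donors within each genotype class per region, then
#' compares genotype classes pairwise with a paired t-test over regions
#' (`t = mean(d) / (sd(d) / sqrt(n))`, df `n - 1`, two-sided p). Regions
#' missing one class of a pair are dropped pairwise.
#'
#' @param coverage long data.frame with columns `region`, `donor`,
#'   `genotype`, `raw_count`, `total_mapped`, `region_length` (as emitted by
#'   [simulate_skew_cohort()], or built from `region_coverage()` output).
#' @return list with `region_values` (normalized per-region per-class
#'   values), `group_means` (per-class mean and n) and `tests` (pairwise
#'   paired t-tests: `class_a`, `class_b`, `n_pairs`, `t`, `df`, `p_value`,
#'   `note`). A zero-variance nonzero difference reports
#'   `p = .Machine$double.xmin` with note `"zero-variance"`; fewer than 2
#'   pairs reports `NA` with note `"undefined"`.
#' @export
genotype_group_meta <- function(coverage) {
  cov <- data.table::as.data.table(coverage)
  req <- c("region", "donor", "genotype", "raw_count", "total_mapped",
           "region_length")
  stopifnot(all(req %in% names(cov)))
  rpkm <- cov$raw_count * 1e9 / (cov$region_length * cov$total_mapped)
  cov$value <- rpkm / (cov$region_length / 1000)
  rv <- cov[, list(value = mean(value)), by = c("region", "genotype")]
  gm <- rv[, list(mean_value = mean(value), n_regions = .N), by = "genotype"]
  classes <- sort(unique(rv$genotype))
  tests <- list()
  if (length(classes) >= 2) {
    for (i in seq_len(length(classes) - 1L)) for (j in seq(i + 1L, length(classes))) {
      a <- classes[i]; b <- classes[j]
      wide <- merge(rv[genotype == a, c("region", "value"), with = FALSE],
                    rv[genotype == b, c("region", "value"), with = FALSE],
                    by = "region", suffixes = c("_a", "_b"))
      d <- wide$value_a - wide$value_b
      n <- length(d)
      if (n < 2) {
        tests[[length(tests) + 1L]] <- data.table::data.table(
          class_a = a, class_b = b, n_pairs = n, t = NA_real_, df = NA_real_,
          p_value = NA_real_, note = "undefined")
        next
      }
      sdd <- stats::sd(d)
      if (sdd == 0) {
        tests[[length(tests) + 1L]] <- data.table::data.table(
          class_a = a, class_b = b, n_pairs = n, t = if (mean(d) == 0) 0 else Inf,
          df = n - 1,
          p_value = if (mean(d) == 0) 1 else .Machine$double.xmin,
          note = if (mean(d) == 0) "" else "zero-variance")
        next
      }
      tstat <- mean(d) / (sdd / sqrt(n))
      tests[[length(tests) + 1L]] <- data.table::data.table(
        class_a = a, class_b = b, n_pairs = n, t = tstat, df = n - 1,
        p_value = 2 * stats::pt(-abs(tstat), df = n - 1), note = "")
    }
  }
  list(region_values = rv, group_means = gm,
       tests = data.table::rbindlist(tests))
}

#' Cross-assay rank correlation of allelic skew
#'
#' Spearman correlation of the signed skew `s - 0.5` between two assays over
#' variants matched by id (and donor when present), with a seeded case
#' bootstrap for the 95% confidence interval.
#'
#' @param results_a,results_b skew-result tables for the two assays.
#' @param element_class optional per-variant class filter: data.frame with
#'   `variant_id`, `class`, plus the `classes` to keep.
#' @param classes classes retained when `element_class` is supplied.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed bootstrap seed.
#' @return list with `rho`, `ci` (2.5/97.5 percentiles), `n` matched
#'   variants; fewer than 3 matches gives an error.
#' @export
cross_assay_skew_correlation <- function(results_a, results_b,
                                         element_class = NULL, classes = NULL,
                                         n_boot = 1000, seed = 1L) {
  a <- data.table::as.data.table(results_a)
  b <- data.table::as.data.table(results_b)
  keycols <- intersect(c("variant_id", "donor"), intersect(names(a), names(b)))
  a <- a[!is.na(a$s)]; b <- b[!is.na(b$s)]
  m <- merge(a[, c(keycols, "s"), with = FALSE],
             b[, c(keycols, "s"), with = FALSE],
             by = keycols, suffixes = c("_a", "_b"))
  if (!is.null(element_class)) {
    ec <- data.table::as.data.table(element_class)
    keep_ids <- ec$variant_id[ec$class %in% classes]
    m <- m[m$variant_id %in% keep_ids]
  }
  if (nrow(m) < 3) stop("fewer than 3 matched variants: correlation undefined")
  x <- m$s_a - 0.5; y <- m$s_b - 0.5
  rho <- stats::cor(x, y, method = "spearman")
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(length(x), replace = TRUE)
    suppressWarnings(stats::cor(x[idx], y[idx], method = "spearman"))
  }, numeric(1))
  ci <- stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(rho = rho, ci = ci, n = nrow(m))
}
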
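#' Configuration of the synthetic diploid world
#'
#' Collects every knob of the generator: genome geometry, donor count, variant
#' density, regulatory-element layout, per-haplotype activity, the
#' cohesin-activity coupling (expected cohesin count = `baseline + kappa * a`),
#' sequencing depth, spike-in fraction and the count-noise model. A fixed
#' `seed` makes every simulated output byte-identical.
#'
#' @param genome_length named vector of chromosome lengths in bp.
#' @param n_donors number of diploid donors (default 3, mirroring a
#'   three-donor biobank cohort).
#' @param snv_density background heterozygous-SNV rate per bp.
#' @param n_elements,element_width,element_spacing regulatory-element layout;
#'   elements are placed on the first chromosome every `element_spacing` bp.
#' @param activity baseline per-haplotype element activity in `[0, 1]`.
#' @param kappa cohesin coupling constant (>= 0).
#' @param baseline cohesin baseline count per haplotype.
#' @param depth expected reads per fully active element haplotype.
#' @param spikein_fraction spike-in cell fraction in `(0, 1)`; 0.01 and 0.04
#'   are the experimentally used mixes.
#' @param background_rate background read rate per bp for coverage tracks.
#' @param noise `"poisson"` (default) or `"negbinom"`.
#' @param dispersion negative-binomial dispersion (used when
#'   `noise = "negbinom"`).
#' @param damage_factor multiplier applied to the activity of a haplotype
#'   carrying the damaging (alt) allele of an element's causal variant;
#'   default 0 = complete loss.
#' @param seed integer random seed.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(genome_length = c(chr1 = 1e6),
                             n_donors = 3,
                             snv_density = 5e-5,
                             n_elements = 20,
                             element_width = 400,
                             element_spacing = 4000,
                             activity = 1,
                             kappa = 50,
                             baseline = 10,
                             depth = 100,
                             spikein_fraction = 0.04,
                             background_rate = 0.01,
                             noise = c("poisson", "negbinom"),
                             dispersion = 0.1,
                             damage_factor = 0,
                             seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(all(genome_length > 0), n_donors >= 1, snv_density >= 0,
            n_elements >= 1, element_width >= 1,
            activity >= 0, activity <= 1, kappa >= 0, baseline >= 0,
            depth >= 0, background_rate >= 0, dispersion > 0,
            damage_factor >= 0, damage_factor <= 1)
  if (spikein_fraction <= 0 || spikein_fraction >= 1)
    stop("spikein_fraction must lie strictly between 0 and 1")
  if (element_width > element_spacing)
    stop("element_width exceeds element_spacing: elements would overlap")
  if (is.null(names(genome_length))) stop("genome_length must be named")
  structure(list(genome_length = genome_length, n_donors = n_donors,
                 snv_density = snv_density, n_elements = n_elements,
                 element_width = element_width,
                 element_spacing = element_spacing, activity = activity,
                 kappa = kappa, baseline = baseline, depth = depth,
                 spikein_fraction = spikein_fraction,
                 background_rate = background_rate, noise = noise,
                 dispersion = dispersion, damage_factor = damage_factor,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

.rcount <- function(n, mu, config) {
  if (config$noise == "poisson") stats::rpois(n, mu)
  else stats::rnbinom(n, size = 1 / config$dispersion, mu = mu)
}

.rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

.other_base <- function(base) {
  vapply(base, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
         character(1))
}

#' Simulate a cohort of diploid donors with polymorphic regulatory elements
#'
#' Builds a random reference genome, places regulatory elements at regular
#' spacing on the first chromosome (each with one causal SNV at its centre
#' plus background SNVs at `snv_density`), and draws per-donor phased
#' genotypes. A haplotype carrying the damaging (alt) allele of an element's
#' causal variant has its activity multiplied by `damage_factor` (default 0:
#' complete loss, the extreme-skew regime).
#'
#' @param config a [synthetic_config()].
#' @param force_genotypes optional character matrix (`n_donors` x
#'   `n_elements`) with entries `"hom_ref"`, `"het"`, `"hom_alt"` forcing the
#'   causal-variant genotype of each donor at each element; `NULL` draws them
#'   at allele frequency 0.5.
#' @return list with `reference` (a `genome_sequence`), `elements`
#'   (interval table with `name`, `class`, `activity`, `causal_pos`,
#'   `causal_id`), `donors` (per-donor list of `variants` table and
#'   `activities` table with per-haplotype activities and genotype class)
#'   and the `config`.
#' @export
simulate_diploid_donors <- function(config, force_genotypes = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  seqs <- vapply(config$genome_length, .rand_seq, character(1))
  reference <- genome_sequence(seqs, label = "reference")

  chr <- names(config$genome_length)[1]
  L1 <- config$genome_length[[1]]
  need <- config$n_elements * config$element_spacing
  if (need > L1)
    stop("first chromosome too short for ", config$n_elements,
         " elements spaced ", config$element_spacing, " bp")
  offset <- floor((L1 - need) / 2)
  starts <- offset + (seq_len(config$n_elements) - 1L) * config$element_spacing
  classes <- rep(c("enhancer", "promoter", "CTCF", "enhancer+CTCF",
                   "promoter+CTCF"), length.out = config$n_elements)
  causal_pos <- starts + floor(config$element_width / 2)
  elements <- data.table::data.table(
    chrom = chr, start = starts, end = starts + config$element_width,
    name = sprintf("elem%03d", seq_len(config$n_elements)),
    class = classes, activity = config$activity,
    causal_pos = causal_pos,
    causal_id = sprintf("causal%03d", seq_len(config$n_elements)))

  # background SNV candidate positions, genome-wide, shared across donors
  bg <- data.table::rbindlist(lapply(names(config$genome_length), function(ch) {
    Lc <- config$genome_length[[ch]]
    n_bg <- stats::rpois(1, config$snv_density * Lc)
    if (n_bg == 0) return(NULL)
    pos <- sort(sample.int(Lc, min(n_bg, Lc)) - 1L)
    data.table::data.table(chrom = ch, pos = pos)
  }))
  # drop background SNVs colliding with causal positions
  if (nrow(bg))
    bg <- bg[!(bg$chrom == chr & bg$pos %in% causal_pos)]
  # with zero SNV density and no forced genotypes the world carries no
  # variation at all: donors are identical and elements have no causal SNV
  include_causal <- config$snv_density > 0 || !is.null(force_genotypes)
  all_pos <- data.table::rbindlist(list(
    if (include_causal)
      data.table::data.table(chrom = chr, pos = causal_pos,
                             id = elements$causal_id),
    if (nrow(bg)) data.table::data.table(chrom = bg$chrom, pos = bg$pos,
                                         id = sprintf("snv%05d", seq_len(nrow(bg))))
  ))
  if (!nrow(all_pos)) {
    donors <- lapply(seq_len(config$n_donors), function(d) {
      list(variants = data.table::data.table(
             chrom = character(), pos = integer(), id = character(),
             ref = character(), alt = character(), gt1 = integer(),
             gt2 = integer(), phased = logical(), het = logical()),
           activities = data.table::data.table(
             element_id = elements$name, genotype = "hom_ref",
             a1 = elements$activity, a2 = elements$activity))
    })
    names(donors) <- sprintf("donor%d", seq_len(config$n_donors))
    return(list(reference = reference, elements = elements, donors = donors,
                config = config))
  }
  data.table::setorder(all_pos, chrom, pos)
  refb <- substring(reference$seqs[all_pos$chrom], all_pos$pos + 1,
                    all_pos$pos + 1)
  all_pos$ref <- refb
  all_pos$alt <- .other_base(refb)

  draw_gt <- function(n) sample(c("hom_ref", "het", "hom_alt"), n,
                                replace = TRUE, prob = c(0.25, 0.5, 0.25))
  donors <- lapply(seq_len(config$n_donors), function(d) {
    gt_class <- draw_gt(nrow(all_pos))
    if (!is.null(force_genotypes)) {
      idx <- match(elements$causal_id, all_pos$id)
      gt_class[idx] <- force_genotypes[d, ]
    }
    # phased orientation of hets: alt on hap1 or hap2 with equal probability
    alt_on_hap1 <- sample(c(TRUE, FALSE), nrow(all_pos), replace = TRUE)
    gt1 <- ifelse(gt_class == "hom_alt", 1L,
                  ifelse(gt_class == "het" & alt_on_hap1, 1L, 0L))
    gt2 <- ifelse(gt_class == "hom_alt", 1L,
                  ifelse(gt_class == "het" & !alt_on_hap1, 1L, 0L))
    variants <- data.table::data.table(
      chrom = all_pos$chrom, pos = all_pos$pos, id = all_pos$id,
      ref = all_pos$ref, alt = all_pos$alt, gt1 = gt1, gt2 = gt2,
      phased = TRUE, het = gt1 != gt2)
    ci <- match(elements$causal_id, all_pos$id)
    dmg <- function(carries_alt)
      ifelse(carries_alt, config$damage_factor, 1) * elements$activity
    activities <- data.table::data.table(
      element_id = elements$name,
      genotype = gt_class[ci],
      a1 = dmg(gt1[ci] == 1L),
      a2 = dmg(gt2[ci] == 1L))
    list(variants = variants[gt1 + gt2 > 0 | het], activities = activities)
  })
  names(donors) <- sprintf("donor%d", seq_len(config$n_donors))
  list(reference = reference, elements = elements, donors = donors,
       config = config)
}

#' Simulate per-haplotype counts and a coverage track for one assay
#'
#' Per-haplotype element counts follow the configured noise model with mean
#' `depth * a_h` for activity assays (ATAC and histone marks / CTCF) or
#' `baseline + kappa * a_h` for RAD21, encoding the assumption that cohesin
#' occupancy is a baseline plus an activity-coupled component. The coverage
#' track bins simulated read positions (elements plus uniform background), so
#' at `bin_size = 1` the bin sum equals the number of simulated reads.
#'
#' @param elements element interval table (from [simulate_diploid_donors()]).
#' @param activities per-element activity table with columns `element_id`,
#'   `a1`, `a2`.
#' @param assay one of `"ATAC"`, `"RAD21"`, `"H3K4me1"`, `"H3K4me3"`,
#'   `"H3K27ac"`, `"CTCF"`.
#' @param config a [synthetic_config()].
#' @param bin_size coverage track bin size (default 1).
#' @param seed optional seed overriding `config$seed` (so several assays of
#'   one cohort get independent noise).
#' @return list with `counts` (per-element `count_hap1`/`count_hap2`),
#'   `track` (raw `coverage_track`) and `n_reads`.
#' @export
simulate_counts <- function(elements, activities, assay, config,
                            bin_size = 1L, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  assays <- c("ATAC", "RAD21", "H3K4me1", "H3K4me3", "H3K27ac", "CTCF")
  if (!assay %in% assays)
    stop("unknown assay '", assay, "'; expected one of ",
         paste(assays, collapse = ", "))
  el <- data.table::as.data.table(elements)
  act <- data.table::as.data.table(activities)
  dt <- merge(el, act, by.x = "name", by.y = "element_id", sort = FALSE)
  if (any(dt$end > config$genome_length[dt$chrom]))
    stop("element outside genome bounds")
  set.seed(seed)
  mu <- function(a) if (assay == "RAD21") config$baseline + config$kappa * a
                    else config$depth * a
  c1 <- .rcount(nrow(dt), mu(dt$a1), config)
  c2 <- .rcount(nrow(dt), mu(dt$a2), config)
  counts <- data.table::data.table(element_id = dt$name, assay = assay,
                                   count_hap1 = c1, count_hap2 = c2)
  # read positions: element reads uniform within the element, background
  # reads uniform along each chromosome
  pos_list <- list()
  for (i in seq_len(nrow(dt))) {
    n <- c1[i] + c2[i]
    if (n > 0)
      pos_list[[length(pos_list) + 1L]] <- data.table::data.table(
        chrom = dt$chrom[i],
        start = dt$start[i] + sample.int(dt$end[i] - dt$start[i], n,
                                         replace = TRUE) - 1L)
  }
  for (ch in names(config$genome_length)) {
    Lc <- config$genome_length[[ch]]
    nb <- stats::rpois(1, config$background_rate * Lc)
    if (nb > 0)
      pos_list[[length(pos_list) + 1L]] <- data.table::data.table(
        chrom = ch, start = sample.int(Lc, nb, replace = TRUE) - 1L)
  }
  pos <- data.table::rbindlist(pos_list)
  track <- track_from_placements(pos, config$genome_length, bin_size = bin_size)
  list(counts = counts, track = track, n_reads = nrow(pos))
}

#' Simulate spike-in calibrated ChIP mixtures
#'
#' Emits, per sample, a ChIP read-placement table mixing target-genome and
#' spike-in-genome reads plus input library totals. Spike-in ChIP totals
#' scale with the per-sample IP efficiency `e_s` (the technical variation the
#' calibration must remove); input totals reflect only the library size and
#' the mixing fraction `f`, drawn as a seeded binomial.
#'
#' @param target_depth input-library size per sample (reads).
#' @param spikein_fraction spike-in fraction `f` in `(0, 1)`.
#' @param n_samples number of samples.
#' @param ip_efficiency per-sample IP efficiency vector `e_s > 0`.
#' @param chip_depth expected target-genome ChIP reads per sample (default
#'   `target_depth / 3`); constant across samples — target-ChIP depth does
#'   not enter the down-sampling factor.
#' @param read_length read length in bp.
#' @param seed random seed.
#' @param materialize_inputs also materialize input placements (`TRUE`) or
#'   return input totals only (default; totals carry the same sampling noise
#'   either way).
#' @param stochastic draw totals from the binomial/Poisson noise model
#'   (default); `FALSE` uses rounded expected totals (the symmetric
#'   noise-free world).
#' @return list with `samples` (per-sample list: `sample_id`, `chip`
#'   placement table, optional `input` placement table) and `totals`
#'   (data.table with per-sample target/spike-in ChIP and Input totals, the
#'   4-column interchange [compute_downsampling_factors()] consumes).
#' @export
simulate_spikein_mixture <- function(target_depth = 1e6,
                                     spikein_fraction = 0.04,
                                     n_samples = 3,
                                     ip_efficiency = rep(1, n_samples),
                                     chip_depth = round(target_depth / 3),
                                     read_length = 75,
                                     seed = 1L,
                                     materialize_inputs = FALSE,
                                     stochastic = TRUE) {
  if (spikein_fraction <= 0 || spikein_fraction >= 1)
    stop("spikein_fraction must lie strictly between 0 and 1")
  stopifnot(length(ip_efficiency) == n_samples, all(ip_efficiency > 0),
            target_depth >= 1, chip_depth >= 1)
  set.seed(seed)
  f <- spikein_fraction
  target_len <- 1e6; spike_len <- 1e6   # placement coordinate space
  mk_places <- function(n_target, n_spike, prefix) {
    n <- n_target + n_spike
    st <- sample.int(target_len - read_length, n, replace = TRUE) - 1L
    data.table::data.table(
      read_id = paste0(prefix, seq_len(n)),
      genome = rep(c("target", "spikein"), c(n_target, n_spike)),
      chrom = rep(c("chrT1", "chrS1"), c(n_target, n_spike)),
      start = st, end = st + as.integer(read_length),
      mate_start = NA_integer_, mate_end = NA_integer_,
      source = rep(c("target", "spikein"), c(n_target, n_spike)))
  }
  samples <- vector("list", n_samples)
  totals <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    e <- ip_efficiency[s]
    if (stochastic) {
      spike_in_input <- stats::rbinom(1, target_depth, f)
      target_chip <- stats::rpois(1, chip_depth)
      spike_chip <- stats::rpois(1, chip_depth * e * f / (1 - f))
    } else {
      spike_in_input <- round(target_depth * f)
      target_chip <- round(chip_depth)
      spike_chip <- round(chip_depth * e * f / (1 - f))
    }
    target_input <- target_depth - spike_in_input
    sid <- sprintf("sample%d", s)
    samp <- list(sample_id = sid,
                 chip = mk_places(target_chip, spike_chip, paste0(sid, "_c")))
    if (materialize_inputs)
      samp$input <- mk_places(target_input, spike_in_input, paste0(sid, "_i"))
    samples[[s]] <- samp
    totals[[s]] <- data.table::data.table(
      sample_id = sid,
      total_reads_target_chip = target_chip,
      total_reads_spikein_chip = spike_chip,
      total_reads_target_input = target_input,
      total_reads_spikein_input = spike_in_input)
  }
  list(samples = samples, totals = data.table::rbindlist(totals))
}

#' Simulate reads from an insertion-edited locus
#'
#' Places `depth` single-end reads uniformly over the edited chromosome and
#' tags, at generation time, whether each read overlaps the left or right
#' insertion junction (truth labels for evaluating the junction classifier —
#' the classifier itself never reads them).
#'
#' @param edited result of [build_edited_genome()].
#' @param depth number of reads (0 gives an empty table).
#' @param read_length read length in bp; must be shorter than the insert for
#'   junction reads to be distinguishable from insert-internal reads.
#' @param seed random seed.
#' @return placement `data.table` with an extra `truth_junction` column in
#'   `{"left", "right", "both", "none"}`.
#' @export
simulate_edited_reads <- function(edited, depth, read_length = 75, seed = 1L) {
  stopifnot(is.list(edited), !is.null(edited$junctions),
            inherits(edited$genome, "genome_sequence"))
  ins_len <- edited$insert_interval$end - edited$insert_interval$start
  if (read_length >= ins_len + 2)
    warning("read_length >= insert length: every insert read spans a junction")
  chr <- edited$insert_interval$chrom
  L <- nchar(edited$genome$seqs[[chr]])
  if (depth == 0)
    return(data.table::data.table(read_id = character(), genome = character(),
                                  chrom = character(), start = integer(),
                                  end = integer(), mate_start = integer(),
                                  mate_end = integer(), source = character(),
                                  truth_junction = character()))
  set.seed(seed)
  st <- sample.int(L - read_length + 1L, depth, replace = TRUE) - 1L
  en <- st + as.integer(read_length)
  jl <- edited$junctions[["left"]]; jr <- edited$junctions[["right"]]
  covl <- st < jl & en > jl
  covr <- st < jr & en > jr
  truth <- ifelse(covl & covr, "both",
                  ifelse(covl, "left", ifelse(covr, "right", "none")))
  data.table::data.table(
    read_id = sprintf("er%06d", seq_len(depth)), genome = "edited",
    chrom = chr, start = st, end = en,
    mate_start = NA_integer_, mate_end = NA_integer_,
    source = "target", truth_junction = truth)
}

#' Simulate the extreme-skew region cohort (meta-analysis fixture)
#'
#' Builds `n_regions` polymorphic elements whose causal-variant genotypes are
#' forced to a per-region permutation of (hom-ref, het, hom-alt) across the
#' donors — the "mix of genotype classes" design — then simulates per-donor
#' RAD21 (or other assay) counts over each region under the activity-coupled
#' model.
#'
#' @param n_regions number of regions (default 51).
#' @param assay assay to simulate (default `"RAD21"`).
#' @param config a [synthetic_config()]; `n_elements` is overridden by
#'   `n_regions`.
#' @return list with `regions` (interval table), `coverage` (long table:
#'   `region`, `donor`, `genotype`, `raw_count`, `total_mapped`,
#'   `region_length`) and the cohort object.
#' @export
simulate_skew_cohort <- function(n_regions = 51, assay = "RAD21", config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  cfg$n_elements <- n_regions
  need <- n_regions * cfg$element_spacing
  if (need > cfg$genome_length[[1]])
    cfg$genome_length[1] <- need + 2 * cfg$element_spacing
  set.seed(cfg$seed)
  perms <- t(replicate(n_regions, sample(c("hom_ref", "het", "hom_alt"))))
  force <- matrix(NA_character_, nrow = cfg$n_donors, ncol = n_regions)
  for (d in seq_len(min(3, cfg$n_donors))) force[d, ] <- perms[, d]
  if (cfg$n_donors > 3)
    for (d in 4:cfg$n_donors) force[d, ] <- sample(c("hom_ref", "het", "hom_alt"),
                                                   n_regions, replace = TRUE)
  cohort <- simulate_diploid_donors(cfg, force_genotypes = force)
  cov <- data.table::rbindlist(lapply(seq_along(cohort$donors), function(d) {
    don <- cohort$donors[[d]]
    sim <- simulate_counts(cohort$elements, don$activities, assay, cfg,
                           bin_size = 100L, seed = cfg$seed + 1000L * d)
    data.table::data.table(
      region = cohort$elements$name,
      donor = names(cohort$donors)[d],
      genotype = don$activities$genotype,
      raw_count = sim$counts$count_hap1 + sim$counts$count_hap2,
      total_mapped = sim$n_reads,
      region_length = cohort$elements$end - cohort$elements$start)
  }))
  list(regions = cohort$elements, coverage = cov, cohort = cohort)
}
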
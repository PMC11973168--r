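---
title: "Models and methods behind skewdomain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind skewdomain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skewdomain)
```

# The scientific question

Cohesin, the ring-shaped complex that extrudes chromatin loops, accumulates
at active regulatory elements, and the degree of its recruitment appears to
track the degree of regulatory activity. skewdomain packages the
quantitative machinery needed to interrogate that relationship on diploid
genomes: allele-resolved skew testing at phased heterozygous variants,
spike-in calibrated ChIP-seq normalization, inside/outside-domain coverage
ratios, neutral-region discovery for enhancer-insertion experiments,
edited-genome bookkeeping with junction-read classification, and
allele-resolved motif enrichment. A synthetic diploid generator supplies
every input, so all claims the package makes are backed by tests that run
from scratch in seconds.

# Coordinate conventions

All internal coordinates are 0-based half-open. BED and bedGraph are native
in that convention; VCF positions and printed browser regions
(`"chrN:a-b"`) are 1-based inclusive and converted at the boundary as
`(a - 1, b)`, so a printed single-base region has length 1 and a printed
region's length is `b - a + 1`. A single internal convention prevents
off-by-one drift between modules; the conversion is confined to
`parse_interval()`/`format_interval()` and the VCF reader.

# The allelic skew model

At a phased heterozygous SNV with haplotype read counts $(c_1, c_2)$, the
null of no allelic skew is $c_1 \sim \mathrm{Binomial}(c_1 + c_2, 1/2)$.
`skew_test()` computes the exact two-sided p-value with the
$\le$-probability summation convention (the probabilities of all outcomes no
more likely than the observed one are summed, ties included). Because the
binomial is discrete this test is conservative: at $\alpha = 0.05$ and
realistic depths the empirical type-I error sits near 4%, and the test suite
asserts it never exceeds 5.5%. The widely used combined haplotype test of
allele-specific pipelines is deliberately *not* re-implemented; the exact
binomial is the transparent desk-scale equivalent whose calibration can be
verified against brute-force enumeration, which the tests do exactly for all
totals up to 30. A beta-binomial variant (symmetric
$\mathrm{Beta}(a, a)$ mixing with overdispersion
$\rho = 1/(2a + 1)$) is available for assays with extra-binomial noise.

Skew is summarized as $s = c_1/(c_1+c_2)$, with hap1 carrying the reference
allele after phasing normalization; direction "up" means reference-haplotype
excess.

Mapping-bias removal ("set both allele counts to zero when necessary") has
no published rule, so the package defines one deterministically
(`zero_bias_sites()`): a site is zeroed when the total depth under the two
personalized-genome alignments differs by more than a fraction
$\tau$ (default 0.2) of their mean, or when the reference alignment sees no
reads while a personalized alignment does. Every zeroed site keeps its flag,
so the decision is auditable.

## Extreme-skew regions and the meta-analysis

`select_extreme_regions()` applies the stringent screen: a region qualifies
when its causal variant shows ATAC skew at $p < 10^{-4}$ in **every**
heterozygous donor and the donors span at least two genotype classes. The
screen is ambiguous in its source description about whether only het donors
must pass; requiring every het donor is the stricter reading and is the
default. `genotype_group_meta()` then normalizes each region's coverage to
RPKM, divides again by region length in kb (the double length normalization
is the documented convention of the original analysis), averages donors
within genotype class per region, and compares classes with paired t-tests
over regions: $t = \bar d / (s_d / \sqrt n)$ with $n - 1$ degrees of
freedom. Zero-variance nonzero differences are reported at the machine
floor with a flag rather than silently as zero.

# Spike-in calibration

For sample $s$ the down-sampling factor is

$$ f_s = \alpha \cdot \frac{1}{\text{spike-in ChIP reads}_s} \cdot
   \frac{\text{spike-in Input reads}_s}{\text{target Input reads}_s}, $$

with $\alpha$ chosen so the largest factor is exactly 1. The Input ratio
term is itself the correction for small variations in spike-in mixing;
`input_correction()` additionally reports each sample's mixing ratio and
flags deviations beyond 50% of the cohort median. Target-ChIP depth does not
enter the formula, and deliberately does not enter the module either.
Subsampling is per-read Bernoulli under a fixed seed (streaming semantics,
matching "randomly subsampled"); an exact-count mode sits behind a flag.

# The synthetic world

The generator is a stated world, not a tuning dial. Defaults:

* **3 donors**, mirroring the three-donor cohort design; configurable.
* Elements carry one causal SNV; a haplotype with the damaging (alt) allele
  has its activity multiplied by the damage factor, **default 0** (complete
  loss — the extreme-skew regime in which an enhancer is fully active or
  fully dead). Intermediate values exercise graded skew.
* Counts are **Poisson** by default with mean $d \cdot a_h$ for activity
  assays (depth $d = 100$, the scale used throughout the worked examples)
  and $\beta + \kappa a_h$ for cohesin (baseline $\beta = 10$, coupling
  $\kappa = 50$). A negative-binomial option (dispersion 0.1) exposes
  overdispersion robustness. No count model is prescribed by the source
  analyses; Poisson is the minimal choice.
* Spike-in fraction defaults to 0.04 (the 4% mix; 1% is the other
  experimentally used value).
* The spike-in fixture for calibration acceptance uses an input library of
  $6 \times 10^6$ reads and a ChIP target component of $2 \times 10^6$:
  at a 4% mix this puts ~$8 \times 10^4$ spike-in ChIP reads per sample, the
  counting regime in which Eq.-1 factors are determined to about 1% —
  chosen a priori from the ±2% acceptance precision, not tuned afterwards.
* Haplotype of origin and junction overlap are tagged **at generation**;
  the analysis code never reads these tags — they exist only for truth-set
  evaluation.

What the generator does *not* emulate: mapping bias (unless injected via
depth tables), sequencing error, fragment-size distributions, GC bias, and
linkage between background SNVs. A green test therefore establishes the
correctness of counting, testing and normalization logic — not robustness
to alignment artefacts, which the real pipelines handle upstream.

# Domain quantification

`coverage_ratio()` computes the inside/outside enrichment as
length-normalized densities, $({\rm inside}/L_{\rm in}) / ({\rm
outside}/L_{\rm out})$. Length normalization is deliberate: the two printed
definitions of the control region disagree in extent, and a density ratio is
robust to that discrepancy. The statistic is invariant under global depth
rescaling and recovers a planted 6-fold enrichment within 10% at the stated
world's depth.

Peak calling is a deliberately simple threshold caller (`call_peaks()`):
bins above $m$× the genome-wide median (default $m = 5$) merged within
200 bp, dropping peaks narrower than 150 bp. It stands in for the ML caller
used upstream of the original analyses; it is deterministic, scale-free and
idempotent on its own output. Likewise `classify_cre()` is a transparent
rank-rule classifier (promoter / enhancer / CTCF, with `+CTCF` flavours)
standing in for the cited rule-based tool; the exact rule table is this
package's own and is documented in the function.

`scan_neutral_regions()` reproduces the neutral-region search: within
A-compartment intervals on a chosen chromosome, subtract every interval with
repressive marks, open chromatin, active marks (each track thresholded and
padded), and annotated genes; keep residual intervals at or above the
minimum length (default 100 kb). Per-track thresholds in the original search
are unstated, so they are explicit, configurable arguments here.

# Genome editing and junction evidence

`build_personalized_genomes()` applies phased alleles consensus-style and
returns exact coordinate maps (block pairs of equal length; indel interiors
are unmappable). `build_edited_genome()` cuts-and-pastes an insert (the
motivating case is a 325 bp enhancer cassette) and reports both junction
breakpoints. `dpnII_digest()` cuts at the *start* of each GATC occurrence —
a convention the source does not fix; the start-of-site rule matches common
3C digestion utilities and is documented so viewpoint coordinates are
reproducible. Viewpoint selection filters fragments to 1–3 kb (bounds
inclusive, reading "between 1 and 3 kb" inclusively) and picks `n`
fragments by an equal-window greedy rule — the even-spacing rule is this
package's own, since the source only asks for viewpoints "across the
locus".

Junction classification calls a read junction-spanning when it covers a
breakpoint with at least $k = 5$ bp on each side; "spanning" has no
published overhang, and 5 bp keeps power at 75 bp reads while excluding
1 bp touches. A pair supports a junction when either mate spans it
directly; insert-size-only evidence (mates straddling without covering) is
off by default. The geometric oracle — $R - 2k + 1$ qualifying start
positions out of $L - R + 1$ — gives the expected counts the tests check
against, and reads simulated from the unedited genome yield exactly zero
junction reads.

# Motif analysis

`scan_pwm()` scores log2-odds against a background (default uniform,
pseudocount $10^{-3}$) and thresholds at a fraction $\theta = 0.8$ of the
maximum achievable score. This deliberately diverges from FIMO's p-value
machinery: a score-fraction threshold is deterministic and reproducible
without that tool's internals. Motif presence in a sequence is "at least
one hit", matching the frequency-count convention of the original
enrichment tables. `allele_motif_enrichment()` compares presence counts in
up- versus down-skewed allele sequences with an exact two-sided
hypergeometric test (minimum-likelihood convention, verified against
`fisher.test`) and BH q-values across motifs. No motif database is bundled;
PWMs are user-supplied (a synthetic 19-column CTCF-like matrix ships for
tests and is labelled synthetic — it is not the JASPAR matrix).

# Numerical choices and degenerate inputs

* Two-sided discrete p-values use a $1 + 10^{-7}$ tie tolerance when
  comparing pmf values, the same guard `binom.test` uses.
* `n_total = 0` skew records carry `p = NA`, direction `none`.
* A degenerate PWM whose maximum achievable score is non-positive returns
  every window with a warning rather than erroring.
* Zero outside-region coverage makes the domain ratio undefined (flagged),
  zero inside coverage makes it 0.
* Down-sampling ties at the maximum raw factor all map to exactly 1.

# Known limitations

Alignment itself, WASP-style read remapping, ML peak calling, Capture-C /
Tiled-C matrix processing and compartment eigenvector computation are out
of scope; the package consumes their products (placements, peaks,
compartment intervals). The open question of whether the landing-pad
insertion replaced reference bases is left open in the data model:
`edit_spec()` supports both pure insertion and replacement.
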
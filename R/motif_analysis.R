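#' Reverse complement of a DNA string
#' @param seq character sequence (ACGTN).
#' @return reverse complement.
#' @export
reverse_complement <- function(seq) {
  vapply(seq, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(s), "")[[1]]),
                                   collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# log2-odds score matrix lookup for one window; NA-free ACGT windows only
.score_matrix <- function(pwm) {
  log2(pwm$mat / pwm$background)
}

#' Scan a sequence with a PWM
#'
#' Scores every window on both strands with the log2-odds score
#' `sum(log2(p_base / background_base))` (the reverse strand scores the
#' reverse complement) and reports windows reaching at least `theta` times
#' the maximum achievable score. Overlapping hits are all reported. When the
#' maximum achievable score is not positive (e.g. a uniform matrix on a
#' uniform background) every window ties the threshold; all are returned
#' with a warning.
#'
#' @param sequence character sequence to scan.
#' @param pwm a [pwm()] object.
#' @param theta score threshold as a fraction of the maximum achievable
#'   score, in `(0, 1]` (default 0.8).
#' @return data.table of hits: `start`, `end` (0-based half-open on the
#'   forward strand), `strand`, `score`, `motif`; empty when the sequence is
#'   shorter than the motif.
#' @export
scan_pwm <- function(sequence, pwm, theta = 0.8) {
  stopifnot(inherits(pwm, "pwm"))
  if (theta <= 0 || theta > 1) stop("theta must lie in (0, 1]")
  seq <- toupper(sequence)
  W <- pwm$width
  L <- nchar(seq)
  empty <- data.table::data.table(start = integer(), end = integer(),
                                  strand = character(), score = numeric(),
                                  motif = character())
  if (L < W) return(empty)
  sm <- .score_matrix(pwm)
  max_score <- sum(apply(sm, 2, max))
  if (max_score <= 0)
    warning("maximum achievable score <= 0: degenerate matrix, ",
            "all windows reach the threshold")
  thr <- theta * max_score
  score_windows <- function(s) {
    chars <- strsplit(s, "")[[1]]
    idx <- match(chars, c("A", "C", "G", "T"))
    n <- length(chars) - W + 1L
    vapply(seq_len(n), function(i) {
      ii <- idx[i:(i + W - 1L)]
      if (anyNA(ii)) return(-Inf)  # N never matches
      sum(sm[cbind(ii, seq_len(W))])
    }, numeric(1))
  }
  fwd <- score_windows(seq)
  rev_ <- score_windows(reverse_complement(seq))
  hits <- list()
  fi <- which(fwd >= thr)
  if (length(fi))
    hits[[1]] <- data.table::data.table(start = fi - 1L, end = fi - 1L + W,
                                        strand = "+", score = fwd[fi],
                                        motif = pwm$id)
  ri <- which(rev_ >= thr)
  if (length(ri)) {
    # window i on the reverse-complement covers forward [L - i + 1 - W, L - i + 1)
    st <- L - (ri - 1L) - W
    hits[[length(hits) + 1L]] <- data.table::data.table(
      start = st, end = st + W, strand = "-", score = rev_[ri], motif = pwm$id)
  }
  out <- data.table::rbindlist(hits)
  if (!nrow(out)) return(empty)
  data.table::setorder(out, start, strand)
  out
}

#' Annotate peaks with CTCF motif orientation
#'
#' Labels each peak `"+"`, `"-"`, `"ambiguous"` (best hits on both strands
#' within 5% of each other) or `"none"` from the motif hits falling inside
#' it.
#'
#' @param peaks interval table with a `name` column (added when absent).
#' @param hits data.frame of motif hits in peak-relative or genomic
#'   coordinates, with columns `peak` (peak name), `strand`, `score`.
#' @return the peak table with an `orientation` column.
#' @export
annotate_ctcf_orientation <- function(peaks, hits) {
  pk <- as_interval_table(peaks)
  if (!"name" %in% names(pk))
    pk$name <- sprintf("peak%03d", seq_len(nrow(pk)))
  ht <- data.table::as.data.table(hits)
  pk$orientation <- vapply(pk$name, function(nm) {
    h <- ht[ht$peak == nm]
    if (!nrow(h)) return("none")
    bp <- suppressWarnings(max(h$score[h$strand == "+"]))
    bm <- suppressWarnings(max(h$score[h$strand == "-"]))
    if (!is.finite(bp)) return("-")
    if (!is.finite(bm)) return("+")
    if (abs(bp - bm) <= 0.05 * max(abs(bp), abs(bm))) return("ambiguous")
    if (bp > bm) "+" else "-"
  }, character(1))
  pk
}

# exact two-sided hypergeometric p for a 2x2 table, summing the
# probabilities of all tables (given the margins) no more likely than the
# observed one
.fisher2x2_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0L, c1 - (n - r1)); hi <- min(r1, c1)
  supp <- lo:hi
  logp <- lchoose(r1, supp) + lchoose(n - r1, c1 - supp) - lchoose(n, c1)
  probs <- exp(logp)
  obs <- probs[match(a, supp)]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

#' Allele-set motif enrichment
#'
#' Counts, per motif, how many up-skewed-allele sequences versus paired
#' down-skewed-allele sequences contain at least one hit (presence/absence),
#' then tests the 2x2 table (with-motif / without-motif by up / down) with an
#' exact two-sided hypergeometric test; Benjamini-Hochberg q-values are
#' computed across motifs. This mirrors the up-vs-background enrichment
#' design in which the down-skewed set is the background.
#'
#' @param up,down character vectors of paired sequences (same regions,
#'   different alleles); must have equal length.
#' @param pwms list of [pwm()] objects.
#' @param theta score-threshold fraction passed to [scan_pwm()].
#' @return data.table with `motif`, `up_count`, `down_count`, `n`,
#'   `p_value`, `q_value`.
#' @export
allele_motif_enrichment <- function(up, down, pwms, theta = 0.8) {
  if (length(up) == 0 || length(down) == 0) stop("empty sequence set")
  if (length(up) != length(down))
    stop("up and down sets must be paired (equal length)")
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  has_hit <- function(seqs, pw)
    vapply(seqs, function(s) nrow(scan_pwm(s, pw, theta)) > 0, logical(1),
           USE.NAMES = FALSE)
  rows <- lapply(pwms, function(pw) {
    u <- sum(has_hit(up, pw))
    d <- sum(has_hit(down, pw))
    n <- length(up)
    p <- .fisher2x2_p(u, n - u, d, n - d)
    data.table::data.table(motif = pw$id, up_count = u, down_count = d,
                           n = n, p_value = min(p, 1))
  })
  out <- data.table::rbindlist(rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Extract paired allele sequences around skewed variants
#'
#' For each variant, builds the up-skewed sequence from the up-skewed allele
#' and the down-skewed sequence from the down-skewed allele, either over a
#' window of `flank` bp each side of the variant (default 20) or over a
#' supplied region.
#'
#' @param reference a `genome_sequence`.
#' @param variants variant table (`chrom`, `pos`, `ref`, `alt`).
#' @param up_allele character vector, `"ref"` or `"alt"` per variant: which
#'   allele is up-skewed.
#' @param flank window half-width in bp.
#' @return list with character vectors `up` and `down` (positionally
#'   paired).
#' @export
allele_window_sequences <- function(reference, variants, up_allele,
                                    flank = 20) {
  vars <- data.table::as.data.table(variants)
  stopifnot(length(up_allele) == nrow(vars),
            all(up_allele %in% c("ref", "alt")))
  up <- character(nrow(vars)); down <- character(nrow(vars))
  for (i in seq_len(nrow(vars))) {
    seq <- reference$seqs[[vars$chrom[i]]]
    p <- vars$pos[i]
    left <- substr(seq, max(1, p + 1 - flank), p)
    right <- substr(seq, p + 2, min(nchar(seq), p + 1 + flank))
    with_allele <- function(al) paste0(left, al, right)
    if (up_allele[i] == "ref") {
      up[i] <- with_allele(vars$ref[i]); down[i] <- with_allele(vars$alt[i])
    } else {
      up[i] <- with_allele(vars$alt[i]); down[i] <- with_allele(vars$ref[i])
    }
  }
  list(up = up, down = down)
}
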
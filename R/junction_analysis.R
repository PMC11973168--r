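#' Classify one read against an insertion locus
#'
#' A read is `left_junction` when it covers the left breakpoint with at
#' least `k` bases on each side (`right_junction` analogously);
#' `spanning_both` when it covers both junctions; `internal` when fully
#' within the insert; `flank` otherwise (including reads on another
#' chromosome).
#'
#' @param start,end read placement (0-based half-open).
#' @param insert insert interval on the edited genome (a [gi()]); its start
#'   and end are the left and right junction breakpoints.
#' @param k minimum overhang in bp on each side of a breakpoint
#'   (default 5).
#' @param chrom read chromosome; reads off the insert chromosome are
#'   `flank`.
#' @return one of `"left_junction"`, `"right_junction"`, `"spanning_both"`,
#'   `"internal"`, `"flank"`.
#' @export
classify_read <- function(start, end, insert, k = 5, chrom = insert$chrom) {
  stopifnot(inherits(insert, "genomic_interval"), k >= 1)
  if (!identical(chrom, insert$chrom)) return("flank")
  jl <- insert$start; jr <- insert$end
  spans <- function(b) start <= b - k && end >= b + k
  sl <- spans(jl); sr <- spans(jr)
  if (sl && sr) return("spanning_both")
  if (sl) return("left_junction")
  if (sr) return("right_junction")
  if (start >= jl && end <= jr) return("internal")
  "flank"
}

#' Classify a placement table against an insertion locus
#'
#' Vectorized [classify_read()] over a placement table.
#'
#' @param placements placement table on the edited genome.
#' @param insert insert interval (a [gi()]).
#' @param k minimum overhang in bp.
#' @return the table with a `category` column.
#' @export
classify_placements <- function(placements, insert, k = 5) {
  dt <- data.table::as.data.table(placements)
  if (!nrow(dt)) {
    dt$category <- character(0)
    return(dt)
  }
  jl <- insert$start; jr <- insert$end
  on_chr <- dt$chrom == insert$chrom
  sl <- on_chr & dt$start <= jl - k & dt$end >= jl + k
  sr <- on_chr & dt$start <= jr - k & dt$end >= jr + k
  internal <- on_chr & dt$start >= jl & dt$end <= jr
  dt$category <- "flank"
  dt$category[internal] <- "internal"
  dt$category[sl] <- "left_junction"
  dt$category[sr] <- "right_junction"
  dt$category[sl & sr] <- "spanning_both"
  dt
}

#' Junction-support summary at an edited locus
#'
#' Classifies reads against the insertion junctions of the edited locus and,
#' when a native copy of the inserted sequence exists elsewhere, against the
#' native copy's boundaries (mapped through no coordinate change: supply the
#' native interval in edited-genome coordinates). The edited-locus signal is
#' flagged confirmed when the left plus right junction-spanning count
#' reaches `min_support`.
#'
#' @param placements placement table on the edited genome.
#' @param insert insert interval on the edited genome (a [gi()]).
#' @param native optional native-copy interval (a [gi()]).
#' @param k minimum overhang in bp (default 5).
#' @param min_support minimum junction-spanning reads to call the edited
#'   locus confirmed (default 3).
#' @return an object of class `junction_report`: list with `edited` and
#'   (optionally) `native` per-category count vectors, `junctions`,
#'   `min_overhang`, `confirmed`.
#' @export
junction_support_summary <- function(placements, insert, native = NULL,
                                     k = 5, min_support = 3) {
  cats <- c("left_junction", "right_junction", "spanning_both", "internal",
            "flank")
  tab <- function(iv) {
    cl <- classify_placements(placements, iv, k = k)
    stats::setNames(vapply(cats, function(cc) sum(cl$category == cc),
                           numeric(1)), cats)
  }
  edited <- tab(insert)
  native_tab <- if (!is.null(native)) tab(native) else NULL
  support <- edited[["left_junction"]] + edited[["right_junction"]] +
    edited[["spanning_both"]]
  structure(list(edited = edited, native = native_tab,
                 junctions = c(left = insert$start, right = insert$end),
                 min_overhang = k,
                 confirmed = support >= min_support),
            class = "junction_report")
}

#' @export
print.junction_report <- function(x, ...) {
  cat("<junction_report>\n  edited locus: ",
      paste(names(x$edited), x$edited, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$native))
    cat("  native locus: ",
        paste(names(x$native), x$native, sep = "=", collapse = ", "), "\n")
  cat("  min_overhang:", x$min_overhang,
      " confirmed:", x$confirmed, "\n")
  invisible(x)
}

#' Expected junction-spanning read count under uniform coverage
#'
#' Geometric oracle: with `depth` reads of length `R` placed uniformly over a
#' chromosome of length `L` (start positions `0 .. L - R`), the number of
#' start positions from which a read covers a breakpoint with at least `k`
#' bases on each side is `R - 2k + 1`, so the expected per-junction count is
#' `depth * (R - 2k + 1) / (L - R + 1)`.
#'
#' @param depth number of reads.
#' @param read_length read length `R`.
#' @param chrom_length chromosome length `L`.
#' @param k minimum overhang.
#' @param n_junctions number of junction breakpoints (default 2).
#' @return list with `expected` count and binomial `se`.
#' @export
expected_junction_reads <- function(depth, read_length, chrom_length, k = 5,
                                    n_junctions = 2) {
  p1 <- (read_length - 2 * k + 1) / (chrom_length - read_length + 1)
  p <- n_junctions * p1
  list(expected = depth * p, se = sqrt(depth * p * (1 - p)))
}
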
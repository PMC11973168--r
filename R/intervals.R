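#' Genomic interval (0-based, half-open)
#'
#' The universal coordinate unit of the package. `start` is 0-based inclusive,
#' `end` is exclusive, so `interval_length()` is simply `end - start`.
#'
#' @param chrom chromosome name.
#' @param start 0-based inclusive start; `0 <= start <= end`.
#' @param end exclusive end.
#' @param strand one of `"+"`, `"-"` or `"*"` (unset, the default).
#' @param name optional label.
#' @return an object of class `genomic_interval`.
#' @examples
#' gi("chr1", 0, 100)
#' @export
gi <- function(chrom, start, end, strand = "*", name = NA_character_) {
  stopifnot(is.character(chrom), length(chrom) == 1L, nzchar(chrom))
  start <- as.double(start); end <- as.double(end)
  if (is.na(start) || is.na(end) || start < 0 || start > end)
    stop("invalid interval: need 0 <= start <= end, got [", start, ", ", end, ")")
  if (!strand %in% c("+", "-", "*")) stop("strand must be one of '+', '-', '*'")
  structure(list(chrom = chrom, start = start, end = end,
                 strand = strand, name = name),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<%s:%s-%s%s%s> (%s bp)\n", x$chrom,
              format(x$start, big.mark = ",", scientific = FALSE),
              format(x$end, big.mark = ",", scientific = FALSE),
              if (x$strand != "*") paste0(" ", x$strand) else "",
              if (!is.na(x$name)) paste0(" ", x$name) else "",
              format(interval_length(x), big.mark = ",")))
  invisible(x)
}

#' Interval length in base pairs
#' @param x a `genomic_interval`.
#' @return `end - start`.
#' @export
interval_length <- function(x) {
  stopifnot(inherits(x, "genomic_interval"))
  x$end - x$start
}

#' Parse a printed region string into a genomic interval
#'
#' Printed regions such as `"chr11:32,188,452-32,249,902"` follow the
#' browser convention: 1-based, inclusive at both ends. They are converted to
#' the internal 0-based half-open convention as `(start - 1, end)`, so a
#' single-base region `"chr1:5-5"` has length 1. Thousands separators,
#' surrounding whitespace and unicode dashes are tolerated.
#'
#' @param text region string `"chrom:start-end"`.
#' @return a [gi()] interval.
#' @examples
#' interval_length(parse_interval("chr11:32,188,452-32,249,902"))  # 61451
#' @export
parse_interval <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  # normalize unicode minus/en-dash and strip commas/space
  norm <- gsub("[−–—]", "-", text)
  norm <- gsub("[,\\s]", "", norm, perl = TRUE)
  m <- regmatches(norm, regexec("^([^:]+):([0-9]+)-([0-9]+)$", norm))[[1]]
  if (length(m) != 4L)
    stop("malformed region string: '", text, "'")
  start1 <- as.double(m[3]); end1 <- as.double(m[4])
  if (start1 < 1) stop("1-based start must be >= 1 in '", text, "'")
  if (start1 > end1)
    stop("start > end in region '", text, "'")
  gi(m[2], start1 - 1, end1)
}

#' Format a genomic interval as a printed region string
#'
#' Inverse of [parse_interval()]: emits 1-based inclusive coordinates without
#' thousands separators, so `parse_interval(format_interval(x))` is the
#' identity on valid intervals of length >= 1.
#'
#' @param x a `genomic_interval`.
#' @return a string `"chrom:start-end"`.
#' @export
format_interval <- function(x) {
  stopifnot(inherits(x, "genomic_interval"))
  sprintf("%s:%s-%s", x$chrom,
          format(x$start + 1, scientific = FALSE, trim = TRUE),
          format(x$end, scientific = FALSE, trim = TRUE))
}

#' Convert a data.frame of intervals to an IRanges per chromosome
#' @noRd
.intervals_to_iranges <- function(df, chrom) {
  sub <- df[df$chrom == chrom, , drop = FALSE]
  IRanges::IRanges(start = sub$start + 1L, end = sub$end)  # IRanges is 1-based closed
}

#' Build an interval table
#'
#' Many operations take interval sets as plain `data.frame`s with columns
#' `chrom`, `start`, `end` and optionally `name`, `score`, `strand` (BED
#' order). This helper validates and normalizes such a table.
#'
#' @param df data.frame with at least `chrom`, `start`, `end`.
#' @return a `data.table` with validated coordinates.
#' @export
as_interval_table <- function(df) {
  dt <- data.table::as.data.table(df)
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(dt)))
    stop("interval table needs columns: ", paste(req, collapse = ", "))
  if (nrow(dt) && any(dt$start < 0 | dt$start > dt$end))
    stop("interval table contains invalid coordinates")
  dt
}
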
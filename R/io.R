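#' Genome sequence container
#'
#' Per-chromosome sequences over `{A,C,G,T,N}` plus an identity label
#' (`reference`, `hap1`, `hap2`, `edited`, `spikein`, ...).
#'
#' @param seqs named character vector of uppercase sequences.
#' @param label genome identity label.
#' @return an object of class `genome_sequence`.
#' @export
genome_sequence <- function(seqs, label = "reference") {
  stopifnot(is.character(seqs), length(seqs) > 0)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be uniquely named by chromosome")
  if (any(!nzchar(seqs))) stop("empty chromosome sequence")
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) stop("non-ACGTN characters in: ", paste(names(seqs)[bad], collapse = ", "))
  structure(list(seqs = seqs, label = label), class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("<genome_sequence '%s': %d chrom(s), %s bp>\n", x$label,
              length(x$seqs), format(sum(nchar(x$seqs)), big.mark = ",")))
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param genome a `genome_sequence`.
#' @return named numeric vector of lengths.
#' @export
chrom_lengths <- function(genome) {
  stopifnot(inherits(genome, "genome_sequence"))
  vapply(genome$seqs, nchar, numeric(1))
}

#' Read a FASTA file as a genome
#' @param path FASTA file.
#' @param label genome identity label.
#' @return a `genome_sequence`.
#' @export
read_genome_fasta <- function(path, label = "reference") {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))  # first token of the header
  genome_sequence(stats::setNames(as.character(ss), nm), label = label)
}

#' Write a genome to FASTA
#' @param genome a `genome_sequence`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "genome_sequence"))
  ss <- Biostrings::DNAStringSet(genome$seqs)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

# ---- BED / bedGraph --------------------------------------------------------

#' Read a BED3/BED6 file
#' @param path BED file (0-based half-open, as BED natively is).
#' @return data.table with columns chrom, start, end and, when present,
#'   name, score, strand.
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  if (ncol(dt) < 3L) stop("BED file needs >= 3 columns: ", path)
  data.table::setnames(dt, seq_len(min(ncol(dt), 6L)), nm[seq_len(min(ncol(dt), 6L))])
  as_interval_table(dt)
}

#' Write a BED file
#' @param df interval table (chrom, start, end, optionally name/score/strand).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  dt <- as_interval_table(df)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(dt))
  # BED columns are positional: stop at the first absent one
  keepn <- character(0)
  for (cn in c("chrom", "start", "end", "name", "score", "strand")) {
    if (cn %in% cols) keepn <- c(keepn, cn) else break
  }
  data.table::fwrite(dt[, keepn, with = FALSE], path, sep = "\t",
                     col.names = FALSE, scipen = 50)
  invisible(path)
}

#' Read a bedGraph coverage file into a track
#'
#' bedGraph rows are 0-based half-open `(chrom, start, end, value)`. Rows must
#' align to a common bin grid; the bin size is inferred from the row spans
#' unless given. Bins absent from the file are zero.
#'
#' @param path bedGraph file.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param bin_size optional; inferred from the most common row span if `NULL`.
#' @param normalization normalization state to record.
#' @param total_mapped_reads mapped-read total to record.
#' @return a `coverage_track`.
#' @export
read_bedgraph <- function(path, chrom_lengths, bin_size = NULL,
                          normalization = "raw", total_mapped_reads = NA_real_) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"))
  if (is.null(bin_size)) {
    spans <- dt$end - dt$start
    bin_size <- if (nrow(dt)) as.integer(stats::median(spans)) else 1L
  }
  vals <- lapply(names(chrom_lengths), function(chr) {
    nb <- ceiling(chrom_lengths[[chr]] / bin_size)
    v <- numeric(nb)
    sub <- dt[chrom == chr]
    if (nrow(sub)) {
      if (any(sub$start %% bin_size != 0))
        stop("bedGraph rows not aligned to bin grid of ", bin_size, " bp")
      idx <- sub$start %/% bin_size + 1L
      v[idx] <- sub$value
    }
    v
  })
  names(vals) <- names(chrom_lengths)
  coverage_track(vals, bin_size, chrom_lengths, normalization, total_mapped_reads)
}

#' Write a coverage track to bedGraph
#'
#' Zero bins are omitted (conventional sparse bedGraph); adjacent equal-value
#' bins are not merged so the bin grid round-trips exactly.
#'
#' @param track a `coverage_track`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  bs <- track$bin_size
  rows <- lapply(names(track$values), function(chr) {
    v <- track$values[[chr]]
    nz <- which(v != 0)
    if (!length(nz)) return(NULL)
    data.table::data.table(chrom = chr,
                           start = (nz - 1L) * bs,
                           end = pmin(nz * bs, track$chrom_lengths[[chr]]),
                           value = v[nz])
  })
  dt <- data.table::rbindlist(rows)
  if (!nrow(dt)) dt <- data.table::data.table(chrom = character(), start = integer(),
                                              end = integer(), value = numeric())
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, scipen = 50)
  invisible(path)
}

# ---- phased VCF subset -----------------------------------------------------

#' Read a simplified phased VCF
#'
#' Supports the biallelic-SNV/indel subset of VCF v4 the skew pipeline
#' consumes: columns CHROM, POS, ID, REF, ALT, (QUAL, FILTER, INFO,) FORMAT
#' with a GT field, and one sample column. `|` genotype separators mark phased
#' records, `/` unphased. Symbolic (`<...>`) and multi-allelic ALTs are
#' skipped with a warning. 1-based POS is converted to 0-based.
#'
#' @param path VCF file (uncompressed text).
#' @return data.table with columns `chrom`, `pos` (0-based), `id`, `ref`,
#'   `alt`, `gt1`, `gt2` (0 = ref, 1 = alt), `phased`, `het`.
#' @export
read_phased_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  header <- grep("^#CHROM", lines, value = TRUE)
  if (!length(header) && length(body))
    warning("VCF without #CHROM header line: assuming standard column order")
  recs <- data.table::rbindlist(lapply(body, .parse_vcf_line), fill = TRUE)
  if (!nrow(recs))
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  id = character(), ref = character(),
                                  alt = character(), gt1 = integer(),
                                  gt2 = integer(), phased = logical(),
                                  het = logical()))
  recs[]
}

.parse_vcf_line <- function(line) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) < 10L) stop("VCF record with no genotype column: ", line)
  alt <- f[5]
  if (grepl("[<>]", alt) || grepl(",", alt, fixed = TRUE)) {
    warning("skipping symbolic/multi-allelic VCF record at ", f[1], ":", f[2])
    return(NULL)
  }
  fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
  gti <- match("GT", fmt)
  if (is.na(gti)) stop("FORMAT without GT field: ", line)
  gt <- strsplit(f[10], ":", fixed = TRUE)[[1]][gti]
  phased <- grepl("|", gt, fixed = TRUE)
  alleles <- strsplit(gt, "[|/]")[[1]]
  if (length(alleles) != 2L || any(!alleles %in% c("0", "1", ".")))
    stop("unsupported GT '", gt, "' at ", f[1], ":", f[2])
  if (any(alleles == ".")) return(NULL)  # missing genotype: skip
  a <- as.integer(alleles)
  data.table::data.table(chrom = f[1], pos = as.integer(f[2]) - 1L, id = f[3],
                         ref = f[4], alt = alt, gt1 = a[1], gt2 = a[2],
                         phased = phased, het = a[1] != a[2])
}

#' Write a simplified phased VCF
#' @param variants table as returned by [read_phased_vcf()].
#' @param path output file.
#' @param sample_name sample column name.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(variants, path, sample_name = "SAMPLE") {
  dt <- data.table::as.data.table(variants)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                      sample_name)), con)
  if (nrow(dt)) {
    sep <- ifelse(dt$phased, "|", "/")
    gt <- paste0(dt$gt1, sep, dt$gt2)
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.\tGT\t%s",
                       dt$chrom, dt$pos + 1L, dt$id, dt$ref, dt$alt, gt), con)
  }
  invisible(path)
}

# ---- MEME minimal motif format --------------------------------------------

#' Read a MEME-minimal motif file into a PWM
#'
#' Parses the first `letter-probability matrix` block of a MEME minimal motif
#' file (`alength` must be 4, alphabet ACGT). Columns whose probabilities sum
#' beyond 0.05 of 1 before pseudocounting trigger a format warning. A
#' pseudocount is added and columns renormalized.
#'
#' @param path MEME-format motif file.
#' @param pseudocount per-cell pseudocount (default 1e-3).
#' @param background length-4 background probabilities (A,C,G,T); default
#'   uniform.
#' @return an object of class `pwm` with fields `id`, `width`, `mat`
#'   (4 x W probability matrix, rows A/C/G/T), `background`, `pseudocount`.
#' @export
read_pwm <- function(path, pseudocount = 1e-3, background = rep(0.25, 4)) {
  lines <- readLines(path)
  al <- grep("^ALPHABET=", lines, value = TRUE)
  if (length(al) && !grepl("ACGT", al[1]))
    stop("non-ACGT alphabet in MEME file: ", al[1])
  mi <- grep("^MOTIF", lines)
  if (!length(mi)) stop("no MOTIF block in ", path)
  id <- strsplit(trimws(lines[mi[1]]), "\\s+")[[1]][2]
  li <- grep("letter-probability matrix", lines)
  if (!length(li)) stop("no letter-probability matrix block in ", path)
  hdr <- lines[li[1]]
  alen <- sub(".*alength= *([0-9]+).*", "\\1", hdr)
  if (grepl("alength=", hdr) && as.integer(alen) != 4L)
    stop("alength must be 4, got ", alen)
  rows <- list()
  for (i in seq(li[1] + 1L, length(lines))) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || !grepl("^[0-9.eE+ -]+$", ln)) break
    rows[[length(rows) + 1L]] <- as.numeric(strsplit(ln, "\\s+")[[1]])
  }
  if (!length(rows)) stop("empty probability matrix in ", path)
  if (any(vapply(rows, length, 1L) != 4L)) stop("matrix rows must have 4 values")
  mat <- t(do.call(rbind, rows))            # 4 x W, MEME rows are positions
  rownames(mat) <- c("A", "C", "G", "T")
  pwm(id = id, mat = mat, background = background, pseudocount = pseudocount)
}

#' Construct a PWM
#'
#' @param id motif identifier.
#' @param mat 4 x W matrix of per-position base probabilities (rows A,C,G,T).
#' @param background length-4 background (sums to 1).
#' @param pseudocount per-cell pseudocount applied before renormalizing.
#' @return a `pwm` object; columns sum to 1 after pseudocounting.
#' @export
pwm <- function(id, mat, background = rep(0.25, 4), pseudocount = 1e-3) {
  stopifnot(is.matrix(mat), nrow(mat) == 4L, ncol(mat) >= 1L)
  if (any(mat < 0)) stop("negative PWM probabilities")
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  csums <- colSums(mat)
  if (any(abs(csums - 1) > 0.05))
    warning("PWM column sums deviate from 1 by more than 0.05 before pseudocounting")
  mat <- sweep(mat + pseudocount, 2, csums + 4 * pseudocount, "/")
  rownames(mat) <- c("A", "C", "G", "T")
  structure(list(id = id, width = ncol(mat), mat = mat,
                 background = background, pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm '%s': width %d, consensus %s>\n", x$id, x$width,
              paste(rownames(x$mat)[apply(x$mat, 2, which.max)], collapse = "")))
  invisible(x)
}

#' Write a PWM as a MEME minimal motif file
#' @param x a `pwm`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(x, path) {
  stopifnot(inherits(x, "pwm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", c("A", "C", "G", "T"), x$background),
                     collapse = " "), "",
               paste("MOTIF", x$id),
               sprintf("letter-probability matrix: alength= 4 w= %d", x$width)),
             con)
  writeLines(apply(x$mat, 2, function(col)
    paste(sprintf("%.6f", col), collapse = "  ")), con)
  invisible(path)
}

# ---- read-placement tables -------------------------------------------------

#' Read a read-placement table
#'
#' The simplified SAM-like interchange: a TSV with columns `read_id`,
#' `genome`, `chrom`, `start`, `end`, `mate_start`, `mate_end`, `source`
#' (`target` or `spikein`). Coordinates are 0-based half-open; mate columns
#' may be NA.
#'
#' @param path TSV file.
#' @return a `data.table`.
#' @export
read_placements <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("read_id", "genome",
                                                          "chrom", "source")))
  for (mc in c("mate_start", "mate_end"))  # all-NA columns come back logical
    if (mc %in% names(dt) && is.logical(dt[[mc]]))
      data.table::set(dt, j = mc, value = as.integer(dt[[mc]]))
  validate_placements(dt)
  dt
}

#' Write a read-placement table
#' @param placements a placement `data.table`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_placements <- function(placements, path) {
  validate_placements(placements)
  data.table::fwrite(placements, path, sep = "\t", na = "NA", scipen = 50)
  invisible(path)
}

#' Validate a read-placement table
#' @param dt candidate table.
#' @return `dt`, invisibly; errors describe the first violation.
#' @export
validate_placements <- function(dt) {
  req <- c("read_id", "genome", "chrom", "start", "end", "source")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stop("placement table missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(dt)) {
    if (any(dt$start >= dt$end)) stop("placement with start >= end")
    if (any(!dt$source %in% c("target", "spikein")))
      stop("source must be 'target' or 'spikein'")
  }
  invisible(dt)
}
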
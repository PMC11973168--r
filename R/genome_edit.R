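#' Edit specification for a custom genome
#'
#' Describes one cut-and-paste edit: `insert` replaces the reference bases of
#' the target interval. A zero-length target (`start == end`) is a pure
#' insertion at that point.
#'
#' @param chrom chromosome carrying the edit.
#' @param start,end target interval on the reference (0-based half-open;
#'   `start == end` for a pure insertion).
#' @param insert non-empty insert sequence.
#' @param landing_pad optional landing-pad identifier.
#' @return an object of class `edit_spec`.
#' @export
edit_spec <- function(chrom, start, end, insert, landing_pad = NA_character_) {
  stopifnot(is.character(insert), length(insert) == 1L, nzchar(insert))
  insert <- toupper(insert)
  if (grepl("[^ACGTN]", insert)) stop("insert contains non-ACGTN characters")
  if (start < 0 || start > end) stop("invalid target interval")
  structure(list(chrom = chrom, start = as.double(start), end = as.double(end),
                 insert = insert, landing_pad = landing_pad),
            class = "edit_spec")
}

# ---- coordinate maps -------------------------------------------------------

#' Construct a coordinate map from aligned blocks
#'
#' A coordinate map is an ordered set of equal-length block pairs
#' `(ref interval, alt interval)`; positions inside blocks map bijectively,
#' positions in the gaps between blocks (indel/insert interiors) are
#' unmappable.
#'
#' @param blocks data.frame with columns `ref_start`, `ref_end`, `alt_start`,
#'   `alt_end`; block pairs must have equal lengths, be sorted and
#'   non-overlapping.
#' @param chrom chromosome the map belongs to.
#' @return an object of class `coordinate_map`.
#' @export
coordinate_map <- function(blocks, chrom = NA_character_) {
  dt <- data.table::as.data.table(blocks)
  req <- c("ref_start", "ref_end", "alt_start", "alt_end")
  stopifnot(all(req %in% names(dt)))
  dt <- dt[dt$ref_end > dt$ref_start]  # drop empty blocks
  if (nrow(dt)) {
    if (any((dt$ref_end - dt$ref_start) != (dt$alt_end - dt$alt_start)))
      stop("coordinate map blocks must pair intervals of equal length")
    data.table::setorder(dt, ref_start)
    if (any(diff(dt$ref_start) < utils::head(dt$ref_end, -1) - utils::head(dt$ref_start, -1) &
            utils::head(dt$ref_end, -1) > utils::tail(dt$ref_start, -1)))
      stop("overlapping reference blocks in coordinate map")
  }
  structure(list(blocks = dt, chrom = chrom), class = "coordinate_map")
}

#' Map positions through a coordinate map
#'
#' @param map a `coordinate_map`.
#' @param pos vector of 0-based positions.
#' @param from `"ref"` to map reference -> alt, `"alt"` for the inverse.
#' @return numeric vector; `NA` where the position falls in an indel gap.
#' @export
map_position <- function(map, pos, from = c("ref", "alt")) {
  stopifnot(inherits(map, "coordinate_map"))
  from <- match.arg(from)
  b <- map$blocks
  s <- if (from == "ref") b$ref_start else b$alt_start
  e <- if (from == "ref") b$ref_end else b$alt_end
  o <- if (from == "ref") b$alt_start else b$ref_start
  vapply(pos, function(p) {
    i <- which(s <= p & p < e)
    if (length(i) != 1L) NA_real_ else o[i] + (p - s[i])
  }, numeric(1))
}

# merge contiguous blocks with identical shift
.compact_blocks <- function(blocks) {
  if (!nrow(blocks)) return(blocks)
  data.table::setorder(blocks, ref_start)
  out <- list(blocks[1, ])
  for (i in seq_len(nrow(blocks))[-1]) {
    prev <- out[[length(out)]]
    cur <- blocks[i, ]
    if (cur$ref_start == prev$ref_end && cur$alt_start == prev$alt_end) {
      prev$ref_end <- cur$ref_end
      prev$alt_end <- cur$alt_end
      out[[length(out)]] <- prev
    } else out[[length(out) + 1L]] <- cur
  }
  data.table::rbindlist(out)
}

# apply a sorted variant set to one chromosome sequence; returns seq + blocks
.apply_alleles <- function(seq, vars) {
  pieces <- character(0)
  blocks <- list()
  cur_ref <- 0; cur_alt <- 0
  L <- nchar(seq)
  if (nrow(vars)) {
    data.table::setorder(vars, pos)
    lastend <- c(-1, utils::head(vars$pos + nchar(vars$ref), -1))
    if (any(vars$pos < lastend))
      stop("overlapping variants at ", vars$chrom[1], ":",
           vars$pos[which(vars$pos < lastend)[1]])
  }
  for (i in seq_len(nrow(vars))) {
    v <- vars[i, ]
    rlen <- nchar(v$ref); alen <- nchar(v$alt)
    if (v$pos + rlen > L) stop("variant beyond chromosome end at pos ", v$pos)
    gap <- v$pos - cur_ref
    if (gap > 0) {
      pieces <- c(pieces, substr(seq, cur_ref + 1, v$pos))
      blocks[[length(blocks) + 1L]] <-
        data.table::data.table(ref_start = cur_ref, ref_end = v$pos,
                               alt_start = cur_alt, alt_end = cur_alt + gap)
      cur_alt <- cur_alt + gap
      cur_ref <- v$pos
    }
    obs <- substr(seq, v$pos + 1, v$pos + rlen)
    if (obs != toupper(v$ref))
      stop("ref allele mismatch at ", v$chrom, ":", v$pos,
           " (expected ", v$ref, ", reference has ", obs, ")")
    pieces <- c(pieces, v$alt)
    if (rlen == alen) {
      # length-preserving: positions inside the allele still map 1:1
      blocks[[length(blocks) + 1L]] <-
        data.table::data.table(ref_start = cur_ref, ref_end = cur_ref + rlen,
                               alt_start = cur_alt, alt_end = cur_alt + alen)
    }
    cur_ref <- cur_ref + rlen
    cur_alt <- cur_alt + alen
  }
  if (cur_ref < L) {
    pieces <- c(pieces, substr(seq, cur_ref + 1, L))
    blocks[[length(blocks) + 1L]] <-
      data.table::data.table(ref_start = cur_ref, ref_end = L,
                             alt_start = cur_alt, alt_end = cur_alt + (L - cur_ref))
  }
  list(seq = paste(pieces, collapse = ""),
       blocks = .compact_blocks(data.table::rbindlist(blocks)))
}

#' Build personalized (per-haplotype) genomes from phased variants
#'
#' Applies, per haplotype, exactly the alleles the phased genotypes assign to
#' it (consensus-style). SNVs preserve length; indels shift downstream
#' coordinates and the returned coordinate maps record the shift.
#'
#' @param reference a `genome_sequence`.
#' @param variants phased variant table (see [read_phased_vcf()]); unphased
#'   heterozygotes are skipped with a warning, homozygous-alt records are
#'   applied to both haplotypes.
#' @return list with `hap1`, `hap2` (`genome_sequence`s) and `map1`, `map2`
#'   (named lists of `coordinate_map`s per chromosome).
#' @export
build_personalized_genomes <- function(reference, variants) {
  stopifnot(inherits(reference, "genome_sequence"))
  vars <- data.table::as.data.table(variants)
  if (nrow(vars)) {
    drop <- vars$het & !vars$phased
    if (any(drop)) {
      warning("skipping ", sum(drop), " unphased heterozygous variant(s)")
      vars <- vars[!drop]
    }
    unknown <- setdiff(unique(vars$chrom), names(reference$seqs))
    if (length(unknown)) stop("variants on unknown chromosome(s): ",
                              paste(unknown, collapse = ", "))
  }
  build_one <- function(gt_col, label) {
    seqs <- character(0); maps <- list()
    for (chr in names(reference$seqs)) {
      v <- vars[vars$chrom == chr & vars[[gt_col]] == 1L, ]
      res <- .apply_alleles(reference$seqs[[chr]], v)
      seqs[[chr]] <- res$seq
      maps[[chr]] <- coordinate_map(res$blocks, chrom = chr)
    }
    list(genome = genome_sequence(seqs, label = label), maps = maps)
  }
  h1 <- build_one("gt1", "hap1")
  h2 <- build_one("gt2", "hap2")
  list(hap1 = h1$genome, hap2 = h2$genome, map1 = h1$maps, map2 = h2$maps)
}

#' Build an insertion/replacement-edited genome
#'
#' Cuts-and-pastes the insert over the target interval. The edited chromosome
#' length is `reference length + insert length - replaced length`. Junction
#' breakpoints sit at `target.start` and `target.start + insert length` in
#' edited coordinates. The coordinate map covers only the flanks: the insert
#' (and any replaced reference bases) are unmappable.
#'
#' @param reference a `genome_sequence`.
#' @param edit an [edit_spec()].
#' @return list with `genome` (edited `genome_sequence`), `map`
#'   (`coordinate_map` for the edited chromosome), `junctions` (length-2
#'   numeric, edited coordinates) and `insert_interval` (a [gi()] on the
#'   edited genome).
#' @export
build_edited_genome <- function(reference, edit) {
  stopifnot(inherits(reference, "genome_sequence"), inherits(edit, "edit_spec"))
  if (!edit$chrom %in% names(reference$seqs))
    stop("edit on unknown chromosome ", edit$chrom)
  seq <- reference$seqs[[edit$chrom]]
  L <- nchar(seq)
  if (edit$end > L) stop("edit target exceeds chromosome ", edit$chrom,
                         " (length ", L, ")")
  ins_len <- nchar(edit$insert)
  edited <- paste0(substr(seq, 1, edit$start), edit$insert,
                   substr(seq, edit$end + 1, L))
  shift <- ins_len - (edit$end - edit$start)
  blocks <- data.table::rbindlist(list(
    data.table::data.table(ref_start = 0, ref_end = edit$start,
                           alt_start = 0, alt_end = edit$start),
    data.table::data.table(ref_start = edit$end, ref_end = L,
                           alt_start = edit$end + shift, alt_end = L + shift)))
  seqs <- reference$seqs
  seqs[[edit$chrom]] <- edited
  list(genome = genome_sequence(seqs, label = "edited"),
       map = coordinate_map(blocks, chrom = edit$chrom),
       junctions = c(left = edit$start, right = edit$start + ins_len),
       insert_interval = gi(edit$chrom, edit$start, edit$start + ins_len,
                            name = "insert"))
}

# ---- in-silico digestion and viewpoint design ------------------------------

#' In-silico DpnII digestion
#'
#' Cuts at the start of every GATC occurrence (blunt in-silico convention),
#' returning fragments that tile the sequence exactly; terminal fragments are
#' included and N never matches.
#'
#' @param sequence a character sequence or a `genome_sequence`.
#' @param chrom chromosome name used for character input (default `"seq"`);
#'   for a `genome_sequence`, all chromosomes are digested.
#' @param site recognition site (default `"GATC"`).
#' @return data.table of fragment intervals (`chrom`, `start`, `end`).
#' @export
dpnII_digest <- function(sequence, chrom = "seq", site = "GATC") {
  if (inherits(sequence, "genome_sequence")) {
    out <- lapply(names(sequence$seqs), function(chr)
      dpnII_digest(sequence$seqs[[chr]], chrom = chr, site = site))
    return(data.table::rbindlist(out))
  }
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seq <- toupper(sequence)
  L <- nchar(seq)
  occ <- gregexpr(site, seq, fixed = TRUE)[[1]]  # GATC cannot overlap itself
  cuts <- if (occ[1] == -1L) integer(0) else as.integer(occ) - 1L  # 0-based
  cuts <- cuts[cuts > 0L]
  bounds <- c(0L, cuts, L)
  data.table::data.table(chrom = chrom,
                         start = utils::head(bounds, -1),
                         end = utils::tail(bounds, -1))
}

#' Select evenly spaced restriction-fragment viewpoints
#'
#' Keeps fragments whose length lies in `[min_len, max_len]` (inclusive) and
#' which fall inside the locus, then greedily partitions the locus into `n`
#' equal windows and picks the qualifying fragment whose midpoint is nearest
#' each window centre (without reuse). If fewer than `n` fragments qualify,
#' all are returned with a warning.
#'
#' @param fragments fragment interval table (e.g. from [dpnII_digest()]).
#' @param min_len,max_len inclusive fragment-length bounds in bp (defaults
#'   1000 and 3000, the 1-3 kb capture design range).
#' @param n number of viewpoints to pick (default 6).
#' @param locus a [gi()] interval the viewpoints must span.
#' @return data.table of selected fragments in genomic order.
#' @export
select_viewpoints <- function(fragments, min_len = 1000, max_len = 3000,
                              n = 6, locus) {
  stopifnot(min_len <= max_len, n >= 1, inherits(locus, "genomic_interval"))
  fr <- as_interval_table(fragments)
  if (!nrow(fr)) stop("empty fragment list")
  len <- fr$end - fr$start
  ok <- fr$chrom == locus$chrom & len >= min_len & len <= max_len &
    fr$start >= locus$start & fr$end <= locus$end
  cand <- fr[ok]
  if (!nrow(cand)) {
    warning("no qualifying fragments in the locus")
    return(cand)
  }
  if (nrow(cand) <= n) {
    if (nrow(cand) < n)
      warning("only ", nrow(cand), " qualifying fragments for n = ", n)
    data.table::setorder(cand, start)
    return(cand)
  }
  mid <- (cand$start + cand$end) / 2
  win <- (locus$end - locus$start) / n
  centers <- locus$start + (seq_len(n) - 0.5) * win
  chosen <- integer(0)
  for (ct in centers) {
    avail <- setdiff(seq_len(nrow(cand)), chosen)
    chosen <- c(chosen, avail[which.min(abs(mid[avail] - ct))])
  }
  out <- cand[sort(unique(chosen))]
  data.table::setorder(out, start)
  out
}
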
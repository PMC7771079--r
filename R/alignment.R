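# SAM/BAM ingestion: record classification, CIGAR read-coordinate
# arithmetic, reference blocks, and grouping of records by read name.
#
# A chimeric (fusion) long read is written by spliced aligners as one
# primary record plus >=1 supplementary records sharing the read name; the
# portions of the read each record consumes are recovered from the CIGAR
# clips and expressed in ORIGINAL-read coordinates so segments of the same
# read are directly comparable regardless of mapping strand.

# CIGAR op groups
.OPS_QUERY <- c("M", "I", "S", "=", "X")   # consume query (soft clips incl.)
.OPS_ALIGN <- c("M", "=", "X")             # aligned (match/mismatch) bases
.OPS_CLIP  <- c("S", "H")

#' Classify a SAM record from its FLAG
#'
#' @param flag integer vector of SAM FLAG values
#' @return character vector: `"unmapped"` (0x4), `"secondary"` (0x100),
#'   `"supplementary"` (0x800), else `"primary"`. Secondary alignments are
#'   alternative placements of the same read portion and are discarded:
#'   the two sides of a genuine fusion junction come from independent genes
#'   and share no read bases, which is the signature of a *supplementary*
#'   record.
#' @export
classify_record <- function(flag) {
  data.table::fcase(
    bitwAnd(flag, 4L) > 0L, "unmapped",
    bitwAnd(flag, 256L) > 0L, "secondary",
    bitwAnd(flag, 2048L) > 0L, "supplementary",
    rep(TRUE, length(flag)), "primary")
}

# exploded CIGAR ops/lengths for a character vector of CIGARs
.explode_cigar <- function(cigar) {
  list(ops = GenomicAlignments::explodeCigarOps(cigar),
       len = GenomicAlignments::explodeCigarOpLengths(cigar))
}

# query length implied by a CIGAR, hard clips counted (= original read length)
cigar_read_length <- function(cigar) {
  ex <- .explode_cigar(cigar)
  vapply(seq_along(ex$ops), function(i)
    sum(ex$len[[i]][ex$ops[[i]] %in% c(.OPS_QUERY, "H")]), integer(1L))
}

#' Read-coordinate span of an alignment record
#'
#' Returns the half-open interval `[M_start, M_end)` of original-read
#' positions consumed by the aligned part of the record. For a
#' forward-strand record this is `[leading_clip, leading_clip + consumed)`;
#' for a reverse-strand record the clip-derived interval is reflected
#' through the read length, so spans from different segments of one read are
#' comparable in the coordinates of the read as it was sequenced.
#'
#' @param cigar CIGAR string (scalar)
#' @param seg_strand `"+"` or `"-"` (SAM reverse flag)
#' @param read_length original read length in bp (clips included; hard
#'   clips count). If `NULL`, inferred from the CIGAR itself.
#' @return integer vector `c(M_start, M_end)`, 0-based half-open
#' @export
read_span_from_cigar <- function(cigar, seg_strand, read_length = NULL) {
  ex <- .explode_cigar(cigar)
  ops <- ex$ops[[1L]]; len <- ex$len[[1L]]
  if (is.null(read_length)) read_length <- sum(len[ops %in% c(.OPS_QUERY, "H")])
  nonclip <- which(!ops %in% .OPS_CLIP)
  if (length(nonclip) == 0L) stop("CIGAR has no aligned ops: ", cigar)
  lead <- if (min(nonclip) > 1L) sum(len[seq_len(min(nonclip) - 1L)]) else 0L
  consumed <- sum(len[ops %in% c("M", "I", "=", "X")])
  if (identical(seg_strand, "-")) {
    c(read_length - lead - consumed, read_length - lead)
  } else {
    c(lead, lead + consumed)
  }
}

#' Reference blocks consumed by a CIGAR
#'
#' M/=/X ops emit aligned blocks; D and N (intron) advance the reference
#' without emitting; I/S/H advance only the query. Blocks separated only by
#' insertions are merged.
#'
#' @param cigar CIGAR string (scalar)
#' @param ref_start 0-based reference start of the alignment
#' @return integer matrix with columns `start`, `end` (0-based half-open),
#'   sorted
#' @export
ref_blocks_from_cigar <- function(cigar, ref_start) {
  rl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, pos = ref_start + 1L, ops = .OPS_ALIGN, reduce.ranges = TRUE)[[1L]]
  cbind(start = IRanges::start(rl) - 1L, end = IRanges::end(rl))
}

#' Load SAM/BAM alignment records into a table
#'
#' Reads every record (primary, supplementary, secondary, unmapped) from a
#' BAM file, or from a text SAM file (converted on the fly through
#' `Rsamtools::asBam`). Duplicate-flagged records are kept.
#'
#' @param path path to a `.bam` or `.sam` file
#' @return data.table with columns qname, flag, chrom, strand, pos0
#'   (0-based leftmost), mapq, cigar, record_class
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("cannot read alignment file: ", path, call. = FALSE)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE))
  }
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "strand",
                                        "pos", "mapq", "cigar"))
  res <- Rsamtools::scanBam(bam, param = p)[[1L]]
  dt <- data.table::data.table(
    qname = res$qname, flag = res$flag,
    chrom = as.character(res$rname),
    strand = as.character(res$strand),
    pos0 = res$pos - 1L, mapq = res$mapq, cigar = res$cigar)
  dt[, record_class := classify_record(flag)]
  dt[]
}

#' Derive per-record coordinate geometry from CIGARs
#'
#' Adds read-coordinate spans, aligned lengths, read lengths and reference
#' ends to a record table, and computes each record's reference blocks.
#'
#' @param records data.table as returned by [read_alignments()] (mapped
#'   records only need valid `cigar`/`pos0`)
#' @return object of class `alignment_segments`: list with `segments` (the
#'   input plus seg_id, read_length, M_start, M_end, aligned_len, ref_start,
#'   ref_end) and `blocks` (seg_id, start, end per reference block, 0-based
#'   half-open)
#' @export
compute_segments <- function(records) {
  dt <- data.table::copy(data.table::as.data.table(records))
  dt <- dt[record_class %in% c("primary", "supplementary")]
  dt[, seg_id := seq_len(.N)]
  if (nrow(dt) == 0L) {
    return(structure(list(
      segments = dt[, `:=`(read_length = integer(), M_start = integer(),
                           M_end = integer(), aligned_len = integer(),
                           ref_start = integer(), ref_end = integer())][0],
      blocks = data.table::data.table(seg_id = integer(), start = integer(),
                                      end = integer())),
      class = "alignment_segments"))
  }
  ex <- .explode_cigar(dt$cigar)
  nop <- lengths(ex$ops)
  l <- data.table::data.table(rec = rep(seq_len(nrow(dt)), nop),
                              op = unlist(ex$ops), len = unlist(ex$len))
  l[, is_clip := op %chin% .OPS_CLIP]
  l[, leading := cumsum(!is_clip) == 0L, by = rec]
  fill_by_rec <- function(sub) { # GForce-able grouped sums
    v <- integer(nrow(dt))
    if (nrow(sub)) { s <- sub[, .(v = sum(len)), by = rec]; v[s$rec] <- s$v }
    v
  }
  qlen <- fill_by_rec(l[op %chin% c(.OPS_QUERY, "H")])
  lead <- fill_by_rec(l[(leading)])
  consumed <- fill_by_rec(l[op %chin% c("M", "I", "=", "X")])
  alen <- fill_by_rec(l[op %chin% .OPS_ALIGN])
  dt[, read_length := qlen]
  dt[, `:=`(M_start = ifelse(strand == "-", read_length - lead - consumed, lead),
            M_end   = ifelse(strand == "-", read_length - lead, lead + consumed))]
  dt[, aligned_len := alen]
  dt[, ref_start := pos0]
  rl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    dt$cigar, pos = dt$pos0 + 1L, ops = .OPS_ALIGN, reduce.ranges = TRUE)
  nb <- S4Vectors::elementNROWS(rl)
  flat <- unlist(rl, use.names = FALSE)
  blocks <- data.table::data.table(
    seg_id = rep(dt$seg_id, nb),
    start = IRanges::start(flat) - 1L, end = IRanges::end(flat))
  dt[, ref_end := blocks[, max(end), by = seg_id][match(dt$seg_id, seg_id), V1]]
  structure(list(segments = dt, blocks = blocks), class = "alignment_segments")
}

#' @export
print.alignment_segments <- function(x, ...) {
  cat(sprintf("alignment_segments: %d segments from %d reads\n",
              nrow(x$segments), length(unique(x$segments$qname))))
  invisible(x)
}

#' Group alignment segments by read and keep multi-segment reads
#'
#' Drops unmapped and secondary records, checks that all records of a read
#' imply the same original read length (supplementary records may hard-clip,
#' so clips are counted), discards inconsistent reads with a warning, and
#' keeps only reads with at least two remaining segments — a read aligned in
#' one piece cannot support a fusion. Grouping is order-independent: input
#' record order never affects the result.
#'
#' @param segs an `alignment_segments` object from [compute_segments()], or
#'   a raw record table (which is passed through [compute_segments()] first)
#' @param min_mapq drop segments with MAPQ below this (default 0 = keep all)
#' @return an `alignment_segments` object restricted to multi-segment
#'   groups, segments sorted by (qname, M_start)
#' @export
group_by_read <- function(segs, min_mapq = 0) {
  if (!inherits(segs, "alignment_segments")) segs <- compute_segments(segs)
  dt <- segs$segments
  if (min_mapq > 0) dt <- dt[is.na(mapq) | mapq >= min_mapq]
  dt <- data.table::copy(dt)
  dt[, rl_ok := data.table::uniqueN(read_length) == 1L, by = qname]
  if (!all(dt$rl_ok)) {
    warning("dropping ", data.table::uniqueN(dt[!(rl_ok), qname]),
            " read group(s) with inconsistent CIGAR-implied read lengths",
            call. = FALSE)
    dt <- dt[(rl_ok)]
  }
  dt[, rl_ok := NULL]
  dt[, n_seg := .N, by = qname]
  dt <- dt[n_seg >= 2L][, n_seg := NULL]
  # sort keys beyond M_start make the order independent of input order
  data.table::setorder(dt, qname, M_start, M_end, chrom, pos0, flag)
  structure(list(segments = dt, blocks = segs$blocks[seg_id %in% dt$seg_id]),
            class = "alignment_segments")
}
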
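# Fusion detection proper: per-segment gene assignment, candidate gene-pair
# formation under the read-gap and overlapping-gene rules, overlapping-window
# breakpoint voting, breakpoint averaging and support ranking.

#' Detection parameters
#'
#' Bundles the tunable thresholds of the detector with their defaults.
#'
#' @param min_map_len minimum aligned (M/=/X) length of a segment, bp
#' @param min_exon_overlap minimum exonic overlap between a segment's
#'   reference blocks and some transcript of a gene, bp
#' @param bin_size window width `w` in bp for breakpoint voting; adjacent
#'   windows overlap by `w/2`, so a tight breakpoint cluster is never split
#'   across a window boundary; must be even and >= 2
#' @param gap_max maximum absolute read-coordinate gap/overlap between the
#'   two segments at the junction, bp
#' @param min_support minimum number of supporting reads in the winning
#'   window pair for a candidate to be reported
#' @param include_pseudogenes allow pseudogene partners (default `FALSE`)
#' @param breakpoints_out number of window pairs (breakpoints) reported per
#'   gene pair
#' @param min_mapq minimum MAPQ per segment (default 0: no filter)
#' @return a list of class `detection_params`
#' @export
detection_params <- function(min_map_len = 100, min_exon_overlap = 100,
                             bin_size = 50, gap_max = 20, min_support = 2,
                             include_pseudogenes = FALSE, breakpoints_out = 1,
                             min_mapq = 0) {
  stopifnot_scalar_num(min_map_len, "min_map_len", 0)
  stopifnot_scalar_num(min_exon_overlap, "min_exon_overlap", 0)
  stopifnot_scalar_num(bin_size, "bin_size", 2)
  stopifnot_scalar_num(gap_max, "gap_max", 0)
  stopifnot_scalar_num(min_support, "min_support", 1)
  stopifnot_scalar_num(breakpoints_out, "breakpoints_out", 1)
  if (bin_size %% 2 != 0) stop("'bin_size' must be even", call. = FALSE)
  structure(list(min_map_len = as.integer(min_map_len),
                 min_exon_overlap = as.integer(min_exon_overlap),
                 bin_size = as.integer(bin_size),
                 gap_max = as.integer(gap_max),
                 min_support = as.integer(min_support),
                 include_pseudogenes = isTRUE(include_pseudogenes),
                 breakpoints_out = as.integer(breakpoints_out),
                 min_mapq = as.integer(min_mapq)),
            class = "detection_params")
}

#' Is the read-coordinate gap between two segments acceptable?
#'
#' `M2` is the read-space end of the upstream segment and `M3` the read-space
#' start of the downstream segment (the one with the larger read-space
#' start). A large positive gap means unaligned read sequence between the
#' two pieces; a large negative gap means the pieces overlap on the read —
#' either pattern is inconsistent with a clean fusion junction.
#'
#' @param M2,M3 read coordinates (vectors recycle)
#' @param gap_max threshold in bp (default 20)
#' @return logical: `-gap_max <= M3 - M2 <= gap_max`
#' @export
gap_ok <- function(M2, M3, gap_max = 20) {
  d <- M3 - M2
  d >= -gap_max & d <= gap_max
}

#' Reference coordinate of a segment's junction side
#'
#' Maps the junction-side read coordinate of a segment to the genome: the
#' upstream segment contributes its read-space *end* (`side = "read_end"`),
#' the downstream segment its read-space *start* (`side = "read_start"`).
#' Which genomic end of the alignment that is depends on the mapping strand.
#' Positions are reported 1-based at the terminal aligned base.
#'
#' @param segment one-row data.frame/list with `ref_start`, `ref_end`
#'   (0-based half-open) and `strand`
#' @param side `"read_end"` or `"read_start"`
#' @return integer genomic coordinate (1-based)
#' @export
junction_coordinate <- function(segment, side = c("read_end", "read_start")) {
  side <- match.arg(side)
  .junction_coord(segment$ref_start, segment$ref_end, segment$strand, side)
}

# vectorized core; returns 1-based positions
.junction_coord <- function(ref_start, ref_end, strand, side) {
  if (side == "read_end") {
    ifelse(strand == "-", ref_start + 1L, ref_end)
  } else {
    ifelse(strand == "-", ref_end, ref_start + 1L)
  }
}

#' Assign genes to one alignment segment
#'
#' A segment is associated with every gene for which the exonic overlap of
#' its reference blocks with some transcript reaches
#' `params$min_exon_overlap`, provided the segment's aligned length reaches
#' `params$min_map_len`. Pseudogenes are excluded unless
#' `params$include_pseudogenes`.
#'
#' @param segment one-row segment (list/data.frame with `chrom`,
#'   `aligned_len`) plus `blocks`, a 2-column matrix of its 0-based
#'   half-open reference blocks
#' @param blocks reference blocks of the segment
#' @param annotation a `gene_annotation`
#' @param params a `detection_params`
#' @return data.table (gene_id, overlap_bp) sorted by overlap descending,
#'   ties by gene_id; zero rows when the segment fails the filters
#' @export
assign_genes <- function(segment, blocks, annotation, params = detection_params()) {
  empty <- data.table::data.table(gene_id = character(), overlap_bp = integer())
  if (segment$aligned_len < params$min_map_len) return(empty)
  g <- annotation$genes
  cand <- g[g$chrom == segment$chrom]
  if (!params$include_pseudogenes)
    cand <- cand[!grepl("pseudogene", cand$biotype %||% "", ignore.case = TRUE) |
                   is.na(cand$biotype)]
  if (nrow(cand) == 0L) return(empty)
  ov <- vapply(cand$gene_id, function(gid)
    exon_overlap_bp(annotation, gid, blocks), integer(1L))
  hits <- data.table::data.table(gene_id = cand$gene_id, overlap_bp = ov)
  hits <- hits[overlap_bp >= params$min_exon_overlap]
  data.table::setorder(hits, -overlap_bp, gene_id)
  hits[]
}

# Bulk gene assignment: top hit per segment over all segments at once.
# Overlap is accumulated per (segment, transcript) then maximized per
# (segment, gene); ties broken by gene_id so output is deterministic.
.assign_genes_bulk <- function(segs, annotation, params) {
  empty <- data.table::data.table(seg_id = integer(), gene_id = character(),
                                  overlap_bp = integer())
  dt <- segs$segments
  blocks <- segs$blocks
  if (nrow(blocks) == 0L || length(annotation$exon_gr) == 0L) return(empty)
  bgr <- GenomicRanges::GRanges(
    dt$chrom[match(blocks$seg_id, dt$seg_id)],
    IRanges::IRanges(blocks$start + 1L, blocks$end))
  hits <- GenomicRanges::findOverlaps(bgr, annotation$exon_gr)
  if (length(hits) == 0L) return(empty)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(bgr)[qi], IRanges::ranges(annotation$exon_gr)[si]))
  odt <- data.table::data.table(
    seg_id = blocks$seg_id[qi],
    transcript_id = annotation$exon_gr$transcript_id[si],
    gene_id = annotation$exon_gr$gene_id[si],
    ov = ov)
  per_tx <- odt[, .(ov = sum(ov)), by = .(seg_id, gene_id, transcript_id)]
  per_gene <- per_tx[, .(overlap_bp = max(ov)), by = .(seg_id, gene_id)]
  if (!params$include_pseudogenes) {
    pseudo <- annotation$genes[grepl("pseudogene", biotype, ignore.case = TRUE),
                               gene_id]
    per_gene <- per_gene[!gene_id %in% pseudo]
  }
  per_gene <- per_gene[overlap_bp >= params$min_exon_overlap]
  # aligned-length filter
  ok_len <- dt[aligned_len >= params$min_map_len, seg_id]
  per_gene <- per_gene[seg_id %in% ok_len]
  data.table::setorder(per_gene, seg_id, -overlap_bp, gene_id)
  per_gene[]
}

#' Fusion supports from multi-segment read groups
#'
#' Sorts each read's segments by read-coordinate start and tests every
#' *consecutive* segment pair: both segments must have a gene assignment,
#' the top-overlap genes must differ, the gene pair must not overlap on the
#' genome, and the read-coordinate gap must satisfy [gap_ok()]. Each passing
#' pair yields one support with junction genomic coordinates from
#' [junction_coordinate()]. A read contributes at most one support to a
#' given gene pair.
#'
#' @param segs grouped `alignment_segments` from [group_by_read()]
#' @param annotation a `gene_annotation`
#' @param params a `detection_params`
#' @param counts optional environment collecting per-stage filter counts
#' @return data.table with one row per support: qname, gene_up, gene_down
#'   (5' and 3' gene in read orientation), pair (canonical key),
#'   junction_up, junction_down (1-based genomic), chrom_up, chrom_down,
#'   overlap_up, overlap_down
#' @export
candidate_supports <- function(segs, annotation, params = detection_params(),
                               counts = NULL) {
  empty <- data.table::data.table(
    qname = character(), gene_up = character(), gene_down = character(),
    pair = character(), chrom_up = character(), chrom_down = character(),
    junction_up = integer(), junction_down = integer(),
    overlap_up = integer(), overlap_down = integer())
  dt <- segs$segments
  if (nrow(dt) == 0L) return(empty)
  hits <- .assign_genes_bulk(segs, annotation, params)
  top <- hits[!duplicated(seg_id)] # sorted: top overlap first, tie gene_id

  dt <- data.table::copy(dt)
  data.table::setorder(dt, qname, M_start, M_end, chrom, pos0, flag)
  dt[, c("gene_id", "overlap_bp") :=
       top[match(dt$seg_id, top$seg_id), .(gene_id, overlap_bp)]]

  # consecutive pairs within each read (rows i, i+1 sharing qname)
  i_up <- which(dt$qname == data.table::shift(dt$qname, -1L))
  up <- dt[i_up]; dn <- dt[i_up + 1L]
  pairs <- data.table::data.table(
    qname = up$qname,
    gene_up = up$gene_id, gene_dn = dn$gene_id,
    chrom_up = up$chrom, chrom_dn = dn$chrom,
    M2 = up$M_end, M3 = dn$M_start,
    ref_start_up = up$ref_start, ref_end_up = up$ref_end, strand_up = up$strand,
    ref_start_dn = dn$ref_start, ref_end_dn = dn$ref_end, strand_dn = dn$strand,
    overlap_up = up$overlap_bp, overlap_dn = dn$overlap_bp)

  n0 <- nrow(pairs)
  pairs <- pairs[!is.na(gene_up) & !is.na(gene_dn)]
  n_assigned <- nrow(pairs)
  pairs <- pairs[gene_up != gene_dn]
  n_distinct <- nrow(pairs)
  pairs <- pairs[gap_ok(M2, M3, params$gap_max)]
  n_gap <- nrow(pairs)
  if (nrow(pairs)) {
    g <- annotation$genes
    iu <- match(pairs$gene_up, g$gene_id); idn <- match(pairs$gene_dn, g$gene_id)
    ovl <- spans_overlap(g$chrom[iu], g$start[iu], g$end[iu],
                         g$chrom[idn], g$start[idn], g$end[idn])
    if (any(ovl))
      lf_msg("rejected ", sum(ovl), " segment pair(s) joining overlapping ",
             "gene spans (need manual review)", verbose = !is.null(counts))
    pairs <- pairs[!ovl]
  }
  if (!is.null(counts)) {
    counts$pairs_total <- (counts$pairs_total %||% 0L) + n0
    counts$pairs_unassigned <- (counts$pairs_unassigned %||% 0L) + (n0 - n_assigned)
    counts$pairs_same_gene <- (counts$pairs_same_gene %||% 0L) + (n_assigned - n_distinct)
    counts$pairs_bad_gap <- (counts$pairs_bad_gap %||% 0L) + (n_distinct - n_gap)
    counts$pairs_overlapping_genes <- (counts$pairs_overlapping_genes %||% 0L) +
      (n_gap - nrow(pairs))
  }
  if (nrow(pairs) == 0L) return(empty)

  pairs[, junction_up := .junction_coord(ref_start_up, ref_end_up, strand_up,
                                         "read_end")]
  pairs[, junction_down := .junction_coord(ref_start_dn, ref_end_dn, strand_dn,
                                           "read_start")]
  pairs[, pair := pair_key(gene_up, gene_dn)]
  # one support per read per gene pair (first consecutive passing pair wins)
  pairs <- unique(pairs, by = c("qname", "pair"))
  out <- pairs[, .(qname, gene_up, gene_down = gene_dn, pair,
                   chrom_up, chrom_down = chrom_dn,
                   junction_up, junction_down,
                   overlap_up, overlap_down = overlap_dn)]
  data.table::setorder(out, pair, qname)
  out[]
}

# window indices (0-based) containing a genomic position within a gene:
# windows W_k = [S + k*w/2, S + k*w/2 + w), anchored at the gene span start.
# Every interior position lies in exactly two windows; offsets < w/2 only in
# window 0. Junctions outside the span are clamped to the terminal window.
.window_indices <- function(junction1, gene_start0, gene_end0, w) {
  h <- w %/% 2L
  off <- (junction1 - 1L) - gene_start0
  span <- gene_end0 - gene_start0
  kmax <- max((span - 1L) %/% h, 0L)
  if (off < 0L || off >= span) {
    warning("junction outside gene span; clamped to terminal window",
            call. = FALSE)
    off <- min(max(off, 0L), span - 1L)
  }
  k2 <- min(off %/% h, kmax)
  unique(pmax(c(k2 - 1L, k2), 0L))
}

#' Bin the supports of one gene pair into overlapping window pairs
#'
#' Junction positions in each gene are discretized into windows of `w` bp
#' anchored at the gene's span start, with adjacent windows overlapping by
#' `w/2` bp; a junction therefore falls into up to two windows per gene, and
#' one support can populate up to four window pairs. Counts are
#' per-window-pair (not partitioned), which is what lets a tight cluster
#' always land intact in at least one window.
#'
#' @param supports data.table of supports for a single canonical gene pair
#'   (as produced by [candidate_supports()])
#' @param annotation a `gene_annotation`
#' @param w window size in bp (even)
#' @return data.table: window_a, window_b, n_support, support_idx
#'   (list of row indices into `supports`); genes a/b are the canonical
#'   (lexicographic) orientation of the pair
#' @export
bin_window_pairs <- function(supports, annotation, w = 50) {
  stopifnot(nrow(supports) >= 1L)
  stopifnot(data.table::uniqueN(supports$pair) == 1L)
  genes <- sort(c(supports$gene_up[1L], supports$gene_down[1L]))
  g <- annotation$genes
  ga <- g[match(genes[1L], g$gene_id)]; gb <- g[match(genes[2L], g$gene_id)]
  # junction belonging to gene a / gene b for each support
  ja <- ifelse(supports$gene_up == genes[1L],
               supports$junction_up, supports$junction_down)
  jb <- ifelse(supports$gene_up == genes[2L],
               supports$junction_up, supports$junction_down)
  wa <- .window_indices_vec(ja, ga$start, ga$end, w) # lo/hi per support
  wb <- .window_indices_vec(jb, gb$start, gb$end, w)
  n <- nrow(supports)
  memb <- data.table::data.table(
    support_idx = rep(seq_len(n), 4L),
    window_a = c(wa$lo, wa$lo, wa$hi, wa$hi),
    window_b = c(wb$lo, wb$hi, wb$lo, wb$hi))
  memb <- unique(memb, by = c("support_idx", "window_a", "window_b"))
  out <- memb[, .(n_support = .N, support_idx = list(support_idx)),
              by = .(window_a, window_b)]
  data.table::setorder(out, -n_support, window_a, window_b)
  out[]
}

# vectorized window membership: each junction lies in windows lo..hi
# (hi = floor(offset / (w/2)) clamped to the span, lo = hi - 1 when valid)
.window_indices_vec <- function(junction1, gene_start0, gene_end0, w) {
  h <- w %/% 2L
  off <- (junction1 - 1L) - gene_start0
  span <- gene_end0 - gene_start0
  kmax <- max((span - 1L) %/% h, 0L)
  out_of_span <- off < 0L | off >= span
  if (any(out_of_span)) {
    warning(sum(out_of_span), " junction(s) outside gene span; clamped to ",
            "terminal window", call. = FALSE)
    off <- pmin(pmax(off, 0L), span - 1L)
  }
  hi <- pmin(off %/% h, kmax)
  list(lo = pmax(hi - 1L, 0L), hi = hi)
}

#' Select winning window pairs and average breakpoints
#'
#' Ranks window pairs by support count (ties by ascending window indices)
#' and, for each of the top `breakpoints_out` pairs, reports the arithmetic
#' mean of the member junction coordinates in each gene, rounded half-up to
#' an integer genomic position.
#'
#' @param window_pairs output of [bin_window_pairs()]
#' @param supports the same support table the windows were built from
#' @param genes character(2): canonical gene ids (a, b)
#' @param breakpoints_out how many window pairs to report
#' @return data.table: window_a, window_b, n_support, breakpoint_a,
#'   breakpoint_b (1-based genomic), ordered best-first
#' @export
select_breakpoints <- function(window_pairs, supports, genes,
                               breakpoints_out = 1) {
  stopifnot(nrow(window_pairs) >= 1L)
  ja <- ifelse(supports$gene_up == genes[1L],
               supports$junction_up, supports$junction_down)
  jb <- ifelse(supports$gene_up == genes[2L],
               supports$junction_up, supports$junction_down)
  top <- utils::head(window_pairs, breakpoints_out)
  top[, breakpoint_a := vapply(support_idx, function(i)
    round_half_up(mean(ja[i])), numeric(1L))]
  top[, breakpoint_b := vapply(support_idx, function(i)
    round_half_up(mean(jb[i])), numeric(1L))]
  top[, .(window_a, window_b, n_support, breakpoint_a, breakpoint_b)]
}

#' Rank fusion candidates by supporting reads
#'
#' Removes candidates whose winning-window support count is below
#' `min_support` and sorts the rest by support count descending, ties by
#' gene pair lexicographically, so output order is deterministic.
#'
#' @param candidates data.table with at least `support_count` and `pair`
#' @param min_support minimum supporting reads
#' @return the filtered, ordered data.table
#' @export
rank_candidates <- function(candidates, min_support = 2) {
  out <- candidates[support_count >= min_support]
  data.table::setorder(out, -support_count, pair)
  out[]
}

#' Detect gene fusions from long-read alignments
#'
#' The full detection pipeline: load alignments, drop secondary/unmapped
#' records, group by read and keep reads split into >= 2 segments, assign
#' genes per segment by exonic overlap, form supports from consecutive
#' segment pairs under the gap and overlapping-gene rules, vote breakpoints
#' in overlapping windows per gene pair, and rank candidates by supporting
#' reads.
#'
#' @param alignments path to a SAM/BAM file, or an `alignment_segments`
#'   object
#' @param annotation path to a GTF file, or a `gene_annotation`
#' @param params a `detection_params`
#' @param verbose log per-stage counts via `message()`
#' @return list of class `fusion_result`: `candidates` (ranked data.table:
#'   gene_a, gene_b, support_count, chrom_a, breakpoint_a, chrom_b,
#'   breakpoint_b, reads, pair, extra breakpoints when
#'   `breakpoints_out > 1`), `supports` (per-read evidence), `counts`
#'   (filter-stage tallies), `params`
#' @export
detect_fusions <- function(alignments, annotation,
                           params = detection_params(), verbose = TRUE) {
  if (is.character(annotation))
    annotation <- parse_gtf(annotation,
                            include_pseudogenes = params$include_pseudogenes)
  stopifnot(inherits(annotation, "gene_annotation"))
  if (is.character(alignments)) {
    records <- read_alignments(alignments)
    segs <- compute_segments(records)
    n_records <- nrow(records)
  } else {
    segs <- alignments
    n_records <- nrow(segs$segments)
  }
  stopifnot(inherits(segs, "alignment_segments"))

  counts <- new.env(parent = emptyenv())
  counts$records <- n_records
  counts$segments <- nrow(segs$segments)
  grouped <- group_by_read(segs, min_mapq = params$min_mapq)
  counts$multiseg_reads <- data.table::uniqueN(grouped$segments$qname)
  lf_msg("records: ", counts$records,
         "; primary/supplementary segments: ", counts$segments,
         "; multi-segment reads: ", counts$multiseg_reads, verbose = verbose)

  supports <- candidate_supports(grouped, annotation, params, counts = counts)
  counts$supports <- nrow(supports)
  lf_msg("supports after gene/gap/overlap rules: ", counts$supports,
         " (rejected - unassigned: ", counts$pairs_unassigned %||% 0L,
         ", same gene: ", counts$pairs_same_gene %||% 0L,
         ", bad gap: ", counts$pairs_bad_gap %||% 0L,
         ", overlapping genes: ", counts$pairs_overlapping_genes %||% 0L, ")",
         verbose = verbose)

  cand_rows <- list(); i <- 0L
  for (pk in unique(supports$pair)) {
    sp <- supports[pair == pk]
    genes <- sort(c(sp$gene_up[1L], sp$gene_down[1L]))
    wp <- bin_window_pairs(sp, annotation, w = params$bin_size)
    bp <- select_breakpoints(wp, sp, genes, params$breakpoints_out)
    # reported orientation: majority 5'->3' over supports; tie keeps
    # lexicographic order
    n_fwd <- sum(sp$gene_up == genes[1L])
    flip <- n_fwd < (nrow(sp) - n_fwd)
    ga <- if (flip) genes[2L] else genes[1L]
    gb <- if (flip) genes[1L] else genes[2L]
    g <- annotation$genes
    best <- bp[1L]
    i <- i + 1L
    cand_rows[[i]] <- data.table::data.table(
      gene_a = ga, gene_b = gb, pair = pk,
      support_count = best$n_support,
      chrom_a = g$chrom[match(ga, g$gene_id)],
      breakpoint_a = if (flip) best$breakpoint_b else best$breakpoint_a,
      chrom_b = g$chrom[match(gb, g$gene_id)],
      breakpoint_b = if (flip) best$breakpoint_a else best$breakpoint_b,
      reads = paste(sort(unique(sp$qname)), collapse = ","),
      n_reads_total = data.table::uniqueN(sp$qname),
      extra_breakpoints = if (nrow(bp) > 1L) list(bp[-1L]) else list(NULL))
  }
  candidates <- if (i > 0L) data.table::rbindlist(cand_rows) else
    data.table::data.table(gene_a = character(), gene_b = character(),
                           pair = character(), support_count = integer(),
                           chrom_a = character(), breakpoint_a = numeric(),
                           chrom_b = character(), breakpoint_b = numeric(),
                           reads = character(), n_reads_total = integer(),
                           extra_breakpoints = list())
  candidates <- rank_candidates(candidates, params$min_support)
  lf_msg("candidates with >= ", params$min_support, " supporting reads: ",
         nrow(candidates), verbose = verbose)
  structure(list(candidates = candidates, supports = supports,
                 counts = as.list(counts), params = params),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("fusion_result: %d candidate(s) from %d support(s)\n",
              nrow(x$candidates), nrow(x$supports)))
  if (nrow(x$candidates))
    print(x$candidates[, .(gene_a, gene_b, support_count,
                           chrom_a, breakpoint_a, chrom_b, breakpoint_b)])
  invisible(x)
}

#' Write a ranked fusion report as TSV
#'
#' Columns: gene_a, gene_b, support_count, chrom_a, breakpoint_a, chrom_b,
#' breakpoint_b, reads (comma-separated supporting read names). Coordinates
#' are 1-based. An empty candidate set writes a header-only file.
#'
#' @param result a `fusion_result` (or its `candidates` table)
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_fusion_report <- function(result, path) {
  cand <- if (inherits(result, "fusion_result")) result$candidates else result
  out <- cand[, .(gene_a, gene_b, support_count, chrom_a, breakpoint_a,
                  chrom_b, breakpoint_b, reads)]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
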
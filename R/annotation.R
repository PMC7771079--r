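# GTF-derived gene/transcript/exon model and gene-level eligibility rules.
#
# Internal coordinate convention: 0-based half-open everywhere. GTF input is
# 1-based inclusive; the conversion (start - 1) happens exactly once, at
# parse time, and is undone only when writing GTF or user-facing reports.

#' Parse a GTF annotation into an indexed gene model
#'
#' Reads a (possibly gzip-compressed) GTF file and builds the gene universe
#' used for fusion detection: genes, their transcripts and exon intervals,
#' together with interval indices over gene spans and exons. Only `exon`
#' features are required; `gene`/`transcript` lines, when present, contribute
#' names and biotypes but spans are always recomputed from exons.
#'
#' Genes whose biotype contains the substring `"pseudogene"`
#' (case-insensitive, read from `gene_biotype`, `gene_type` or
#' `transcript_biotype` attributes) are excluded unless
#' `include_pseudogenes = TRUE`; pseudogene alignments are a known source of
#' spurious fusion calls.
#'
#' @param path path to a GTF file (plain or gzipped)
#' @param include_pseudogenes keep genes with a pseudogene biotype
#'   (default `FALSE`)
#' @return an object of class `gene_annotation`: a list with data.tables
#'   `genes` (gene_id, gene_name, chrom, strand, start, end, biotype;
#'   coordinates 0-based half-open), `transcripts` (transcript_id, gene_id)
#'   and `exons` (chrom, start, end, strand, transcript_id, gene_id), plus a
#'   `GRanges` exon index in `exon_gr` and gene-span index in `gene_gr`
#' @export
parse_gtf <- function(path, include_pseudogenes = FALSE) {
  if (!file.exists(path)) stop("cannot read GTF file: ", path, call. = FALSE)
  con <- gzfile(path, "rt") # gzfile transparently reads plain text too
  on.exit(close(con), add = TRUE)
  lines <- readLines(con, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) return(.build_annotation(.empty_exon_table()))

  fields <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  if (length(fields) < 9L)
    stop("malformed GTF: fewer than 9 tab-separated columns", call. = FALSE)
  dt <- data.table::data.table(
    chrom = fields[[1]], feature = fields[[3]],
    start1 = suppressWarnings(as.integer(fields[[4]])),
    end1 = suppressWarnings(as.integer(fields[[5]])),
    strand = fields[[7]], attrs = fields[[9]]
  )

  dt[, gene_id := gtf_attr(attrs, "gene_id")]
  dt[, transcript_id := gtf_attr(attrs, "transcript_id")]
  dt[, gene_name := gtf_attr(attrs, "gene_name")]
  dt[, biotype := data.table::fcoalesce(
    gtf_attr(attrs, "gene_biotype"),
    gtf_attr(attrs, "gene_type"),
    gtf_attr(attrs, "transcript_biotype"))]

  bad_coord <- is.na(dt$start1) | is.na(dt$end1) | dt$end1 < dt$start1
  if (any(bad_coord)) {
    warning(sum(bad_coord), " GTF line(s) rejected: end < start or ",
            "non-numeric coordinates", call. = FALSE)
    dt <- dt[!bad_coord]
  }
  no_gene <- is.na(dt$gene_id)
  if (any(no_gene)) {
    warning(sum(no_gene), " GTF line(s) rejected: missing gene_id attribute",
            call. = FALSE)
    dt <- dt[!no_gene]
  }

  # biotype / gene_name can live on any feature line of the gene
  meta <- dt[, .(gene_name = first_non_na(gene_name),
                 biotype = first_non_na(biotype)), by = gene_id]

  ex <- dt[feature == "exon" & !is.na(transcript_id)]
  ex <- ex[, .(chrom, start = start1 - 1L, end = end1, strand,
               transcript_id, gene_id)]

  if (!include_pseudogenes) {
    pseudo <- meta[grepl("pseudogene", biotype, ignore.case = TRUE), gene_id]
    ex <- ex[!gene_id %in% pseudo]
  }
  .build_annotation(ex, meta)
}

# vectorized GTF attribute extraction; tolerates `key "value";` and
# `key value;` dialects
gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexpr(paste0('(^|;)\\s*', key, '\\s+"?[^";]+'),
                                 attrs, perl = TRUE))
  out <- rep(NA_character_, length(attrs))
  hit <- attr(regexpr(paste0('(^|;)\\s*', key, '\\s+"?[^";]+'), attrs,
                      perl = TRUE), "match.length") > 0
  out[hit] <- sub(paste0('(^|;)\\s*', key, '\\s+"?'), "", m)
  out
}

first_non_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x)) x[[1L]] else NA_character_
}

.empty_exon_table <- function() {
  data.table::data.table(chrom = character(), start = integer(),
                         end = integer(), strand = character(),
                         transcript_id = character(), gene_id = character())
}

.build_annotation <- function(ex, meta = NULL) {
  data.table::setorder(ex, gene_id, transcript_id, start)
  tx <- unique(ex[, .(transcript_id, gene_id, chrom)])
  genes <- if (nrow(ex)) {
    ex[, .(chrom = chrom[1L], strand = strand[1L],
           start = min(start), end = max(end)), by = gene_id]
  } else {
    data.table::data.table(gene_id = character(), chrom = character(),
                           strand = character(), start = integer(),
                           end = integer())
  }
  if (!is.null(meta) && nrow(meta)) {
    genes <- merge(genes, meta, by = "gene_id", all.x = TRUE, sort = FALSE)
  } else {
    genes[, `:=`(gene_name = NA_character_, biotype = NA_character_)]
  }
  genes[is.na(gene_name), gene_name := gene_id]
  data.table::setorder(genes, gene_id)
  data.table::setcolorder(genes, c("gene_id", "gene_name", "chrom", "strand",
                                   "start", "end", "biotype"))

  if (nrow(ex)) {
    exon_gr <- GenomicRanges::GRanges(
      ex$chrom, IRanges::IRanges(ex$start + 1L, ex$end),
      transcript_id = ex$transcript_id, gene_id = ex$gene_id)
    gene_gr <- GenomicRanges::GRanges(
      genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end),
      gene_id = genes$gene_id)
  } else {
    exon_gr <- GenomicRanges::GRanges()
    gene_gr <- GenomicRanges::GRanges()
  }
  structure(list(genes = genes, transcripts = tx[, .(transcript_id, gene_id)],
                 exons = ex, exon_gr = exon_gr, gene_gr = gene_gr),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene_annotation: %d genes, %d transcripts, %d exons on %d sequence(s)\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons),
              length(unique(x$genes$chrom))))
  invisible(x)
}

#' Write a gene annotation back to GTF
#'
#' Emits gene, transcript and exon features with 1-based inclusive
#' coordinates and quoted attributes. Parsing the output with [parse_gtf()]
#' reproduces the gene spans and exon lists exactly (round-trip property).
#'
#' @param annotation a `gene_annotation`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gtf <- function(annotation, path) {
  stopifnot(inherits(annotation, "gene_annotation"))
  g <- annotation$genes
  ex <- annotation$exons
  attr_g <- sprintf('gene_id "%s"; gene_name "%s"; gene_biotype "%s";',
                    g$gene_id, g$gene_name,
                    ifelse(is.na(g$biotype), "protein_coding", g$biotype))
  bio <- g$biotype[match(ex$gene_id, g$gene_id)]
  attr_e <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                    ex$gene_id, ex$transcript_id,
                    ifelse(is.na(bio), "protein_coding", bio))
  lines <- c(
    sprintf("%s\tlongfusr\tgene\t%d\t%d\t.\t%s\t.\t%s",
            g$chrom, g$start + 1L, g$end, g$strand, attr_g),
    sprintf("%s\tlongfusr\texon\t%d\t%d\t.\t%s\t.\t%s",
            ex$chrom, ex$start + 1L, ex$end, ex$strand, attr_e))
  writeLines(lines, path)
  invisible(path)
}

#' Do two genes overlap on the genome?
#'
#' Implements the overlapping-gene exclusion: with gene labels chosen so that
#' the start of gene 1 precedes the start of gene 2 (S1 <= S2), the pair is
#' called overlapping when E1 - S2 > 0 in 1-based inclusive coordinates
#' (abutting spans that share a single base are not significant overlap,
#' since then E1 = S2). Gene pairs that
#' overlap are never reported as fusion candidates (read-through and nested
#' loci masquerade as fusions); genes on different chromosomes never overlap.
#'
#' @param annotation a `gene_annotation`
#' @param gene_a,gene_b gene ids present in `annotation`
#' @return logical scalar
#' @export
genes_overlap <- function(annotation, gene_a, gene_b) {
  g <- annotation$genes
  a <- g[gene_id == gene_a]
  b <- g[gene_id == gene_b]
  if (nrow(a) != 1L || nrow(b) != 1L)
    stop("unknown gene id(s): ", gene_a, ", ", gene_b, call. = FALSE)
  spans_overlap(a$chrom, a$start, a$end, b$chrom, b$start, b$end)
}

# vectorized core used at support-formation time. Coordinates are 0-based
# half-open; with gene 1 the earlier-starting gene, the 1-based rule
# E1 - S2 > 0 becomes end1 - start2 > 1 (spans sharing exactly one base do
# not count as significant overlap).
spans_overlap <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  first_end <- ifelse(start_a <= start_b, end_a, end_b)
  second_start <- pmax(start_a, start_b)
  chrom_a == chrom_b & (first_end - second_start) > 1L
}

#' Exonic overlap between aligned reference blocks and a gene
#'
#' Computes, for each transcript of the gene, the total length (bp) of the
#' intersection between the alignment's reference blocks and that
#' transcript's exons, and returns the maximum over transcripts. The
#' per-transcript (rather than unioned-across-transcripts) accounting matches
#' the rule that an alignment is associated with a *transcript* when the
#' overlap exceeds the threshold.
#'
#' @param annotation a `gene_annotation`
#' @param gene_id gene id present in `annotation`
#' @param blocks two-column matrix (or data.frame) of 0-based half-open
#'   reference intervals, sorted and non-overlapping, on the gene's chromosome
#' @return integer, maximum per-transcript overlap in bp (0 when no exon is
#'   touched)
#' @export
exon_overlap_bp <- function(annotation, gene_id, blocks) {
  sel <- annotation$exons$gene_id == gene_id
  ex <- annotation$exons[sel]
  if (nrow(ex) == 0L) stop("unknown gene id: ", gene_id, call. = FALSE)
  blocks <- as.matrix(blocks)
  if (nrow(blocks) == 0L) return(0L)
  bir <- IRanges::IRanges(blocks[, 1L] + 1L, blocks[, 2L])
  per_tx <- vapply(split(seq_len(nrow(ex)), ex$transcript_id), function(i) {
    eir <- IRanges::IRanges(ex$start[i] + 1L, ex$end[i])
    sum(IRanges::width(IRanges::intersect(bir, eir)))
  }, integer(1L))
  if (length(per_tx)) max(per_tx) else 0L
}
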
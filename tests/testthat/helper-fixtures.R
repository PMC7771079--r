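# Fixtures are built in code: a hand-written two-gene GTF, annotation
# builders, and alignment-segment constructors used across test files.

# two-gene toy GTF: gene A (chrT, +) with transcripts A.t1 (3 exons) and
# A.t2 (2 exons); gene B (chrT, -) with one transcript of 2 exons.
# 1-based inclusive coordinates as in real GTF.
toy_gtf_lines <- function(quote_attrs = TRUE) {
  q <- function(x) if (quote_attrs) sprintf('"%s"', x) else x
  att <- function(g, t = NULL, bio = "protein_coding") {
    s <- sprintf("gene_id %s; gene_biotype %s;", q(g), q(bio))
    if (!is.null(t)) s <- sprintf("gene_id %s; transcript_id %s; gene_biotype %s;",
                                  q(g), q(t), q(bio))
    s
  }
  c(
    "#!genome-build toy",
    sprintf("chrT\ttest\tgene\t101\t1300\t.\t+\t.\t%s", att("A")),
    sprintf("chrT\ttest\texon\t101\t300\t.\t+\t.\t%s", att("A", "A.t1")),
    sprintf("chrT\ttest\texon\t501\t700\t.\t+\t.\t%s", att("A", "A.t1")),
    sprintf("chrT\ttest\texon\t1101\t1300\t.\t+\t.\t%s", att("A", "A.t1")),
    sprintf("chrT\ttest\texon\t101\t300\t.\t+\t.\t%s", att("A", "A.t2")),
    sprintf("chrT\ttest\texon\t1101\t1300\t.\t+\t.\t%s", att("A", "A.t2")),
    sprintf("chrT\ttest\texon\t2001\t2400\t.\t-\t.\t%s", att("B", "B.t1")),
    sprintf("chrT\ttest\texon\t2801\t3000\t.\t-\t.\t%s", att("B", "B.t1")))
}

toy_gtf_file <- function(..., gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".gtf.gz" else ".gtf")
  con <- if (gz) gzfile(path, "wt") else file(path, "wt")
  writeLines(toy_gtf_lines(...), con)
  close(con)
  path
}

# annotation straight from an exon table (0-based half-open coordinates)
ann_from_exons <- function(df, biotype = NULL) {
  ex <- data.table::as.data.table(df)
  meta <- NULL
  if (!is.null(biotype))
    meta <- data.table::data.table(gene_id = names(biotype),
                                   gene_name = names(biotype),
                                   biotype = unname(biotype))
  longfusr:::.build_annotation(ex, meta)
}

# simple multi-gene annotation on one chromosome: each gene a single
# transcript with `n_ex` exons of width `exw` separated by `intw` introns
grid_annotation <- function(n_genes = 4, n_ex = 3, exw = 200, intw = 300,
                            gap = 1000, chrom = "chrT", start0 = 0) {
  rows <- list()
  cur <- start0
  for (i in seq_len(n_genes)) {
    g <- sprintf("g%02d", i)
    starts <- cur + cumsum(c(0, rep(exw + intw, n_ex - 1)))
    rows[[i]] <- data.table::data.table(
      chrom = chrom, start = starts, end = starts + exw,
      strand = if (i %% 2 == 0) "-" else "+",
      transcript_id = paste0(g, ".t1"), gene_id = g)
    cur <- max(rows[[i]]$end) + gap
  }
  ann_from_exons(data.table::rbindlist(rows))
}

# construct an alignment_segments object directly from a record sketch:
# data.frame(qname, flag, chrom, strand, pos0, cigar [, mapq])
segs_from_records <- function(df) {
  dt <- data.table::as.data.table(df)
  if (!"mapq" %in% names(dt)) dt[, mapq := 60L]
  dt[, record_class := classify_record(flag)]
  compute_segments(dt)
}

# write records as a SAM file (single @SQ per chrom, dummy lengths)
sam_from_records <- function(df, seqlen = 1e6) {
  dt <- data.table::as.data.table(df)
  chroms <- unique(dt$chrom)
  qlen <- vapply(dt$cigar, function(cg) {
    ex <- longfusr:::.explode_cigar(cg)
    sum(ex$len[[1]][ex$ops[[1]] %in% c("M", "I", "S", "=", "X")])
  }, integer(1))
  seq <- vapply(qlen, function(k) strrep("A", k), character(1))
  lines <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", chroms, as.integer(seqlen)),
             sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                     dt$qname, dt$flag, dt$chrom, dt$pos0 + 1L,
                     if ("mapq" %in% names(dt)) dt$mapq else 60L,
                     dt$cigar, seq))
  path <- tempfile(fileext = ".sam")
  writeLines(lines, path)
  path
}

# small simulated dataset cached per test run (shared by several files)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 11, n_genes = 40, n_fusions = 5,
                        total_reads = 4000, error_free = TRUE)
      cache <<- simulate_fusion_dataset(cfg, tempfile("smallsim"))
    }
    cache
  }
})
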
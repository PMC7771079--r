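test_that("parse_gtf handles empty input and the hand-written toy GTF", {
  empty <- tempfile(fileext = ".gtf")
  writeLines(character(0), empty)
  expect_equal(nrow(parse_gtf(empty)$genes), 0L)

  ann <- parse_gtf(toy_gtf_file())
  expect_s3_class(ann, "gene_annotation")
  expect_equal(nrow(ann$genes), 2L)
  expect_equal(sort(ann$genes$gene_id), c("A", "B"))
  # manual parse of the fixture: A has 2 transcripts (3 + 2 exons), B has 1
  expect_equal(sum(ann$transcripts$gene_id == "A"), 2L)
  expect_equal(sum(ann$exons$transcript_id == "A.t1"), 3L)
  expect_equal(sum(ann$exons$transcript_id == "A.t2"), 2L)
  expect_equal(sum(ann$exons$transcript_id == "B.t1"), 2L)
  # span from exons, 1-based 101..1300 -> 0-based [100, 1300)
  a <- ann$genes[ann$genes$gene_id == "A", ]
  expect_equal(c(a$start, a$end), c(100L, 1300L))
})

test_that("parse_gtf tolerates unquoted attributes and gzip input", {
  ann1 <- parse_gtf(toy_gtf_file(quote_attrs = FALSE))
  expect_equal(nrow(ann1$genes), 2L)
  ann2 <- parse_gtf(toy_gtf_file(gz = TRUE))
  expect_equal(ann2$exons, parse_gtf(toy_gtf_file())$exons)
})

test_that("parse_gtf rejects bad lines with warnings and bad files fatally", {
  path <- tempfile(fileext = ".gtf")
  writeLines(c(toy_gtf_lines(),
               "chrT\ttest\texon\t900\t800\t.\t+\t.\tgene_id \"A\"; transcript_id \"A.t1\";",
               "chrT\ttest\texon\t10\t90\t.\t+\t.\ttranscript_id \"X.t1\";"),
             path)
  expect_warning(expect_warning(ann <- parse_gtf(path), "end < start"),
                 "missing gene_id")
  expect_equal(sum(ann$exons$transcript_id == "A.t1"), 3L) # bad line dropped
  expect_error(parse_gtf(tempfile()), "cannot read")
})

test_that("pseudogenes are excluded by default and kept on request", {
  path <- tempfile(fileext = ".gtf")
  writeLines(c(toy_gtf_lines(),
               paste0("chrT\ttest\texon\t5001\t5400\t.\t+\t.\t",
                      'gene_id "PG"; transcript_id "PG.t1"; ',
                      'gene_biotype "processed_pseudogene";')),
             path)
  expect_false("PG" %in% parse_gtf(path)$genes$gene_id)
  expect_true("PG" %in% parse_gtf(path, include_pseudogenes = TRUE)$genes$gene_id)
})

test_that("write_gtf round-trips gene spans and exon lists", {
  ann <- parse_gtf(toy_gtf_file())
  out <- tempfile(fileext = ".gtf")
  write_gtf(ann, out)
  ann2 <- parse_gtf(out)
  expect_equal(ann2$genes[, .(gene_id, chrom, strand, start, end)],
               ann$genes[, .(gene_id, chrom, strand, start, end)])
  expect_equal(ann2$exons, ann$exons)
})

test_that("parse_gtf agrees with rtracklayer on the toy fixture", {
  skip_if_not_installed("rtracklayer")
  path <- toy_gtf_file()
  ann <- parse_gtf(path)
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  expect_equal(nrow(ann$exons), length(ex))
  o <- order(ex$transcript_id, GenomicRanges::start(ex))
  expect_equal(ann$exons$start, GenomicRanges::start(ex)[o] - 1L)
  expect_equal(ann$exons$end, GenomicRanges::end(ex)[o])
})

test_that("genes_overlap implements the E1 - S2 > 0 span rule", {
  ex <- data.table::data.table(
    chrom = c("c1", "c1", "c1", "c2"),
    start = c(99L, 399L, 499L, 99L), end = c(500L, 900L, 900L, 500L),
    strand = "+",
    transcript_id = c("gi.t", "gj.t", "gk.t", "gl.t"),
    gene_id = c("gi", "gj", "gk", "gl"))
  ann <- ann_from_exons(ex)
  # spans [100,500] and [400,900] 1-based: E1 - S2 = 500 - 400 > 0
  expect_true(genes_overlap(ann, "gi", "gj"))
  # abutting 1-based spans [100,500] and [500,900]: E1 - S2 = 0, so the
  # shared single base does not count as significant overlap
  ex2 <- data.table::data.table(
    chrom = "c1", start = c(99L, 499L), end = c(500L, 900L), strand = "+",
    transcript_id = c("x.t", "y.t"), gene_id = c("x", "y"))
  ann2 <- ann_from_exons(ex2)
  expect_false(genes_overlap(ann2, "x", "y"))
  # same span, different chromosome
  expect_false(genes_overlap(ann, "gi", "gl"))
  expect_error(genes_overlap(ann, "gi", "nope"), "unknown gene")
})

test_that("genes_overlap is symmetric across fixture pairs", {
  ann <- grid_annotation(n_genes = 5)
  ids <- ann$genes$gene_id
  for (i in seq_along(ids)) for (j in seq_along(ids))
    expect_identical(genes_overlap(ann, ids[i], ids[j]),
                     genes_overlap(ann, ids[j], ids[i]))
})

test_that("exon_overlap_bp maximizes per transcript, not over the union", {
  ann <- parse_gtf(toy_gtf_file())
  # blocks equal to A.t1's exons: total 600 bp (identity)
  bl <- as.matrix(ann$exons[ann$exons$transcript_id == "A.t1",
                            c("start", "end")])
  expect_equal(exon_overlap_bp(ann, "A", bl), 600L)
  # 150 bp inside the first exon (shared by both transcripts)
  expect_equal(exon_overlap_bp(ann, "A", cbind(120L, 270L)), 150L)
  # blocks overlapping A.t1 by 240 bp (middle exon 500..700 plus 40 bp of
  # exon 1) but A.t2 by only 40 bp (A.t2 skips the middle exon)
  bl2 <- rbind(c(260L, 300L), c(500L, 700L))
  expect_equal(exon_overlap_bp(ann, "A", bl2),
               oracle_exon_overlap(ann, "A", bl2))
  expect_equal(exon_overlap_bp(ann, "A", bl2), 240L)
  # intronic blocks -> 0
  expect_equal(exon_overlap_bp(ann, "A", cbind(320L, 480L)), 0L)
})

test_that("exon_overlap_bp is bounded by block and exon totals", {
  ann <- grid_annotation(n_genes = 3)
  set.seed(5)
  for (rep in 1:20) {
    g <- sample(ann$genes$gene_id, 1)
    s <- sort(sample(0:4000, 2))
    bl <- cbind(s[1], s[2])
    ov <- exon_overlap_bp(ann, g, bl)
    expect_lte(ov, s[2] - s[1])
    txlen <- max(ann$exons[ann$exons$gene_id == g,
                           sum(end - start), by = transcript_id]$V1)
    expect_lte(ov, txlen)
    expect_equal(ov, oracle_exon_overlap(ann, g, bl))
  }
})

test_that("exon interval index agrees with a brute-force scan", {
  ann <- grid_annotation(n_genes = 6)
  set.seed(9)
  for (rep in 1:15) {
    s <- sort(sample(0:8000, 2))
    q <- GenomicRanges::GRanges("chrT", IRanges::IRanges(s[1] + 1, s[2]))
    idx_hits <- sort(unique(
      ann$exon_gr$gene_id[S4Vectors::subjectHits(
        GenomicRanges::findOverlaps(q, ann$exon_gr))]))
    brute <- sort(unique(ann$exons$gene_id[
      ann$exons$start < s[2] & ann$exons$end > s[1]]))
    expect_equal(idx_hits, brute)
  }
})
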
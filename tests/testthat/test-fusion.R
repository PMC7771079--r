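# grid_annotation() genes (w = exons 200 bp, introns 300 bp, gaps 1000 bp):
# g01 exons [0,200) [500,700) [1000,1200); g02 from 2200; g03 from 4400; ...

test_that("gap_ok accepts exactly the [-gap_max, gap_max] band", {
  expect_false(gap_ok(100, 121, 20))   # M3 - M2 = 21
  expect_false(gap_ok(100, 79, 20))    # M3 - M2 = -21
  expect_true(gap_ok(100, 100, 20))    # abutting
  expect_true(gap_ok(100, 120, 20))
  expect_true(gap_ok(100, 80, 20))
  expect_equal(gap_ok(0, c(-21, -20, 0, 20, 21)),
               c(FALSE, TRUE, TRUE, TRUE, FALSE))
})

test_that("junction_coordinate maps read ends through strand", {
  seg_fwd <- list(ref_start = 1000L, ref_end = 1200L, strand = "+")
  seg_rev <- list(ref_start = 1000L, ref_end = 1200L, strand = "-")
  expect_equal(junction_coordinate(seg_fwd, "read_end"), 1200L)
  expect_equal(junction_coordinate(seg_rev, "read_end"), 1001L)
  expect_equal(junction_coordinate(seg_fwd, "read_start"), 1001L)
  expect_equal(junction_coordinate(seg_rev, "read_start"), 1200L)
})

test_that("assign_genes applies aligned-length and exon-overlap thresholds", {
  ann <- grid_annotation()
  params <- detection_params()
  mk <- function(cigar, pos0) {
    s <- segs_from_records(data.frame(qname = "q", flag = 0L, chrom = "chrT",
                                      strand = "+", pos0 = pos0, cigar = cigar))
    list(seg = as.list(s$segments[1]),
         blocks = as.matrix(s$blocks[, .(start, end)]))
  }
  x <- mk("150M", 0L)                       # 150 bp on g01 exon 1
  hits <- assign_genes(x$seg, x$blocks, ann, params)
  expect_equal(hits$gene_id, "g01")
  expect_equal(hits$overlap_bp, 150L)
  x <- mk("150M", 101L)                     # only 99 exonic bp
  expect_equal(nrow(assign_genes(x$seg, x$blocks, ann, params)), 0L)
  x <- mk("99M", 0L)                        # aligned length below 100
  expect_equal(nrow(assign_genes(x$seg, x$blocks, ann, params)), 0L)
  x <- mk("150M", 250L)                     # intronic
  expect_equal(nrow(assign_genes(x$seg, x$blocks, ann, params)), 0L)
})

two_gene_read <- function(qname = "r1") {
  # 400 bp read: first half on g01 exon 1, second half on g02 exon 1
  data.frame(qname = qname, flag = c(0L, 2048L), chrom = "chrT",
             strand = "+", pos0 = c(0L, 2200L),
             cigar = c("200M200S", "200S200M"))
}

test_that("candidate_supports forms supports from consecutive segments", {
  ann <- grid_annotation()
  g <- group_by_read(segs_from_records(two_gene_read()))
  sp <- candidate_supports(g, ann, detection_params())
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$gene_up, "g01")
  expect_equal(sp$gene_down, "g02")
  expect_equal(sp$junction_up, 200L)     # end of g01 exon 1, 1-based
  expect_equal(sp$junction_down, 2201L)  # start of g02 exon 1, 1-based
  expect_equal(sp$pair, "g01|g02")

  # a bad read-coordinate gap (overlap of 50 bp on the read) kills it
  bad <- two_gene_read()
  bad$cigar <- c("200M200S", "150S250M")  # M3 - M2 = -50
  g2 <- group_by_read(segs_from_records(bad))
  expect_equal(nrow(candidate_supports(g2, ann, detection_params())), 0L)

  # three segments A -> B -> C yield supports A:B and B:C
  tri <- data.frame(qname = "t", flag = c(0L, 2048L, 2048L), chrom = "chrT",
                    strand = "+", pos0 = c(0L, 2200L, 4400L),
                    cigar = c("200M400S", "200S200M200S", "400S200M"))
  sp3 <- candidate_supports(group_by_read(segs_from_records(tri)), ann,
                            detection_params())
  expect_equal(nrow(sp3), 2L)
  expect_setequal(sp3$pair, c("g01|g02", "g02|g03"))
})

test_that("overlapping gene pairs are rejected at support formation", {
  # two genes whose spans overlap (nested exons), plus segments hitting them
  ex <- data.table::data.table(
    chrom = "chrT",
    start = c(0L, 1000L, 300L, 600L), end = c(200L, 1200L, 500L, 800L),
    strand = "+",
    transcript_id = c("ga.t", "ga.t", "gb.t", "gb.t"),
    gene_id = c("ga", "ga", "gb", "gb"))
  ann <- ann_from_exons(ex)
  recs <- data.frame(qname = "r", flag = c(0L, 2048L), chrom = "chrT",
                     strand = "+", pos0 = c(0L, 300L),
                     cigar = c("200M200S", "200S200M"))
  g <- group_by_read(segs_from_records(recs))
  expect_equal(nrow(candidate_supports(g, ann, detection_params())), 0L)
})

test_that("pseudogene partners appear only when requested", {
  ex <- data.table::data.table(
    chrom = "chrT", start = c(0L, 3000L), end = c(200L, 3200L), strand = "+",
    transcript_id = c("gn.t", "ps.t"), gene_id = c("gn", "ps"))
  ann <- ann_from_exons(ex, biotype = c(gn = "protein_coding",
                                        ps = "processed_pseudogene"))
  recs <- data.frame(qname = "r", flag = c(0L, 2048L), chrom = "chrT",
                     strand = "+", pos0 = c(0L, 3000L),
                     cigar = c("200M200S", "200S200M"))
  g <- group_by_read(segs_from_records(recs))
  expect_equal(nrow(candidate_supports(g, ann, detection_params())), 0L)
  sp <- candidate_supports(g, ann,
                           detection_params(include_pseudogenes = TRUE))
  expect_equal(sp$pair, "gn|ps")
})

test_that("bin_window_pairs places junctions in overlapping windows", {
  ann <- grid_annotation()   # g01 span starts at 0, g02 at 2200
  mk_support <- function(ja_off, jb_off, qn = "q") data.table::data.table(
    qname = qn, gene_up = "g01", gene_down = "g02", pair = "g01|g02",
    chrom_up = "chrT", chrom_down = "chrT",
    junction_up = 0L + ja_off + 1L, junction_down = 2200L + jb_off + 1L,
    overlap_up = 200L, overlap_down = 200L)
  # offsets 30/30 with w=50: windows {0,1} x {0,1} -> 4 pairs, 1 support each
  wp <- bin_window_pairs(mk_support(30L, 30L), ann, w = 50)
  expect_equal(nrow(wp), 4L)
  expect_setequal(paste(wp$window_a, wp$window_b),
                  c("0 0", "0 1", "1 0", "1 1"))
  expect_true(all(wp$n_support == 1L))
  # offset 0 -> member of window 0 only
  wp0 <- bin_window_pairs(mk_support(0L, 30L), ann, w = 50)
  expect_setequal(wp0$window_a, 0L)
  # three junctions within 10 bp share at least one window pair
  sp3 <- data.table::rbindlist(list(mk_support(40L, 60L, "q1"),
                                    mk_support(44L, 63L, "q2"),
                                    mk_support(49L, 55L, "q3")))
  wp3 <- bin_window_pairs(sp3, ann, w = 50)
  expect_equal(max(wp3$n_support), 3L)
  expect_equal(wp3[1, .(window_a, window_b, n_support)],
               oracle_window_pairs(sp3, ann, 50)[
                 order(-n_support, window_a, window_b)][
                   1, .(window_a, window_b, n_support)])
})

test_that("junctions outside the gene span clamp with a warning", {
  ann <- grid_annotation()
  sp <- data.table::data.table(
    qname = "q", gene_up = "g01", gene_down = "g02", pair = "g01|g02",
    chrom_up = "chrT", chrom_down = "chrT",
    junction_up = 1500L,             # beyond g01 span end (1200)
    junction_down = 2231L, overlap_up = 200L, overlap_down = 200L)
  expect_warning(wp <- bin_window_pairs(sp, ann, w = 50), "clamped")
  expect_true(all(wp$window_a <= (1200 - 1) %/% 25))
})

test_that("select_breakpoints averages member junctions half-up", {
  ann <- grid_annotation()
  sp <- data.table::data.table(
    qname = c("a", "b", "c"), gene_up = "g01", gene_down = "g02",
    pair = "g01|g02", chrom_up = "chrT", chrom_down = "chrT",
    junction_up = c(1000L, 1002L, 1004L),
    junction_down = c(5000L, 5000L, 5001L),
    overlap_up = 200L, overlap_down = 200L)
  wp <- data.table::data.table(window_a = 0L, window_b = 0L, n_support = 3L,
                               support_idx = list(1:3))
  bp <- select_breakpoints(wp, sp, c("g01", "g02"), breakpoints_out = 1)
  expect_equal(bp$breakpoint_a, 1002)
  expect_equal(bp$breakpoint_b, 5000)     # mean 5000.33 -> 5000
  # half-up rounding: junctions 10 and 11 average to 10.5 -> 11
  sp2 <- sp[1:2][, junction_up := c(10L, 11L)]
  wp2 <- data.table::data.table(window_a = 0L, window_b = 0L, n_support = 2L,
                                support_idx = list(1:2))
  expect_equal(select_breakpoints(wp2, sp2, c("g01", "g02"))$breakpoint_a, 11)
  # only the top window pair is reported by default
  wps <- data.table::data.table(window_a = c(0L, 5L), window_b = c(0L, 5L),
                                n_support = c(3L, 2L),
                                support_idx = list(1:3, 1:2))
  data.table::setorder(wps, -n_support)
  expect_equal(nrow(select_breakpoints(wps, sp, c("g01", "g02"), 1L)), 1L)
  expect_equal(select_breakpoints(wps, sp, c("g01", "g02"), 1L)$n_support, 3L)
  # single support: breakpoints are its junctions exactly
  bp1 <- select_breakpoints(
    data.table::data.table(window_a = 0L, window_b = 0L, n_support = 1L,
                           support_idx = list(1L)),
    sp[1], c("g01", "g02"))
  expect_equal(c(bp1$breakpoint_a, bp1$breakpoint_b), c(1000, 5000))
})

test_that("rank_candidates filters by support and orders deterministically", {
  cand <- data.table::data.table(
    pair = c("a|b", "c|d", "e|f", "a|z", "x|y"),
    support_count = c(2L, 8L, 1L, 2L, 7L))
  r <- rank_candidates(cand, min_support = 2)
  expect_equal(r$support_count, c(8L, 7L, 2L, 2L))
  expect_equal(r$pair, c("c|d", "x|y", "a|b", "a|z"))  # ties lexicographic
  expect_equal(nrow(rank_candidates(cand, min_support = 100)), 0L)
})

test_that("detection is invariant to segment input order (canonical pairs)", {
  ann <- grid_annotation()
  recs <- rbind(two_gene_read("r1"), two_gene_read("r2"))
  g1 <- group_by_read(segs_from_records(recs))
  g2 <- group_by_read(segs_from_records(recs[rev(seq_len(nrow(recs))), ]))
  s1 <- candidate_supports(g1, ann, detection_params())
  s2 <- candidate_supports(g2, ann, detection_params())
  expect_equal(s1[, .(qname, pair, junction_up, junction_down)],
               s2[, .(qname, pair, junction_up, junction_down)])
  expect_true(all(s1$pair == "g01|g02"))  # canonical regardless of order
})

test_that("raising thresholds never adds supports or candidates", {
  sim <- small_sim()
  segs <- compute_segments(read_alignments(sim$sam))
  ann <- parse_gtf(sim$gtf)
  base <- detect_fusions(segs, ann, detection_params(), verbose = FALSE)
  stricter <- list(
    detection_params(min_support = 5),
    detection_params(min_map_len = 200),
    detection_params(min_exon_overlap = 150))
  for (p in stricter) {
    res <- detect_fusions(segs, ann, p, verbose = FALSE)
    expect_lte(nrow(res$supports), nrow(base$supports))
    expect_lte(nrow(res$candidates), nrow(base$candidates))
    expect_true(all(res$supports$qname %in% base$supports$qname))
  }
})

test_that("winning-window support never exceeds distinct supporting reads", {
  sim <- small_sim()
  res <- detect_fusions(sim$sam, sim$gtf, verbose = FALSE)
  expect_true(all(res$candidates$support_count <=
                    res$candidates$n_reads_total))
  # each read contributes at most one support per pair
  expect_false(any(duplicated(res$supports[, .(qname, pair)])))
})
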
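# Independent brute-force implementations used as oracles. These walk
# CIGARs base by base and enumerate windows by direct membership tests;
# they share no code with the package internals they check.

oracle_parse_cigar <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  list(len = as.integer(sub("[A-Z=]$", "", toks)),
       op = sub("^\\d+", "", toks))
}

# per-base query walk: returns the 0-based half-open interval of
# original-read positions consumed by aligned ops, reflecting for reverse
oracle_read_span <- function(cigar, strand, read_length) {
  ct <- oracle_parse_cigar(cigar)
  qpos <- 0L
  touched <- integer(0)
  for (i in seq_along(ct$op)) {
    op <- ct$op[i]; len <- ct$len[i]
    if (op %in% c("S", "H")) qpos <- qpos + len
    else if (op %in% c("M", "I", "=", "X")) {
      touched <- c(touched, qpos:(qpos + len - 1L))
      qpos <- qpos + len
    } # D/N/P: no query
  }
  span <- c(min(touched), max(touched) + 1L)
  if (strand == "-") span <- c(read_length - span[2], read_length - span[1])
  span
}

# per-base reference walk: 0-based positions covered by M/=/X, merged
oracle_ref_blocks <- function(cigar, ref_start) {
  ct <- oracle_parse_cigar(cigar)
  rpos <- ref_start
  covered <- integer(0)
  for (i in seq_along(ct$op)) {
    op <- ct$op[i]; len <- ct$len[i]
    if (op %in% c("M", "=", "X")) {
      covered <- c(covered, rpos:(rpos + len - 1L))
      rpos <- rpos + len
    } else if (op %in% c("D", "N")) rpos <- rpos + len
  }
  covered <- sort(unique(covered))
  if (length(covered) == 0L) return(matrix(integer(0), ncol = 2))
  brk <- c(0L, which(diff(covered) > 1L), length(covered))
  t(vapply(seq_len(length(brk) - 1L), function(j)
    c(covered[brk[j] + 1L], covered[brk[j + 1L]] + 1L), integer(2)))
}

# set-based exonic overlap: max over transcripts of shared base count
oracle_exon_overlap <- function(ann, gene, blocks) {
  ex <- ann$exons[ann$exons$gene_id == gene, ]
  bset <- unlist(lapply(seq_len(nrow(blocks)), function(i)
    seq(blocks[i, 1], blocks[i, 2] - 1L)))
  per_tx <- vapply(unique(ex$transcript_id), function(tx) {
    e <- ex[ex$transcript_id == tx, ]
    eset <- unlist(lapply(seq_len(nrow(e)), function(i)
      seq(e$start[i], e$end[i] - 1L)))
    length(intersect(bset, eset))
  }, integer(1))
  if (length(per_tx)) max(per_tx) else 0L
}

# brute-force support enumeration for one read group
oracle_supports_for_group <- function(segdt, blocks, ann, params) {
  # documented tie-break: M_start, then M_end, chrom, pos0, flag
  segdt <- segdt[order(segdt$M_start, segdt$M_end, segdt$chrom,
                       segdt$pos0, segdt$flag), ]
  out <- list()
  for (i in seq_len(nrow(segdt) - 1L)) {
    up <- segdt[i, ]; dn <- segdt[i + 1L, ]
    hit <- function(s) {
      if (s$aligned_len < params$min_map_len) return(NULL)
      g <- ann$genes[ann$genes$chrom == s$chrom, ]
      if (!params$include_pseudogenes)
        g <- g[!grepl("pseudogene", g$biotype, ignore.case = TRUE) |
                 is.na(g$biotype), ]
      bl <- as.matrix(blocks[blocks$seg_id == s$seg_id, c("start", "end")])
      ov <- vapply(g$gene_id, function(gg) oracle_exon_overlap(ann, gg, bl),
                   integer(1))
      g <- g[ov >= params$min_exon_overlap, ]
      ov <- ov[ov >= params$min_exon_overlap]
      if (nrow(g) == 0L) return(NULL)
      o <- order(-ov, g$gene_id)
      list(gene = g$gene_id[o[1]], ov = ov[o[1]])
    }
    hu <- hit(up); hd <- hit(dn)
    if (is.null(hu) || is.null(hd)) next
    if (hu$gene == hd$gene) next
    d <- dn$M_start - up$M_end
    if (d < -params$gap_max || d > params$gap_max) next
    ga <- ann$genes[ann$genes$gene_id == hu$gene, ]
    gb <- ann$genes[ann$genes$gene_id == hd$gene, ]
    # paper formula on 1-based inclusive coordinates: E1 - S2 > 0
    if (ga$chrom == gb$chrom) {
      S1 <- min(ga$start, gb$start) + 1L
      E1 <- if (ga$start <= gb$start) ga$end else gb$end
      S2 <- max(ga$start, gb$start) + 1L
      if (E1 - S2 > 0L) next
    }
    ju <- if (up$strand == "-") up$ref_start + 1L else up$ref_end
    jd <- if (dn$strand == "-") dn$ref_end else dn$ref_start + 1L
    out[[length(out) + 1L]] <- data.table::data.table(
      qname = up$qname, gene_up = hu$gene, gene_down = hd$gene,
      junction_up = ju, junction_down = jd)
  }
  if (length(out) == 0L) return(NULL)
  res <- data.table::rbindlist(out)
  res[, pair := ifelse(gene_up <= gene_down,
                       paste(gene_up, gene_down, sep = "|"),
                       paste(gene_down, gene_up, sep = "|"))]
  res[!duplicated(paste(qname, pair))]
}

# direct window membership: all (ka, kb) pairs with their support counts
oracle_window_pairs <- function(supports, ann, w) {
  genes <- sort(c(supports$gene_up[1], supports$gene_down[1]))
  h <- w / 2
  win_of <- function(j1, g) {
    gr <- ann$genes[ann$genes$gene_id == g, ]
    off <- (j1 - 1) - gr$start
    span <- gr$end - gr$start
    kmax <- max((span - 1) %/% h, 0)
    off <- min(max(off, 0), span - 1)
    which(vapply(0:kmax, function(k)
      off >= k * h && off < k * h + w, logical(1))) - 1L
  }
  rows <- list()
  for (i in seq_len(nrow(supports))) {
    ja <- if (supports$gene_up[i] == genes[1]) supports$junction_up[i] else
      supports$junction_down[i]
    jb <- if (supports$gene_up[i] == genes[2]) supports$junction_up[i] else
      supports$junction_down[i]
    for (ka in win_of(ja, genes[1]))
      for (kb in win_of(jb, genes[2]))
        rows[[length(rows) + 1L]] <- data.table::data.table(
          window_a = ka, window_b = kb, support_idx = i)
  }
  memb <- data.table::rbindlist(rows)
  memb[, .(n_support = .N, support_idx = list(support_idx)),
       by = .(window_a, window_b)]
}

# oracle breakpoints: top window pair by (-count, window_a, window_b),
# arithmetic mean of member junctions per gene, half-up rounding
oracle_breakpoints <- function(supports, ann, w) {
  genes <- sort(c(supports$gene_up[1], supports$gene_down[1]))
  wp <- oracle_window_pairs(supports, ann, w)
  wp <- wp[order(-n_support, window_a, window_b)]
  idx <- wp$support_idx[[1]]
  ja <- ifelse(supports$gene_up == genes[1], supports$junction_up,
               supports$junction_down)
  jb <- ifelse(supports$gene_up == genes[2], supports$junction_up,
               supports$junction_down)
  c(bp_a = floor(mean(ja[idx]) + 0.5), bp_b = floor(mean(jb[idx]) + 0.5),
    n = wp$n_support[1])
}
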
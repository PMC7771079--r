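# Fully synthetic, truth-annotated data generator: toy genome, multi-exon
# gene models, fused transcripts with TPM-tiered expression, long reads
# under a truncation + error model, and analytically constructed split SAM
# alignments (no external simulator or aligner).
#
# Alignments are obtained by projecting transcript coordinates through the
# exon structure onto the genome: splice junctions become N ops, sequencing
# errors perturb sequence and CIGAR consistently, and a junction-spanning
# read is emitted as two records (primary = longer aligned part,
# supplementary = shorter, soft-clipped) sharing the read name. Truth is
# therefore exact by construction.

#' Simulation configuration
#'
#' Defaults describe the desk-scale simulation world: 150 background genes
#' (~1e5 total TPM universe, preserving the reads-per-TPM ratio of a 500k
#' read / 1e6 TPM transcriptome at 50k reads), 20 fusions split evenly
#' between a high tier (TPM > 1000) and a low tier (TPM 10-1000), and a
#' Nanopore-like error model (2% substitution, 1% insertion, 3% deletion)
#' with occasional soft-clip slip of a few bases at the fusion junction.
#'
#' @param seed integer RNG seed; a fixed seed yields byte-identical output
#' @param n_genes number of background genes
#' @param n_chroms number of toy chromosomes
#' @param exons_per_gene integer range (min, max) of exons per gene
#' @param exon_len,intron_len,intergenic_len bp ranges (min, max)
#' @param second_isoform_prob probability a gene gets a second isoform
#'   (one internal exon skipped)
#' @param n_fusions number of simulated gene fusions
#' @param tpm_high_count fusions in the high-expression tier (default half)
#' @param tpm_high_range,tpm_low_range TPM ranges of the two tiers
#'   (log-uniform sampling)
#' @param bg_tpm_range background gene TPM range (log-uniform)
#' @param total_reads reads per dataset
#' @param p_full probability a read is full-length; otherwise it is
#'   truncated from the 5' or 3' end (equal odds) to a uniform length
#'   >= `min_read_len`
#' @param min_read_len minimum truncated read length, bp
#' @param error_rates named numeric: per-base `sub`, `ins`, `del` rates
#' @param error_free disable all errors and junction slip (exact alignments)
#' @param slip_prob,slip_max junction soft-clip slip: probability per
#'   junction side, maximum slipped bases (emulates aligner ambiguity at
#'   the breakpoint; inactive when `error_free`)
#' @param secondary_frac fraction of reads whose primary record is also
#'   emitted as a secondary duplicate (exercises secondary filtering)
#' @param overlapping_pair also place one gene overlapping another gene's
#'   span (negative control for the overlapping-gene rule)
#' @param add_pseudogene also place one processed-pseudogene gene
#' @param fusion_margin cut points are uniform over the transcript
#'   excluding this many bp at each end
#' @param min_fusion_tx_len minimum transcript length for fusion partners
#' @param min_supp_align shortest junction-side part emitted as its own
#'   record; shorter parts are soft-clipped into the longer record
#' @param write_fastq also write reads as FASTQ
#' @return list of class `sim_config`
#' @export
sim_config <- function(seed = 1L, n_genes = 150, n_chroms = 3,
                       exons_per_gene = c(3, 8), exon_len = c(100, 400),
                       intron_len = c(200, 2000),
                       intergenic_len = c(500, 3000),
                       second_isoform_prob = 0.3,
                       n_fusions = 20, tpm_high_count = NULL,
                       tpm_high_range = c(1000, 5000),
                       tpm_low_range = c(10, 1000),
                       bg_tpm_range = c(10, 2000),
                       total_reads = 50000, p_full = 0.6,
                       min_read_len = 200,
                       error_rates = c(sub = 0.02, ins = 0.01, del = 0.03),
                       error_free = FALSE,
                       slip_prob = 0.4, slip_max = 5,
                       secondary_frac = 0.02,
                       overlapping_pair = FALSE, add_pseudogene = FALSE,
                       fusion_margin = 200, min_fusion_tx_len = 500,
                       min_supp_align = 30, write_fastq = FALSE) {
  if (is.null(tpm_high_count)) tpm_high_count <- ceiling(n_fusions / 2)
  if (n_fusions > n_genes / 2)
    stop("n_fusions must be <= n_genes/2", call. = FALSE)
  stopifnot(all(c("sub", "ins", "del") %in% names(error_rates)))
  structure(as.list(environment()), class = "sim_config")
}

# --- gene model / genome construction -----------------------------------

#' Generate a toy genome and gene annotation
#'
#' Places multi-exon genes (random strand, optional second isoform) without
#' span overlap along a small multi-chromosome random genome. Optionally
#' adds one overlapping gene pair and one pseudogene as negative controls.
#'
#' @param config a [sim_config()]
#' @return list: `annotation` (a `gene_annotation`, pseudogene included so
#'   the written GTF carries it), `genome` (named `DNAStringSet`),
#'   `special` (character: gene ids of the controls)
#' @export
make_genome_and_annotation <- function(config) {
  nch <- config$n_chroms
  cursor <- rep(0L, nch)
  chrom_names <- paste0("chrS", seq_len(nch))
  exon_rows <- list(); meta_rows <- list(); ri <- 0L
  special <- character(0)

  place_gene <- function(gid, gname, biotype, chrom_i, start_at = NULL) {
    n_ex <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]), 1L)
    elens <- sample(seq(config$exon_len[1], config$exon_len[2]), n_ex,
                    replace = TRUE)
    ilens <- if (n_ex > 1L)
      sample(seq(config$intron_len[1], config$intron_len[2]), n_ex - 1L,
             replace = TRUE) else integer(0)
    strand <- sample(c("+", "-"), 1L)
    gap <- sample(seq(config$intergenic_len[1], config$intergenic_len[2]), 1L)
    s0 <- if (is.null(start_at)) cursor[chrom_i] + gap else start_at
    starts <- s0 + cumsum(c(0L, utils::head(elens, -1L) + ilens))
    ends <- starts + elens
    ex <- data.table::data.table(
      chrom = chrom_names[chrom_i], start = starts, end = ends,
      strand = strand, transcript_id = paste0(gid, ".t1"), gene_id = gid)
    if (n_ex >= 3L && stats::runif(1) < config$second_isoform_prob) {
      drop <- sample(2:(n_ex - 1L), 1L)
      ex2 <- ex[-drop][, transcript_id := paste0(gid, ".t2")]
      ex <- rbind(ex, ex2)
    }
    if (is.null(start_at))
      cursor[chrom_i] <<- max(ends)
    ri <<- ri + 1L
    exon_rows[[ri]] <<- ex
    meta_rows[[ri]] <<- data.table::data.table(
      gene_id = gid, gene_name = gname, biotype = biotype)
    invisible(ex)
  }

  for (i in seq_len(config$n_genes)) {
    place_gene(sprintf("G%04d", i), sprintf("G%04d", i), "protein_coding",
               ((i - 1L) %% nch) + 1L)
  }
  if (isTRUE(config$overlapping_pair)) {
    # a compact gene nested in gene G0001's span (2 x 150 bp exons, 200 bp
    # intron); G0001 spans >= 700 bp by construction, so no third gene is
    # touched
    g1 <- exon_rows[[1L]]
    s0 <- min(g1$start) + 50L
    ri <- ri + 1L
    exon_rows[[ri]] <- data.table::data.table(
      chrom = chrom_names[1L], start = c(s0, s0 + 350L),
      end = c(s0 + 150L, s0 + 500L), strand = sample(c("+", "-"), 1L),
      transcript_id = "OVL001.t1", gene_id = "OVL001")
    meta_rows[[ri]] <- data.table::data.table(
      gene_id = "OVL001", gene_name = "OVL001", biotype = "protein_coding")
    special <- c(special, "OVL001")
  }
  if (isTRUE(config$add_pseudogene)) {
    place_gene("PSG001", "PSG001", "processed_pseudogene", 1L)
    special <- c(special, "PSG001")
  }

  ex_all <- data.table::rbindlist(exon_rows)
  meta <- data.table::rbindlist(meta_rows)
  ann <- .build_annotation(ex_all, meta)

  chrom_len <- pmax(cursor + 1000L,
                    ex_all[, max(end), by = chrom][match(chrom_names, chrom), V1] +
                      1000L, na.rm = TRUE)
  genome <- Biostrings::DNAStringSet(vapply(chrom_len, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1L)))
  names(genome) <- chrom_names
  list(annotation = ann, genome = genome, special = special)
}

# --- transcript coordinate machinery ------------------------------------

# per-transcript structure: genome-sorted exons + transcript-order mapping
.tx_structure <- function(annotation, tx_id) {
  sel <- annotation$exons$transcript_id == tx_id
  ex <- data.table::copy(annotation$exons[sel])
  data.table::setorder(ex, start)
  strand <- ex$strand[1L]
  ord <- if (strand == "-") rev(seq_len(nrow(ex))) else seq_len(nrow(ex))
  w <- (ex$end - ex$start)[ord]
  list(chrom = ex$chrom[1L], strand = strand,
       gs = ex$start[ord], ge = ex$end[ord],       # transcript order
       w = w, cs = cumsum(c(0L, utils::head(w, -1L))),
       len = sum(w))
}

# 1-based genomic coordinate of transcript base t (1-based)
.tx_to_genome <- function(txs, t) {
  k <- findInterval(t - 1L, cumsum(txs$w), left.open = FALSE) + 1L
  o <- t - txs$cs[k]
  if (txs$strand == "+") txs$gs[k] + o else txs$ge[k] - o + 1L
}

# project transcript interval [t1, t2] (1-based) onto the genome.
# Returns blocks in TRANSCRIPT order: m (aligned lens), gs0/ge0 (0-based
# half-open genome coords) and the genomic gap (intron length) preceding
# each block after the first.
.project_tx_interval <- function(txs, t1, t2) {
  lo <- txs$cs + 1L; hi <- txs$cs + txs$w
  keep <- which(hi >= t1 & lo <= t2)
  o1 <- pmax(t1, lo[keep]) - txs$cs[keep]
  o2 <- pmin(t2, hi[keep]) - txs$cs[keep]
  if (txs$strand == "+") {
    gs0 <- txs$gs[keep] + o1 - 1L
    ge0 <- txs$gs[keep] + o2
  } else {
    gs0 <- txs$ge[keep] - o2
    ge0 <- txs$ge[keep] - o1 + 1L
  }
  m <- o2 - o1 + 1L
  gap <- if (length(keep) > 1L) {
    if (txs$strand == "+") gs0[-1L] - ge0[-length(ge0)]
    else gs0[-length(gs0)] - ge0[-1L]
  } else integer(0)
  list(m = m, gs0 = gs0, ge0 = ge0, gap = gap,
       ref_start0 = min(gs0), ref_end0 = max(ge0))
}

# transcript sequence (transcript orientation)
.tx_seq <- function(genome, txs) {
  parts <- substring(as.character(genome[[txs$chrom]]),
                     sort(txs$gs) + 1L, sort(txs$ge))
  s <- paste(parts, collapse = "")
  if (txs$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

# --- fusion truth -------------------------------------------------------

#' Construct the simulated fusion truth set
#'
#' Samples `n_fusions` distinct gene pairs from the eligible background
#' genes (no pseudogenes, no overlapping-pair controls, transcript long
#' enough), one transcript per partner, cuts each transcript at a uniform
#' exonic position away from the ends, and assigns a TPM from the fusion's
#' expression tier. The fused transcript is the 5' part of transcript A
#' followed by the 3' part of transcript B.
#'
#' @param sim output of [make_genome_and_annotation()]
#' @param config a [sim_config()]
#' @return data.table truth: fusion_id, gene_a, gene_b, transcript_a,
#'   transcript_b, chrom_a, chrom_b, breakpoint_a, breakpoint_b (1-based
#'   genomic), cut_a, cut_b (transcript coords), fused_len, tpm, tier
#' @export
make_fusions <- function(sim, config) {
  ann <- sim$annotation
  min_len <- max(config$min_fusion_tx_len, 2L * config$fusion_margin + 2L)
  eligible <- ann$transcripts[!ann$transcripts$gene_id %in% sim$special, ]
  tx_len <- ann$exons[, .(len = sum(end - start)), by = transcript_id]
  eligible <- merge(eligible, tx_len, by = "transcript_id")[len >= min_len]
  elig_genes <- unique(eligible$gene_id)
  if (length(elig_genes) < 2L * config$n_fusions)
    stop("not enough eligible genes for ", config$n_fusions, " fusions",
         call. = FALSE)
  partners <- sample(elig_genes, 2L * config$n_fusions)
  ga <- partners[seq_len(config$n_fusions)]
  gb <- partners[config$n_fusions + seq_len(config$n_fusions)]

  tier <- rep("low", config$n_fusions)
  tier[sample(config$n_fusions, min(config$tpm_high_count, config$n_fusions))] <- "high"
  rng <- function(r, n) exp(stats::runif(n, log(r[1]), log(r[2])))
  tpm <- ifelse(tier == "high",
                rng(config$tpm_high_range, config$n_fusions),
                rng(config$tpm_low_range, config$n_fusions))

  pick_tx <- function(g) {
    cand <- eligible[gene_id == g, transcript_id]
    cand[sample.int(length(cand), 1L)]
  }
  rows <- lapply(seq_len(config$n_fusions), function(i) {
    ta <- pick_tx(ga[i]); tb <- pick_tx(gb[i])
    sa <- .tx_structure(ann, ta); sb <- .tx_structure(ann, tb)
    m <- config$fusion_margin
    cut_a <- sample(seq(m, sa$len - m), 1L)
    cut_b <- sample(seq(m, sb$len - m), 1L)
    data.table::data.table(
      fusion_id = sprintf("F%03d", i), gene_a = ga[i], gene_b = gb[i],
      transcript_a = ta, transcript_b = tb,
      chrom_a = sa$chrom, chrom_b = sb$chrom,
      breakpoint_a = .tx_to_genome(sa, cut_a),
      breakpoint_b = .tx_to_genome(sb, cut_b + 1L),
      cut_a = cut_a, cut_b = cut_b,
      fused_len = cut_a + (sb$len - cut_b),
      tpm = tpm[i], tier = tier[i])
  })
  data.table::rbindlist(rows)
}

# --- error model --------------------------------------------------------

# split one pre-error M run of length m at sorted distinct query offsets
# `rel` with event types in {del, ins}; returns op/len vectors. Query
# consumption changes by (+ins - del); reference consumption is unchanged.
.split_m_run <- function(m, rel, type) {
  k <- length(rel)
  if (k == 0L) return(list(ops = "M", lens = m))
  ops <- character(2L * k + 1L); lens <- integer(2L * k + 1L)
  n <- 0L; prev <- 0L
  for (j in seq_len(k)) {
    o <- rel[j]
    if (type[j] == "del") {
      if (o - 1L > prev) { n <- n + 1L; ops[n] <- "M"; lens[n] <- o - 1L - prev }
      n <- n + 1L; ops[n] <- "D"; lens[n] <- 1L
      prev <- o
    } else { # ins (after offset o)
      if (o > prev) { n <- n + 1L; ops[n] <- "M"; lens[n] <- o - prev }
      n <- n + 1L; ops[n] <- "I"; lens[n] <- 1L
      prev <- o
    }
  }
  if (m > prev) { n <- n + 1L; ops[n] <- "M"; lens[n] <- m - prev }
  list(ops = ops[seq_len(n)], lens = lens[seq_len(n)])
}

# --- read / alignment emission ------------------------------------------

# build one alignment record for an aligned transcript interval.
#   txs: transcript structure; t1,t2: aligned tx interval (1-based);
#   eoff/etype: sorted indel event offsets (1..t2-t1+1) and types
# Returns list(ops/lens in TRANSCRIPT order, ref_start0)
.build_job <- function(txs, t1, t2, eoff, etype) {
  pr <- .project_tx_interval(txs, t1, t2)
  qcum <- cumsum(pr$m)
  parts <- vector("list", 2L * length(pr$m))
  np <- 0L
  for (b in seq_along(pr$m)) {
    span_lo <- if (b == 1L) 1L else qcum[b - 1L] + 1L
    inb <- eoff >= span_lo & eoff <= qcum[b]
    sp <- .split_m_run(pr$m[b], eoff[inb] - span_lo + 1L, etype[inb])
    if (b > 1L) {
      np <- np + 1L
      parts[[np]] <- list(ops = "N", lens = pr$gap[b - 1L])
    }
    np <- np + 1L
    parts[[np]] <- sp
  }
  parts <- parts[seq_len(np)]
  list(ops = unlist(lapply(parts, `[[`, "ops")),
       lens = unlist(lapply(parts, `[[`, "lens")),
       ref_start0 = pr$ref_start0)
}

# assemble final CIGAR string for a job given final-length clips
# (lead/trail in transcript-forward orientation of the stored read)
.job_cigar <- function(ops, lens, strand, lead, trail) {
  if (strand == "-") { ops <- rev(ops); lens <- rev(lens)
    tmp <- lead; lead <- trail; trail <- tmp }
  if (lead > 0L) { ops <- c("S", ops); lens <- c(lead, lens) }
  if (trail > 0L) { ops <- c(ops, "S"); lens <- c(lens, trail) }
  paste0(lens, ops, collapse = "")
}

#' Emit simulated reads and split alignments
#'
#' Draws reads per transcript with probability proportional to TPM x
#' length, applies the truncation and error models, and writes SAM records:
#' junction-spanning fusion reads become two records (primary = longer
#' aligned part, supplementary = shorter, soft-clipped), everything else a
#' single record; a configurable fraction of primaries is duplicated as
#' secondary records. Each read is emitted forward or reverse-complemented
#' with probability 1/2.
#'
#' @param sim output of [make_genome_and_annotation()]
#' @param truth output of [make_fusions()]
#' @param config a [sim_config()]
#' @param sam_path output SAM path
#' @param fastq_path optional FASTQ path (used when `config$write_fastq`)
#' @return list: `reads` (per-read provenance: read_name, source, tpm,
#'   spans_junction, junction_read_pos, read_len), `sam` (path),
#'   `n_records`
#' @export
emit_reads_and_alignments <- function(sim, truth, config, sam_path,
                                      fastq_path = NULL) {
  ann <- sim$annotation
  rates <- if (config$error_free) c(sub = 0, ins = 0, del = 0) else
    config$error_rates

  # source universe: one random isoform per background gene + fused txs
  bg_genes <- ann$genes$gene_id[!ann$genes$gene_id %in% sim$special]
  bg_tx <- vapply(bg_genes, function(g) {
    cand <- ann$transcripts[ann$transcripts$gene_id == g, transcript_id]
    cand[sample.int(length(cand), 1L)]
  }, character(1L))
  bg_tpm <- exp(stats::runif(length(bg_genes),
                             log(config$bg_tpm_range[1]),
                             log(config$bg_tpm_range[2])))
  txs_cache <- new.env(parent = emptyenv())
  get_txs <- function(id) {
    if (is.null(txs_cache[[id]])) txs_cache[[id]] <- .tx_structure(ann, id)
    txs_cache[[id]]
  }
  seq_cache <- new.env(parent = emptyenv())
  get_seq <- function(id) {
    if (is.null(seq_cache[[id]])) seq_cache[[id]] <- .tx_seq(sim$genome, get_txs(id))
    seq_cache[[id]]
  }

  nf <- nrow(truth)
  src <- data.table::data.table(
    source = c(bg_genes, truth$fusion_id),
    type = c(rep("background", length(bg_genes)), rep("fusion", nf)),
    tx = c(bg_tx, rep(NA_character_, nf)),
    tpm = c(bg_tpm, truth$tpm),
    len = c(vapply(bg_tx, function(t) get_txs(t)$len, integer(1L)),
            truth$fused_len))
  # fused sequences: 5' part of tx A + 3' part of tx B
  fused_seq <- vapply(seq_len(nf), function(i) {
    paste0(substr(get_seq(truth$transcript_a[i]), 1L, truth$cut_a[i]),
           substr(get_seq(truth$transcript_b[i]), truth$cut_b[i] + 1L,
                  get_txs(truth$transcript_b[i])$len))
  }, character(1L))
  src_seq <- c(vapply(bg_tx, get_seq, character(1L)), fused_seq)

  w <- src$tpm * src$len
  counts <- as.vector(stats::rmultinom(1L, config$total_reads, w / sum(w)))
  n <- sum(counts)
  src_idx <- rep(seq_len(nrow(src)), counts)

  # truncation model
  L <- src$len[src_idx]
  full <- stats::runif(n) < config$p_full
  tlen <- ifelse(L <= config$min_read_len, L,
                 floor(stats::runif(n, config$min_read_len, L + 1)))
  tlen <- pmin(ifelse(full, L, tlen), L)
  side5 <- stats::runif(n) < 0.5
  a <- as.integer(ifelse(full | !side5, 1L, L - tlen + 1L))
  b <- as.integer(a + tlen - 1L)
  flip <- stats::runif(n) < 0.5
  rname <- sprintf("r%07d", seq_len(n))

  R0 <- substring(src_seq[src_idx], a, b)

  fid <- match(src$source[src_idx], truth$fusion_id) # NA for background
  J <- truth$cut_a[fid]                              # fused-coord junction
  spans <- !is.na(fid) & a <= J & b >= J + 1L
  pa <- ifelse(spans, J - a + 1L, NA_integer_)
  pb <- ifelse(spans, b - J, NA_integer_)
  split_read <- spans & pmin(pa, pb) >= config$min_supp_align

  # junction slip (aligner ambiguity), only for split reads with errors on
  slip <- function(k) {
    s <- ifelse(stats::runif(k) < config$slip_prob,
                pmin(stats::rgeom(k, 0.5) + 1L, config$slip_max), 0L)
    if (config$error_free) rep(0L, k) else s
  }
  c_up <- rep(0L, n); c_dn <- rep(0L, n)
  c_up[split_read] <- as.integer(pmin(slip(sum(split_read)),
                           pmax(pa[split_read] - config$min_supp_align, 0L)))
  c_dn[split_read] <- as.integer(pmin(slip(sum(split_read)),
                           pmax(pb[split_read] - config$min_supp_align, 0L)))

  # --- job table: one aligned part per row, vectorized ------------------
  bases <- c("A", "C", "G", "T")
  is_bg <- is.na(fid)
  in_a  <- !is_bg & !split_read & b <= J                 # read in 5' part
  in_b  <- !is_bg & !split_read & a > J                  # read in 3' part
  clip3 <- !is_bg & !split_read & spans & pa >= pb       # short 3' clipped
  clip5 <- !is_bg & !split_read & spans & pa < pb        # short 5' clipped

  tx1 <- character(n); t1_1 <- integer(n); t2_1 <- integer(n)
  q1_1 <- rep(1L, n)
  tx1[is_bg] <- src$tx[src_idx[is_bg]]
  t1_1[is_bg] <- a[is_bg]; t2_1[is_bg] <- b[is_bg]
  s <- split_read
  tx1[s] <- truth$transcript_a[fid[s]]
  t1_1[s] <- a[s]; t2_1[s] <- J[s] - c_up[s]
  tx1[in_a] <- truth$transcript_a[fid[in_a]]
  t1_1[in_a] <- a[in_a]; t2_1[in_a] <- b[in_a]
  tx1[in_b] <- truth$transcript_b[fid[in_b]]
  t1_1[in_b] <- truth$cut_b[fid[in_b]] + (a[in_b] - J[in_b])
  t2_1[in_b] <- truth$cut_b[fid[in_b]] + (b[in_b] - J[in_b])
  tx1[clip3] <- truth$transcript_a[fid[clip3]]
  t1_1[clip3] <- a[clip3]; t2_1[clip3] <- J[clip3]
  tx1[clip5] <- truth$transcript_b[fid[clip5]]
  t1_1[clip5] <- truth$cut_b[fid[clip5]] + 1L
  t2_1[clip5] <- truth$cut_b[fid[clip5]] + (b[clip5] - J[clip5])
  q1_1[clip5] <- pa[clip5] + 1L

  jt <- data.table::data.table(read_i = seq_len(n), jord = 1L, tx = tx1,
                               t1 = t1_1, t2 = t2_1, q1 = q1_1)
  if (any(split_read)) {
    si2 <- which(split_read)
    jt <- rbind(jt, data.table::data.table(
      read_i = si2, jord = 2L,
      tx = truth$transcript_b[fid[si2]],
      t1 = truth$cut_b[fid[si2]] + c_dn[si2] + 1L,
      t2 = truth$cut_b[fid[si2]] + (b[si2] - J[si2]),
      q1 = (J[si2] + c_dn[si2] + 1L) - a[si2] + 1L))
  }
  data.table::setorder(jt, read_i, jord)
  nj <- nrow(jt)
  jt[, plen := t2 - t1 + 1L]

  # --- error events, sampled for all jobs at once -----------------------
  rate_tot <- sum(rates)
  k <- integer(nj)
  elig <- jt$plen >= 6L & rate_tot > 0
  if (any(elig)) k[elig] <- stats::rbinom(sum(elig), jt$plen[elig], rate_tot)
  k <- pmin(k, jt$plen %/% 3L)
  if (sum(k) > 0L) {
    jidx <- rep(seq_len(nj), k)
    ev <- data.table::data.table(
      job = jidx,
      pos = 2L + as.integer(floor(stats::runif(sum(k)) *
                                    (jt$plen[jidx] - 3L))))
    data.table::setorder(ev, job, pos)
    # enforce >= 2 bp spacing within a job so edits never collide
    ev <- ev[c(TRUE, !(diff(pos) < 2L & diff(job) == 0L))]
    ev[, type := sample(c("del", "ins", "sub"), .N, replace = TRUE,
                        prob = rates[c("del", "ins", "sub")])]
  } else {
    ev <- data.table::data.table(job = integer(), pos = integer(),
                                 type = character())
  }
  n_del_j <- n_ins_j <- integer(nj)
  if (nrow(ev)) {
    td <- ev[type == "del", .N, by = job]; n_del_j[td$job] <- td$N
    ti <- ev[type == "ins", .N, by = job]; n_ins_j[ti$job] <- ti$N
  }
  jt[, qlen_final := plen - n_del_j + n_ins_j]
  jt[, delta := n_ins_j - n_del_j]
  jt[, delta_before := data.table::fifelse(
    jord == 2L, data.table::shift(delta, 1L, fill = 0L), 0L)]
  Lf <- as.integer(b - a + 1L)
  dsum <- jt[, .(d = sum(delta)), by = read_i]
  Lf[dsum$read_i] <- Lf[dsum$read_i] + dsum$d
  read_len_final <- Lf

  jt[, lead_f := (q1 - 1L) + delta_before]
  jt[, trail_f := Lf[read_i] - lead_f - qlen_final]
  jt[, n_jobs := .N, by = read_i]
  jt[, is_primary := TRUE]
  idx2 <- which(jt$jord == 2L)     # rows immediately follow their jord-1 row
  if (length(idx2)) {
    p1 <- jt$qlen_final[idx2 - 1L] >= jt$qlen_final[idx2]
    jt$is_primary[idx2 - 1L] <- p1
    jt$is_primary[idx2] <- !p1
  }

  # --- sequence edits (simultaneous, original read coordinates) ---------
  R_err <- R0
  if (nrow(ev)) {
    ev[, read_i := jt$read_i[job]]
    ev[, p := jt$q1[job] + pos - 1L]
    ev[, from := data.table::fifelse(type == "ins", p + 1L, p)]
    ev[, to := data.table::fifelse(type == "ins", p, p)]
    ev[, val := data.table::fifelse(
      type == "del", "", bases[sample.int(4L, .N, replace = TRUE)])]
    # ev is sorted by (job, pos) and jobs by (read, query start), so
    # per-read positions are ascending
    uf <- unique(ev$read_i)
    fct <- factor(ev$read_i, levels = uf)
    R_err[uf] <- stringi::stri_sub_replace_all(
      R0[uf], from = split(ev$from, fct), to = split(ev$to, fct),
      replacement = split(ev$val, fct))
  }

  # --- per-job CIGAR assembly -------------------------------------------
  evi <- ev[type != "sub"]
  cnt <- tabulate(evi$job, nbins = nj)
  ends <- cumsum(cnt); starts <- ends - cnt + 1L
  txmap <- unique(jt$tx)
  tx_strand <- vapply(txmap, function(id) get_txs(id)$strand, character(1L))
  tx_chrom <- vapply(txmap, function(id) get_txs(id)$chrom, character(1L))
  tmi <- match(jt$tx, txmap)
  cig <- character(nj); pos1 <- integer(nj)
  jt_tx <- jt$tx; jt_t1 <- jt$t1; jt_t2 <- jt$t2
  jt_lead <- jt$lead_f; jt_trail <- jt$trail_f
  e_off <- evi$pos; e_ty <- evi$type
  for (jj in seq_len(nj)) {
    sl <- if (cnt[jj] > 0L) starts[jj]:ends[jj] else integer(0)
    built <- .build_job(get_txs(jt_tx[jj]), jt_t1[jj], jt_t2[jj],
                        e_off[sl], e_ty[sl])
    cig[jj] <- .job_cigar(built$ops, built$lens, tx_strand[tmi[jj]],
                          jt_lead[jj], jt_trail[jj])
    pos1[jj] <- built$ref_start0 + 1L
  }

  neg_j <- tx_strand[tmi] == "-"
  rec <- data.table::data.table(
    qname = rname[jt$read_i],
    flag = data.table::fifelse(neg_j != flip[jt$read_i], 16L, 0L) +
      data.table::fifelse(jt$is_primary, 0L, 2048L),
    chrom = tx_chrom[tmi], pos = pos1, mapq = 60L, cigar = cig,
    read_i = jt$read_i, neg = neg_j)

  # stored SEQ is genome-forward: reverse-complement for '-' gene records
  seqs <- R_err[rec$read_i]
  if (any(rec$neg)) {
    seqs[rec$neg] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[rec$neg])))
  }
  rec[, seq := seqs]

  # secondary duplicates of a fraction of primaries
  if (config$secondary_frac > 0) {
    prim <- which(bitwAnd(rec$flag, 2048L) == 0L)
    pick <- prim[stats::runif(length(prim)) < config$secondary_frac]
    if (length(pick)) {
      sec <- data.table::copy(rec[pick])
      sec[, `:=`(flag = flag + 256L, mapq = 0L)]
      rec <- rbind(rec, sec)
    }
  }
  data.table::setorder(rec, read_i, flag)

  # SAM output
  chrlen <- vapply(seq_along(sim$genome), function(k)
    length(sim$genome[[k]]), integer(1L))
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(sim$genome), chrlen),
              "@PG\tID:longfusr-sim\tPN:longfusr-sim")
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                  rec$qname, rec$flag, rec$chrom, rec$pos, rec$mapq,
                  rec$cigar, rec$seq)
  writeLines(c(header, body), sam_path)

  if (isTRUE(config$write_fastq) && !is.null(fastq_path)) {
    as_seq <- R_err
    if (any(flip)) {
      as_seq[flip] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(as_seq[flip])))
    }
    writeLines(paste0("@", rname, "\n", as_seq, "\n+\n",
                      strrep("I", nchar(as_seq))), fastq_path)
  }

  reads <- data.table::data.table(
    read_name = rname, source = src$source[src_idx],
    type = src$type[src_idx], tpm = src$tpm[src_idx],
    spans_junction = spans, split = split_read,
    junction_read_pos = ifelse(spans, pa, NA_integer_),
    read_start = a, read_end = b, read_len = read_len_final,
    flipped = flip)
  list(reads = reads, sam = sam_path, n_records = nrow(rec))
}

#' Simulate a complete truth-annotated dataset
#'
#' Orchestrates genome/annotation construction, fusion truth generation and
#' read/alignment emission under one seed, writing all files to `out_dir`:
#' `genome.fa`, `annotation.gtf`, `alignments.sam`, `truth_fusions.tsv`,
#' `truth_reads.tsv` and optionally `reads.fastq`.
#'
#' @param config a [sim_config()]
#' @param out_dir output directory (created if missing)
#' @return list: paths (`fasta`, `gtf`, `sam`, `truth`, `reads_tsv`,
#'   `fastq` or NULL), plus `annotation`, `truth`, `reads`, `config`
#' @export
simulate_fusion_dataset <- function(config = sim_config(), out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  sim <- make_genome_and_annotation(config)
  truth <- if (config$n_fusions > 0L) make_fusions(sim, config) else
    data.table::data.table(fusion_id = character(), gene_a = character(),
                           gene_b = character(), transcript_a = character(),
                           transcript_b = character(), chrom_a = character(),
                           chrom_b = character(), breakpoint_a = integer(),
                           breakpoint_b = integer(), cut_a = integer(),
                           cut_b = integer(), fused_len = integer(),
                           tpm = numeric(), tier = character())
  fasta <- file.path(out_dir, "genome.fa")
  Biostrings::writeXStringSet(sim$genome, fasta)
  gtf <- file.path(out_dir, "annotation.gtf")
  write_gtf(sim$annotation, gtf)
  sam <- file.path(out_dir, "alignments.sam")
  fastq <- if (config$write_fastq) file.path(out_dir, "reads.fastq") else NULL
  em <- emit_reads_and_alignments(sim, truth, config, sam, fastq)
  truth_path <- file.path(out_dir, "truth_fusions.tsv")
  data.table::fwrite(truth, truth_path, sep = "\t")
  reads_path <- file.path(out_dir, "truth_reads.tsv")
  data.table::fwrite(em$reads, reads_path, sep = "\t")
  list(fasta = fasta, gtf = gtf, sam = sam, truth = truth_path,
       reads_tsv = reads_path, fastq = fastq,
       annotation = sim$annotation, truth_dt = truth, reads = em$reads,
       n_records = em$n_records, config = config)
}
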
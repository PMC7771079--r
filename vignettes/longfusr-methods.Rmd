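---
title: "Detecting gene fusions from long-read RNA-seq: methods and design"
author: "longfusr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gene fusions from long-read RNA-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The detection model

A fusion transcript concatenates the 5′ part of one gene's transcript with
the 3′ part of another's. A long read covering the junction cannot be placed
in one piece by a spliced aligner; it is reported as a chimeric alignment —
a primary record for one portion of the read plus a supplementary record
(flag 0x800) for the rest, mapping inside the partner gene. `longfusr`
treats this split-alignment pattern as the unit of evidence and asks two
questions: *do the two segments of a read land cleanly in two distinct
annotated genes?* and *do many reads agree on where the junction is?*

**Secondary alignments are discarded.** A secondary record (flag 0x100)
re-places substantially the same read portion elsewhere; the two sides of a
genuine junction share no read bases, so only primary + supplementary
combinations are informative. Unmapped records are dropped; duplicate flags
are ignored (no dedup is meaningful for long cDNA reads).

**Read-coordinate arithmetic.** For each record the half-open interval of
*original-read* positions consumed by the alignment is recovered from the
CIGAR: the leading clip (S or H) gives the offset for a forward-strand
record; for a reverse-strand record the interval is reflected through the
read length, so segments of one read are comparable regardless of mapping
strand. Hard clips are counted toward the read length because supplementary
records routinely hard-clip; all records of a read must imply the same
length or the read is dropped with a warning.

**Gene assignment.** The reference blocks of a segment (CIGAR M/=/X runs; N
advances the reference as an intron, D as a small deletion) are intersected
with exon intervals *per transcript*, and the segment is assigned to the
gene whose best transcript overlap is largest (ties broken by gene id for
reproducibility). Two thresholds guard against noise: the segment must
align `min_map_len` bases and overlap exons of some transcript by
`min_exon_overlap` bases. The per-transcript accounting (rather than a
union over transcripts) reflects that a read arises from one isoform.

**Candidate pairs.** Segments are ordered by read coordinate and each
*consecutive* pair is tested (non-adjacent pairing would imply a third
intervening locus; such reads are better handled as two separate junctions,
and multi-segment reads passing all rules do produce one support per
junction). A pair becomes a support when:

* both segments have a gene assignment and the genes differ;
* the read-space gap `M3 − M2` between the upstream segment's end and the
  downstream segment's start lies in `[−gap_max, gap_max]` (default 20 bp) —
  a large positive gap means unaligned sequence between the pieces, a large
  negative gap means the pieces overlap on the read, and either pattern
  suggests alignment artifacts or complex structural variation rather than
  a clean fusion junction;
* the two gene spans do not overlap on the genome: with gene starts
  S1 ≤ S2 and ends E1, E2 in 1-based inclusive coordinates, pairs with
  `E1 − S2 > 0` are excluded. Read-through transcription and nested loci
  otherwise masquerade as fusions; rejected overlapping pairs are counted
  in the log for manual follow-up. Note the boundary: spans sharing exactly
  one base give `E1 − S2 = 0` and are *not* excluded — the rule is applied
  exactly as stated rather than as "any positive-width intersection".
* a read contributes at most one support per gene pair (first passing
  consecutive pair), so no read is double-counted in support totals.

**Junction coordinates.** The upstream segment contributes the reference
position of its read-space *end*, the downstream one its read-space
*start*; which genomic end of the alignment that is depends on the mapping
strand (for a reverse-strand segment the read-space end is the alignment's
leftmost base). Positions are reported 1-based at the terminal aligned
base.

**Window voting.** Individual junction coordinates wobble because of
sequencing and alignment errors. Per gene pair, each junction is discretized
into windows of `w` bp (default 50) anchored at the gene's span start, with
adjacent windows overlapping by `w/2` — every interior position lies in two
windows, so a cluster tighter than `w/2` can never be split across a
boundary. A support therefore populates up to 2 × 2 window pairs; counts
are per window pair, not partitioned. The pair with the most supports wins
(ties broken by ascending window indices — the tie rule is a documented
implementation choice), and the arithmetic mean of its member junctions per
gene, rounded half-up, is the reported breakpoint. `breakpoints_out > 1`
reports runner-up window pairs for downstream refinement.

**Ranking.** Candidates whose winning window holds fewer than `min_support`
reads (default 2) are dropped; the rest are sorted by support count, ties by
gene pair, making output byte-stable across runs.

# Parameters

| parameter | default | units | role |
|---|---|---|---|
| `min_map_len` | 100 | bp | minimum aligned (M/=/X) length per segment; shorter alignments of noisy reads are indistinguishable from mapping noise |
| `min_exon_overlap` | 100 | bp | minimum exonic overlap with some transcript; genes contributing < 100 bp to a fusion are undetectable by design |
| `bin_size` (`w`) | 50 | bp | breakpoint-voting window; must be even; error-free breakpoints are recovered within `w/2` |
| `gap_max` | 20 | bp | allowed read-space gap/overlap at the junction |
| `min_support` | 2 | reads | winning-window reads needed to report a candidate |
| `include_pseudogenes` | FALSE | — | pseudogene partners (biotype containing "pseudogene", case-insensitive, per Ensembl/GENCODE vocabulary) are excluded by default as a dominant source of false calls |
| `breakpoints_out` | 1 | pairs | window pairs reported per gene pair |
| `min_mapq` | 0 | — | optional MAPQ filter; off by default since the method's own overlap rules do the filtering |

# The simulator: what it emulates, and what it does not

`simulate_fusion_dataset()` produces a *stated world* in which every
quantity is known exactly:

* a toy genome (3 chromosomes) carrying 150 background genes with 3–8
  exons of 100–400 bp, introns of 0.2–2 kb, random strand, and a second
  isoform (one skipped internal exon) in ~30% of genes;
* `n_fusions` = 20 fusions: distinct, non-overlapping gene pairs; one
  transcript per partner is cut at a uniform exonic position and the 5′
  part of A is joined to the 3′ part of B. Half of the fusions draw TPM
  log-uniformly from (1000, 5000], half from [10, 1000] — the two
  expression tiers of the benchmark design this package reproduces at desk
  scale;
* background genes draw TPM log-uniformly from [10, 2000]. This makes the
  whole universe ≈ 1e5 total TPM. Rationale: the full-scale benchmark this
  emulates uses 500k reads against a ~1e6-TPM transcriptome, so a fusion at
  TPM *t* receives ≈ t/2 reads; at the desk scale of 50,000 reads per
  dataset, a ~1e5-TPM universe preserves that reads-per-TPM ratio, and with
  it the per-fusion support counts that drive recall. This is a deliberate
  scaling choice, fixed once, not a tuning knob;
* reads are drawn multinomially with probability ∝ TPM × transcript
  length; each read is full-length with probability 0.6, else truncated
  from the 5′ or 3′ end to a uniform length ≥ 200 bp (median read length
  ≈ 1 kb, matching the order of magnitude of real Nanopore cDNA data);
  each read is emitted forward or reverse-complemented with probability
  1/2 to exercise the strand-reflection arithmetic;
* the error model perturbs sequence and CIGAR *consistently*:
  substitutions (2%/base), 1-bp insertions (1%) and deletions (3%) at
  interior positions spaced ≥ 2 bp apart; indels never cross the junction.
  In addition, each junction side of a split read suffers a soft-clip
  "slip" of 1–5 bp with probability 0.4, emulating aligner ambiguity at
  the breakpoint — this, not the indel model, is what makes reported
  breakpoints scatter by a few bp. `error_free = TRUE` disables both, and
  then detected breakpoints equal truth exactly;
* alignments are constructed *analytically* by projecting transcript
  coordinates through the exon structure (splices become N ops): a
  junction-spanning read is emitted as two records (primary = longer
  aligned part, supplementary = shorter, both soft-clipped), a read whose
  junction-side part is shorter than 30 bp is emitted as one record with
  the stub soft-clipped, as a real aligner would, and ~2% of primaries are
  duplicated as secondary records to exercise the secondary filter.

What the simulator does **not** model: homologous/paralogous gene families
(the dominant real-world false-positive source), basecaller-specific error
profiles, chimeric library artifacts, expression-dependent aligner failure,
or reference bias. A green simulation test therefore establishes the
correctness of the coordinate arithmetic, filtering rules, window voting
and ranking — not robustness to paralogy, which the pseudogene and
overlapping-gene exclusions only partially address.

Two deviations from the emulated benchmark design are deliberate: fusion
expression is
drawn directly from the tier ranges (the original averaged the partners'
expression in a reference dataset that is not available here), and cut
points avoid 200 bp at each transcript end — real fusion partners are
kb-scale genes, and a fragment shorter than the 100-bp overlap threshold is
undetectable *by definition of the method*, so allowing it would only
measure the truncation of a uniform distribution, not detector quality.

# Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; GTF input is converted
  once at parse time, and 1-based inclusive coordinates appear only in
  reports and logs.
* Breakpoint averaging rounds half-up (`floor(x + 0.5)`), so reported
  positions are stable integers.
* Window-pair ties and equal-support candidates are broken
  lexicographically; segment ordering within a read uses (M_start, M_end,
  chromosome, position, flag), so results are independent of record order
  in the input file.
* A junction falling outside its gene's span (possible only with exotic
  annotations) is clamped to the terminal window with a warning.
* Empty inputs are legal everywhere: an empty GTF yields an empty
  annotation, an alignment-free BAM yields an empty, header-only report
  with exit success, and zero-fusion simulations yield zero candidates.
* GTF attribute parsing accepts both `key "value";` and `key value;`
  dialects; lines with `end < start` or without `gene_id` are rejected
  individually with warnings rather than failing the file.

# Design decisions that were genuinely open

* **In-memory grouping.** Records are loaded wholesale and grouped with
  data.table rather than streamed; at the scales this package targets
  (desk-scale BAMs, tens of MB) this is the R idiom, and it makes grouping
  trivially order-independent. A `--two-pass` flag is accepted for
  compatibility and documented as a no-op.
* **Top-hit-only gene assignment.** A segment overlapping several genes is
  assigned to the best one only; emitting all combinations would inflate
  support counts. Ambiguous assignments are visible via the returned
  per-segment overlap tables.
* **Pair-level rejection of overlapping genes.** Overlapping gene pairs are
  rejected at support-formation time rather than by deleting genes from the
  annotation, so a gene nested in another can still fuse with a third gene
  elsewhere.
* **Orientation of the reported pair.** The pair itself is unordered; the
  reported `gene_a:gene_b` orientation follows the majority of supports'
  read 5′→3′ order. With mixed-strand cDNA reads this is a convention, not
  an inference of the biological 5′ partner; evaluation is
  orientation-insensitive.

# Limitations

* Fusions involving unannotated genes or novel exons are invisible: the
  gene universe is the GTF (users can extend the GTF to work around this).
* Paralogous genes can absorb each other's reads, producing wrong partners;
  no sequence-similarity screen is applied.
* Fusions contributing < `min_exon_overlap` bases of one partner are
  undetectable at default settings; lowering the thresholds trades recall
  for noise.
* Support counts are raw read counts; no statistical significance model is
  attached (candidates are ranked, not tested).
* Three-or-more-partner fusion transcripts are reported as separate
  consecutive-pair events, not as one complex event.
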
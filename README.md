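# longfusr

Gene fusion detection from long-read RNA-seq alignments, with a synthetic
truth-annotated data simulator and an evaluation harness.

## The problem

A fusion transcript — the product of a translocation, deletion, inversion or
trans-splicing event joining two genes — is read end-to-end by long-read
RNA-seq (Nanopore cDNA/direct-RNA, PacBio Iso-Seq). A spliced aligner maps
such a read as a *chimeric* alignment: one **primary** record for one part of
the read and a **supplementary** record (SAM flag 0x800) for the other, in a
different gene. `longfusr` collects this signal and turns it into a ranked
list of candidate fusions with base-resolution breakpoints. It is aimed at
transcriptomics analysts working with noisy long reads, where per-base error
rates rule out the assembly- and k-mer-based approaches used for short reads.

## Method in brief

Given a SAM/BAM and a GTF annotation:

1. **Multi-segment reads.** Secondary alignments (flag 0x100) are discarded —
   the two sides of a real fusion junction share no read bases, which is the
   supplementary signature. Reads with ≥ 2 remaining segments are kept.
2. **Gene assignment.** Each segment's reference blocks (CIGAR M/=/X, with N
   treated as introns) are intersected with exons per transcript; a segment
   is assigned to the gene maximising exonic overlap, requiring aligned
   length ≥ `min_map_len` (100 bp) and overlap ≥ `min_exon_overlap` (100 bp).
3. **Candidate pairs.** For consecutive segments in read coordinates with
   spans `[M1,M2)` and `[M3,M4)`, the pair is kept when the genes differ,
   the read-space gap satisfies −20 ≤ M3 − M2 ≤ 20, and the gene spans do
   not overlap on the genome (with starts S1 ≤ S2 and ends E1, E2 in 1-based
   coordinates, pairs with E1 − S2 > 0 are excluded as read-through /
   nested-locus artifacts).
4. **Window voting.** Per gene pair, junction coordinates are binned into
   windows of `w` = 50 bp overlapping by `w/2`; the window pair with the most
   supporting reads wins and its mean junction positions (rounded half-up)
   become the reported breakpoints.
5. **Ranking.** Candidates with ≥ `min_support` (2) winning-window reads are
   reported, ordered by support count.

The simulator builds a toy genome and gene models, fuses the 5′ part of one
transcript to the 3′ part of another at random exonic cut points, assigns
TPM-tiered expression (half of fusions > 1000 TPM, half in 10–1000), and
emits reads under a truncation + substitution/indel error model as
analytically constructed split SAM records — so the truth (gene pairs,
breakpoints, per-read provenance) is exact. The evaluation module scores
predictions at the gene-pair level with precision, recall and
F1 = 2·P·R/(P+R), plus breakpoint distances.

## Worked example

```r
library(longfusr)
cfg <- sim_config(seed = 11, n_genes = 40, n_fusions = 5,
                  total_reads = 4000, error_free = TRUE)
sim <- simulate_fusion_dataset(cfg, "demo")
res <- detect_fusions(sim$sam, sim$gtf, detection_params())
print(res)
match_predictions(res$candidates, sim$truth_dt)
```

Output (as printed by the code above):

```
records: 5048; primary/supplementary segments: 4963; multi-segment reads: 963
supports after gene/gap/overlap rules: 940 (rejected - unassigned: 23, same gene: 0, bad gap: 0, overlapping genes: 0)
candidates with >= 2 supporting reads: 5
fusion_result: 5 candidate(s) from 940 support(s)
   gene_a gene_b support_count chrom_a breakpoint_a chrom_b breakpoint_b
1:  G0029  G0020           521   chrS2        79306   chrS2        52494
2:  G0024  G0010           242   chrS3        63879   chrS1        29769
3:  G0028  G0007           162   chrS1        69704   chrS1        23771
4:  G0004  G0039            12   chrS1        13727   chrS3       104897
5:  G0035  G0026             3   chrS2        97486   chrS2        71080
fusion_eval: 5 truth, 5 predicted, 5 TP | precision 1.000 recall 1.000 F1 1.000
```

All five simulated fusions are recovered, ranked by the number of
junction-spanning reads in the winning 50-bp window pair; support counts
track the TPM tier each fusion was assigned. In error-free mode every
breakpoint equals the simulated truth exactly; under the default error model
the median breakpoint error is ~1 bp.

A command-line interface wraps the same pipeline:

```sh
Rscript -e 'longfusr::lf_cli()' simulate --output-dir demo --seed 11
Rscript -e 'longfusr::lf_cli()' detect --bam demo/alignments.sam \
    --gtf demo/annotation.gtf --output-dir demo
Rscript -e 'longfusr::lf_cli()' evaluate --predictions demo/fusions.tsv \
    --truth demo/truth_fusions.tsv
```

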
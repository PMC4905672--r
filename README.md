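# lincseek

Genome-wide identification, classification and stress-response profiling of
long noncoding RNAs (lncRNAs) in polyploid plant genomes, built for the
classic drought RNA-seq design: control (C) → drought (D) → re-watering
(ReW), three biological replicates each.

lncRNAs are transcripts of at least 200 nt with no evident protein-coding
capacity. Starting from assembled transcript models (GTF), transcript
sequences (FASTA) and a fragment-count matrix, `lincseek` provides:

1. **Five-step filtration** into high-confidence lncRNAs:
   size/exon screen (length ≥ 200 nt) → expression screen (FPKM ≥ 0.5 in ≥ 3
   replicates of one condition) → removal of same-strand exonic overlaps
   with known coding transcripts → ORF screen (longest complete ORF
   < 300 nt) → coding-potential screen combining ingested CPC labels and
   Pfam domain hits (union rule: any evidence of coding excludes; an
   ORF-only fallback serves dataset-free runs).
2. **Positional classification** with strict precedence:
   *antisense* (≥ 1 bp exon–exon overlap with a coding gene on the opposite
   strand) ≻ *intronic* (span fully inside a coding gene with zero exonic
   overlap) ≻ *lincRNA* (intergenic); plus subgenome attribution
   (`At_*` / `Dt_*` / unplaced) for allotetraploid genomes.
3. **Expression analysis**: FPKM
   (`counts / (length/10³ · fragments/10⁶)`), a negative-binomial Wald test
   with median-of-ratios normalization, trended method-of-moments dispersion
   shrinkage and Benjamini–Hochberg adjustment (call: padj < 0.05 and
   |log₂FC| ≥ 1), and multi-contrast response patterns — *sustained*
   (DE in D vs C and ReW vs C), *drought-specific* (D only), *delayed*
   (ReW only), each for up and down.
4. **Target prediction**: cis (coding genes within 10 kb / 100 kb genomic
   windows), trans (Pearson |r| ≥ 0.9 on log₂(FPKM+1) profiles), intronic
   lncRNA–host gene concordance, small-RNA precursor summaries from Rfam
   hits (E ≤ 1e-5), and repeat/TE overlap fractions.
5. **A synthetic-data generator** (`synth_config()`, `generate_dataset()`)
   that emulates the full input bundle with planted ground truth — classes,
   coding flags, response patterns, co-expressed pairs, precursor families,
   repeat densities — so every stage is testable offline.

## Worked example

```r
library(lincseek)

cfg <- synth_config(seed = 7)          # ~950 transcripts + 500 coding genes
ds  <- generate_dataset(cfg, "ds7")    # writes GTF/FASTA/counts/aux tables

rep <- run_all(list(
  ref_gtf = "ds7/ref.gtf", transcripts_gtf = "ds7/transcripts.gtf",
  fasta = "ds7/transcripts.fa", counts = "ds7/counts.tsv",
  design = "ds7/design.csv", libsizes = "ds7/libsizes.tsv",
  cpc = "ds7/cpc.tsv", pfam = "ds7/pfam.tsv",
  rfam = "ds7/rfam.tsv", repeats = "ds7/repeats.tsv"), out_dir = "out7")

rep$filtration
#>               step n_input n_retained
#> 1        size_exon     950        870
#> 2       expression     870        770
#> 3    known_overlap     770        650
#> 4              orf     650        530
#> 5 coding_potential     530        530

rep$class_counts
#>   lincRNA  intronic antisense
#>       400        50        80
```

The filtration chain removes exactly the planted decoys (80 sub-200 nt
fragments, 100 silent transcripts, 120 known-isoform overlaps, 120 coding
transcripts), and the surviving 530 lncRNAs classify back to their planted
positional labels. Downstream numbers from the same run: response patterns
`sustained_up 66 / specific_up 41 / delayed_up 47` among 107 drought-up
lncRNAs (planted proportions 0.12/0.08/0.08 of 530), intronic–host
concordance `0.76` (planted rate 0.7595), and a precursor table of
`miRNA 14 (35%) / tRNA 4 (10%) / other 22 (55%)`. `out7/` holds the lncRNA
GTF, per-stage TSV tables and `report.json`.

A command-line driver with `synth`, `all` and `identify` subcommands is
installed under `inst/cli/lincseek.R`.

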
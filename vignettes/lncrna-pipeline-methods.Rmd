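---
title: "Methods: lncRNA identification, classification and drought-response profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lncRNA identification, classification and drought-response profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lincseek)
```

# Scope and model

`lincseek` implements a desk-scale, fully testable version of the standard
genome-wide lncRNA workflow for a polyploid plant under a
control → drought → re-watering (C/D/ReW) RNA-seq design with three
replicates per condition. The package treats the workflow as five composable
stages — filtration, positional classification, expression/differential
expression, response-pattern categorization, and target prediction — each
with a declared contract, and ships a synthetic-data generator that plants
ground truth for every stage.

All internal coordinates are 0-based half-open; GTF's 1-based closed
convention is converted exactly once at the I/O boundary. This makes window
arithmetic (`gap = max(0, max(starts) - min(ends))`) and overlap tests
(`a.start < b.end && b.start < a.end`) free of ±1 adjustments.

# Filtration

Candidates pass five ordered screens; the order is fixed as
size/exon → expression → known-overlap → ORF → coding-potential and every
threshold is a config key:

| key | default | meaning |
|---|---|---|
| `min_len` | 200 nt | the defining lncRNA length floor (inclusive) |
| `min_exons` | 1 | single-exon transcripts are *kept* by default — roughly 46% of plant lincRNAs are single-exon, so an exon floor would discard the majority class |
| `min_fpkm`, `min_reps` | 0.5, 3 | expressed means FPKM ≥ 0.5 in all 3 replicates of at least one condition; the underlying studies do not print this threshold, so it is explicit and conservative |
| `orf_threshold_nt` | 300 nt | longest complete ORF at/above this flags coding potential; plant lncRNA ORFs concentrate below 300 nt |
| `pfam_evalue` | 0.001 | domain-hit threshold applied to the ingested Pfam table |

The known-overlap screen removes candidates with ≥ 1 bp *same-strand
exonic* overlap against coding reference transcripts: those are putative
mRNA isoforms. Opposite-strand and intron-contained candidates deliberately
survive — they are the antisense and intronic classes.

The ORF finder scans the three sense-strand frames for ATG-initiated,
stop-terminated codon runs, reporting length including the stop codon. It is
N-intolerant (an ambiguous base anywhere in a candidate ORF voids it —
ambiguity must not manufacture coding potential), and ties break on the
smallest start offset, then the smallest frame. Reverse-strand frames are
out of scope: assembled transcripts are already oriented.

Coding potential combines evidence by **union**: a CPC "coding" label *or*
any Pfam hit at threshold excludes a transcript. The union reflects the
upstream practice of excluding any transcript with a Pfam hit, and makes the
screen conservative (higher precision for the surviving noncoding set).
When no evidence tables exist, the ORF flag alone decides
(`final = coding iff longest ORF ≥ 300 nt`); because the ORF screen runs as
step 4, the fallback-mode step 5 removes nothing further, and the suite
asserts that evidence generated from the same truth gives identical calls.

# Positional classification

Precedence, applied per surviving lncRNA:

1. **antisense** — ≥ 1 bp exon–exon overlap with a coding gene on the
   opposite strand. Exon-level (not span-level) overlap is required because
   a natural antisense transcript is defined by complementarity of
   transcribed sequence.
2. **intronic** — transcript span *fully contained* in a coding gene's span
   with zero exonic overlap, either strand. Full containment is the
   conservative reading for partial cases the literature leaves undefined;
   a partial span overlap without exon contact falls through to lincRNA.
   Whether intronic lncRNAs may lie on either strand is genuinely open; we
   allow both and expose `same_strand_intronic = TRUE` as the stricter
   switch.
3. **lincRNA** — everything else.

A fourth "overlapping" class is not emitted: in the realized taxonomy the
three classes are exhaustive, and any same-strand span-overlap survivor is
classed lincRNA. Host ties break by largest overlap, then lexicographic
gene id, making classification deterministic. Transcripts with unknown
strand skip the antisense test (with a warning) since the test is undefined
without an orientation.

Subgenome attribution is a pure naming rule (`At_*` → At, `Dt_*` → Dt,
else Un), with lookup-table and function overrides for other conventions.

# Expression and differential expression

FPKM is the defining ratio `count / ((length/10³)·(total/10⁶))`; library
totals are supplied, not inferred, for determinism. The DE test is a
declared stand-in for the heavier isoform-deconvolution machinery of the
original tooling (which is a black box), designed to be fully specified and
property-testable:

* **Normalization** — median-of-ratios size factors over transcripts
  nonzero in all samples (library-size ratio fallback when none exists).
* **Dispersion** — per-transcript method of moments pooled across the two
  groups, clamped to [1e-8, 10], shrunk 50/50 toward an `a0 + a1/μ` trend
  fitted by least squares. The 50/50 weight is the simplest compromise that
  stabilizes n = 3 estimates without erasing genuine heterogeneity.
* **Test** — Wald z on `log2((μ_B + 0.5)/(μ_A + 0.5))` with delta-method NB
  variance; the 0.5 pseudocount bounds the statistic for zero groups.
  All-zero transcripts get p = 1 and log2FC = 0 (never NaN).
* **Calling** — BH-adjusted p < 0.05 *and* |log2FC| ≥ `min_lfc` (default 1,
  settable to 0 for padj-only calling). The fold-change gate also applies in
  the replicate path since the source protocol is ambiguous on that point.
  The published non-replicate rule prints "|log2FC| **<** 1" as its
  threshold — almost certainly a typo, since it would call near-unchanged
  transcripts significant — so the package implements ≥ 1.
* **BH** — implemented directly (step-up with running minimum), tested
  against the brute-force definition rather than delegated, because the
  adjustment is part of the declared contract.

With the stated world (dispersion 0.1, n = 3 vs 3, 4-fold effects), the
suite requires TPR ≥ 0.7 with empirical FDR ≤ 0.10 on planted effects and
type-I ≤ 0.05 + 2·SE on nulls.

Response-pattern categorization is pure set logic over two contrasts
against control: sustained (DE in both), stress-specific (first only),
delayed (second only), per direction. The identities
`|A_up| = sustained_up + specific_up` and `|B_up| = sustained_up +
delayed_up` are asserted at computation time and again before any report is
rendered. Two contrast pairings circulate in this literature (D−C with
ReW−C, and D−C with ReW−D); both are computed, patterns use ReW−C, and
per-class directional fractions use ReW−D, matching each summary's origin.
A transcript up in one contrast and down in the other contributes to both
direction families in the counts and is labelled `mixed` per-transcript.

# Target prediction

* **cis** — strand-agnostic genomic gap between spans (0 when overlapping),
  both directions, same chromosome, windows 10 kb and 100 kb; each pair is
  reported once at the smallest qualifying window. No strand-aware rule is
  imposed because none is established for these windows.
* **trans** — Pearson correlation of log₂(FPKM+1) profiles; default
  |r| ≥ 0.9. The source protocol names neither coefficient nor cutoff; 0.9
  on log-scale profiles over 9 samples is the conventional stringent
  choice. Constant profiles have undefined r and yield no pair (never NaN).
  Note that under the log transform an exactly proportional profile gives
  r slightly below 1; the contract is |r| ≥ threshold, not exact unity.
  Module-detection approaches for > 25-sample designs are out of scope
  (this design has 9).
* **concordance** — intronic lncRNA vs host gene compared by categorical
  D-vs-C call equality (up=up, down=down, ns=ns), matching how "similar
  expression pattern" is phrased for such pairs; a profile-correlation
  alternative would measure something else and is not the default.
* **precursors** — Rfam hits filtered at E ≤ 1e-5, one best (lowest-E)
  family per lncRNA, percentages half-up to one decimal.

# Rounding and reporting

Printed class percentages round half-up (not banker's): one decimal at
≥ 10%, two decimals below 10% — the convention of the summaries this
package reproduces (92.3% and 6.27% from counts 9,989/153/678 of 10,820) —
exposed as `pct_digits`. Every percentage in a report is recomputable from
the printed counts, and `render_report()` refuses to render a report whose
internal identities fail.

# The synthetic world

The generator's defaults are the stated world, fixed once:

* lncRNA spliced lengths lognormal (meanlog `log(686) − 0.245`, sdlog 0.7,
  clamped to 200–12,057 nt) so the mean sits near 686 nt with the observed
  range; exon counts with P(1 exon) = 0.46 tailing to 9.
* Coding genes with 2–8 exons placed sequentially (no same-strand overlap
  by construction); intronic lncRNAs embedded in an enlarged first intron;
  antisense lncRNAs starting inside the host's first exon on the opposite
  strand; decoy families for each filtration step (sub-200 nt fragments,
  silent transcripts, known-isoform copies, coding novel transcripts).
* NB counts with dispersion 0.1 and 4-fold multiplicative condition
  effects — detectable at n = 3 yet realistic; planted pattern proportions
  (12/8/8% up, 8/6/5% down, 53% flat) give a DE landscape of the right
  order without being tuned to any published total.
* Intronic–host concordance planted at 0.7595; trans partners planted on
  condition-responsive lncRNAs with counts mirroring the lncRNA's realized
  counts (mean `2·(count+1)`, dispersion 0.02) — co-expression at
  |r| ≥ 0.9 over 9 samples is only physically present when expression
  varies, so planting partners on flat profiles would test noise, not
  co-expression.
* Noncoding sequences are random DNA with any chance ORF reaching 300 nt
  broken by an in-frame stop at its midpoint; coding sequences carry a
  planted ATG + ≥ 98 non-stop codons + stop. Repeat intervals are planted
  per family at densities 0.53/0.30/0.10; Rfam decoys sit strictly above
  the E-value cutoff.

Everything is deterministic given the seed (byte-identical reruns are a
test). What a green suite establishes: the algebra, contracts and
recoverability of every stage on clean, well-separated synthetic data. What
it does not establish: performance on real polyploid data — homeologous
sequence similarity, mapping ambiguity, assembly fragmentation, overlapping
gene models, and library-preparation biases are all absent from the
generator, and the published genome-scale totals (e.g. 10,820 lncRNAs)
derive from unreleased reads and are not reproducible here. Acceptance
checks therefore exercise the published *arithmetic* (set-logic counts,
percentages) through the real operations at the published magnitudes.

# Known limitations

* The DE stand-in is not the original isoform-level likelihood; its
  calibration is validated only under the stated NB world.
* CPC and Pfam internals are out of scope; their outputs are ingested.
* Conservation scoring, GO/KEGG enrichment, protein interaction networks,
  splicing and variant analyses are deliberately out of scope.
* The four-class taxonomy variant with an explicit "overlapping" class is
  not emitted (see classification rationale above).
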
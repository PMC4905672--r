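ref_one_gene <- function() {
  annotation_set(
    data.table::data.table(
      transcript_id = "G1.t1", gene_id = "G1", chrom = "At_chr1", strand = "+",
      start = c(1000L, 5000L), end = c(2000L, 6000L)),
    biotypes = c(G1 = "coding"))
}

test_that("positional classes follow the definitions and precedence", {
  ref <- ref_one_gene()

  # no gene context -> lincRNA
  lone <- annotation_set(simple_exons("lnc1", chrom = "Dt_chr9", starts = 100L))
  expect_equal(classify_lncrnas(lone, ref)$positional_class, "lincRNA")

  # opposite-strand exonic overlap -> antisense with host
  anti <- annotation_set(simple_exons("lnc2", strand = "-", starts = 1500L))
  row <- classify_lncrnas(anti, ref)
  expect_equal(row$positional_class, "antisense")
  expect_equal(row$host_gene_id, "G1")

  # fully inside the intron, no exon contact -> intronic (either strand)
  intr <- annotation_set(simple_exons("lnc3", strand = "-", starts = 2500L))
  row <- classify_lncrnas(intr, ref)
  expect_equal(row$positional_class, "intronic")
  expect_equal(row$host_gene_id, "G1")

  # same-strand-only switch turns that call into lincRNA
  row <- classify_lncrnas(intr, ref, same_strand_intronic = TRUE)
  expect_equal(row$positional_class, "lincRNA")

  # precedence: inside the gene span AND touching an exon opposite-strand
  both <- annotation_set(
    data.table::data.table(transcript_id = "lnc4", gene_id = "x", chrom = "At_chr1",
                           strand = "-", start = c(1800L, 2500L),
                           end = c(1900L, 3000L)))
  expect_equal(classify_lncrnas(both, ref)$positional_class, "antisense")

  # immediately downstream of the gene, no overlap -> lincRNA
  near <- annotation_set(simple_exons("lnc5", strand = "-", starts = 6500L))
  expect_equal(classify_lncrnas(near, ref)$positional_class, "lincRNA")

  # unknown strand: antisense test skipped with a warning
  dot <- annotation_set(simple_exons("lnc6", strand = ".", starts = 1500L))
  expect_warning(row <- classify_lncrnas(dot, ref), "antisense")
  expect_equal(row$positional_class, "lincRNA")
})

test_that("planted classes are recovered exactly and survive translation", {
  cfg <- synth_config(seed = 23, n_coding_genes = 320, n_linc = 180,
                      n_intronic = 50, n_anti = 70, n_isoform = 0,
                      n_short = 0, n_silent = 0, n_coding_novel = 0)
  ann <- generate_annotation(cfg)
  lnc_ids <- ann$truth[is_lnc == TRUE, id]
  lnc <- subset_transcripts(ann$transcripts, lnc_ids)
  rec <- classify_lncrnas(lnc, ann$reference)
  truth <- ann$truth[match(rec$transcript_id, id)]
  expect_equal(rec$positional_class, truth$class)
  host_known <- !is.na(truth$host_gene_id)
  expect_equal(rec$host_gene_id[host_known], truth$host_gene_id[host_known])
  # partition: one class per record, counts sum to total
  expect_true(all(rec$positional_class %in% c("lincRNA", "intronic", "antisense")))
  expect_equal(sum(summarize_classes(rec)$counts), nrow(rec))

  # translation invariance
  shift <- function(a, k) {
    ex <- data.table::copy(a$exons)
    ex[, `:=`(start = start + k, end = end + k)]
    bt <- stats::setNames(a$genes$biotype, a$genes$gene_id)
    annotation_set(ex, biotypes = bt)
  }
  rec2 <- classify_lncrnas(shift(lnc, 12345L), shift(ann$reference, 12345L))
  expect_equal(rec2$positional_class, rec$positional_class)
})

test_that("subgenome attribution follows the naming rule", {
  expect_equal(assign_subgenome(c("At_chr9", "Dt_chr3", "scaffold123")),
               c("At", "Dt", "Un"))
  # custom lookup rule over A01..A13 / D01..D13
  rule <- stats::setNames(rep(c("At", "Dt"), each = 13),
                          c(sprintf("A%02d", 1:13), sprintf("D%02d", 1:13)))
  chroms <- c(sprintf("A%02d", 1:13), sprintf("D%02d", 1:13))
  expect_equal(assign_subgenome(chroms, rule), rep(c("At", "Dt"), each = 13))
  expect_equal(assign_subgenome("chrX", rule), "Un")
  # function rule
  expect_equal(assign_subgenome("9A", function(x) ifelse(grepl("A", x), "At", "Un")),
               "At")
})

test_that("class summaries reproduce printed-style percentages", {
  rec <- data.table::data.table(
    transcript_id = sprintf("t%05d", 1:10820),
    positional_class = rep(c("lincRNA", "intronic", "antisense"),
                           c(9989, 153, 678)),
    length = 686L, n_exons = 1L)
  s <- summarize_classes(rec)
  expect_equal(unname(s$counts), c(9989L, 153L, 678L))
  expect_equal(unname(s$percentages[["lincRNA"]]), 92.3)
  expect_equal(unname(s$percentages[["antisense"]]), 6.27)
  expect_equal(unname(format_pct(100 * 678 / 10820, digits = 2)), 6.27)

  single <- summarize_classes(rec[1])
  expect_equal(unname(single$percentages[["lincRNA"]]), 100.0)

  empty <- summarize_classes(rec[0])
  expect_equal(sum(empty$counts), 0L)
})

test_that("repeat overlap fractions count span overlaps per family", {
  rec <- data.table::data.table(
    transcript_id = c("l1", "l2"), chrom = "At_chr1",
    start = c(1000L, 9000L), end = c(2000L, 9500L), subgenome = "At")
  none <- data.table::data.table(chrom = character(), start = integer(),
                                 end = integer(), label = character())
  expect_true(all(repeat_overlap_summary(rec, none)$fraction == 0))

  reps <- data.table::data.table(chrom = "At_chr1", start = 1500L, end = 1600L,
                                 label = "LTR/Copia")
  out <- repeat_overlap_summary(rec, reps)
  expect_equal(out[family == "LTR/Copia" & subgenome == "all", fraction], 0.5)

  # planted rate: exactly 80 of 200 lncRNAs get a Satellite interval
  rec200 <- data.table::data.table(
    transcript_id = sprintf("l%03d", 1:200), chrom = "Dt_chr1",
    start = seq(0L, by = 10000L, length.out = 200), subgenome = "Dt")
  rec200[, end := start + 600L]
  set.seed(77)
  hit <- sample(200, 80)
  sat <- data.table::data.table(chrom = "Dt_chr1",
                                start = rec200$start[hit] + 10L,
                                end = rec200$start[hit] + 60L,
                                label = "Satellite")
  out <- repeat_overlap_summary(rec200, sat)
  expect_equal(out[family == "Satellite" & subgenome == "all", fraction], 0.4)
  expect_equal(out[family == "Satellite" & subgenome == "Dt", fraction], 0.4)
})
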
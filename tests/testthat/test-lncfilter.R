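make_expr <- function(counts) {
  design <- data.frame(
    sample_id = colnames(counts),
    condition = sub("_[0-9]+$", "", colnames(counts)),
    replicate = as.integer(sub("^.*_", "", colnames(counts))))
  expression_matrix(counts, design,
                    lengths = stats::setNames(rep(1000, nrow(counts)), rownames(counts)),
                    lib_sizes = stats::setNames(rep(1e7, ncol(counts)), colnames(counts)))
}

test_that("step 1 applies the 200 nt floor inclusively", {
  ann <- annotation_set(simple_exons(c("a", "b"), lens = c(199L, 200L)))
  s1 <- step1_size_exon(ann)
  expect_identical(s1$retained, "b")
  expect_equal(s1$entry$removed_ids, "a")

  empty <- annotation_set(simple_exons(character(), lens = integer()))
  expect_equal(step1_size_exon(empty)$entry$n_input, 0L)

  set.seed(5)
  lens <- sample(150:250, 100, replace = TRUE)
  ann <- annotation_set(simple_exons(sprintf("t%03d", 1:100), lens = lens))
  expect_equal(length(step1_size_exon(ann)$retained), sum(lens >= 200))
})

test_that("step 2 keeps transcripts expressed in one full condition", {
  samples <- c(paste0("C_", 1:3), paste0("D_", 1:3), paste0("ReW_", 1:3))
  counts <- matrix(0L, nrow = 3, ncol = 9,
                   dimnames = list(c("zero", "drought", "weak"), samples))
  # with length 1000 and totals 1e7, FPKM = count / 10
  counts["drought", paste0("D_", 1:3)] <- c(6L, 7L, 9L)   # FPKM 0.6/0.7/0.9
  counts["weak", paste0("D_", 1:3)] <- c(6L, 7L, 2L)      # only 2 reps >= 0.5
  expr <- make_expr(counts)
  s2 <- step2_expression(rownames(counts), expr)
  expect_identical(s2$retained, "drought")
  expect_true(all(c("zero", "weak") %in% s2$entry$removed_ids))

  expect_error(step2_expression(c("drought", "ghost"), expr), "ghost")
})

test_that("step 2 recovers a planted expressed/silent split", {
  set.seed(31)
  ids <- sprintf("t%03d", 1:100)
  expressed <- ids[1:40]
  counts <- matrix(0L, 100, 9,
                   dimnames = list(ids, c(paste0("C_", 1:3), paste0("D_", 1:3),
                                          paste0("ReW_", 1:3))))
  counts[expressed, ] <- matrix(rpois(40 * 9, 50), 40, 9)
  s2 <- step2_expression(ids, make_expr(counts))
  expect_setequal(s2$retained, expressed)
})

test_that("step 3 removes same-strand exonic overlaps only", {
  ref <- annotation_set(
    data.table::data.table(
      transcript_id = "G1.t1", gene_id = "G1", chrom = "At_chr1", strand = "+",
      start = c(1000L, 3000L), end = c(1500L, 3600L)),
    biotypes = c(G1 = "coding"))
  cand <- annotation_set(data.table::rbindlist(list(
    simple_exons("same_strand_exonic", starts = 1200L, lens = 400L),
    simple_exons("opposite_strand", strand = "-", starts = 1200L, lens = 400L),
    simple_exons("intronic_same_strand", starts = 1700L, lens = 600L),
    simple_exons("far_away", starts = 50000L, lens = 400L))))
  ids <- cand$transcripts$transcript_id
  s3 <- step3_known_overlap(cand, ids, ref)
  expect_setequal(s3$retained,
                  c("opposite_strand", "intronic_same_strand", "far_away"))

  # 10 candidates, 4 planted isoform overlaps
  over <- simple_exons(sprintf("iso%d", 1:4), starts = rep(1100L, 4), lens = 300L)
  clean <- simple_exons(sprintf("ok%d", 1:6), starts = 10000L + (0:5) * 5000L,
                        lens = 400L)
  cand10 <- annotation_set(rbind(over, clean))
  s3 <- step3_known_overlap(cand10, cand10$transcripts$transcript_id, ref)
  expect_equal(length(s3$retained), 6L)
})

test_that("coding potential applies the union rule with ORF fallback", {
  pfam <- data.table::data.table(query_id = "t1", label = "Pkinase",
                                 score = NA_real_, e_value = 1e-6)
  cp <- coding_potential(c("t1", "t2"), pfam_records = pfam,
                         orf_lengths = c(t1 = 90L, t2 = 90L))
  expect_equal(cp$calls[transcript_id == "t1", final], "coding")
  expect_equal(cp$calls[transcript_id == "t2", final], "noncoding")

  # pfam hit above the e-value threshold does not flag coding
  weak <- data.table::data.table(query_id = "t1", label = "Pkinase",
                                 score = NA_real_, e_value = 0.5)
  cp <- coding_potential("t1", pfam_records = weak, orf_lengths = c(t1 = 90L))
  expect_equal(cp$calls$final, "noncoding")

  # fallback mode: ORF length decides
  cp <- coding_potential(c("a", "b"), orf_lengths = c(a = 90L, b = 300L))
  expect_equal(cp$calls$final, c("noncoding", "coding"))

  expect_error(coding_potential("a"), "cannot call")
})

test_that("coding potential recovers planted evidence and Venn counts", {
  coding_ids <- sprintf("c%02d", 1:50)
  noncoding_ids <- sprintf("n%02d", 1:50)
  ids <- c(coding_ids, noncoding_ids)
  # planted evidence: 20 both, 15 CPC-only, 15 Pfam-only
  cpc_pos <- coding_ids[1:35]
  pfam_pos <- coding_ids[c(1:20, 36:50)]
  cpc <- data.table::data.table(query_id = ids,
                                label = ifelse(ids %in% cpc_pos, "coding", "noncoding"),
                                score = 1, e_value = NA_real_)
  pfam <- data.table::data.table(query_id = pfam_pos, label = "dom",
                                 score = NA_real_, e_value = 1e-8)
  orf <- stats::setNames(ifelse(ids %in% coding_ids, 450L, 120L), ids)
  cp <- coding_potential(ids, cpc, pfam, orf_lengths = orf)
  expect_setequal(cp$calls[final == "coding", transcript_id], coding_ids)
  expect_equal(unname(cp$venn), c(15L, 15L, 20L))

  # fallback mode agrees when evidence was generated from the same truth
  cp_fb <- coding_potential(ids, orf_lengths = orf)
  expect_identical(cp_fb$calls$final, cp$calls$final)
})

test_that("full identification recovers planted lncRNAs and chains counts", {
  cfg <- synth_config(seed = 19, n_coding_genes = 120, n_linc = 70,
                      n_intronic = 12, n_anti = 18, n_isoform = 30,
                      n_short = 20, n_silent = 25, n_coding_novel = 30)
  ann <- generate_annotation(cfg)
  seqs <- generate_sequences(ann, cfg)
  cnt <- generate_counts(ann, cfg)
  expr <- expression_matrix(cnt$counts, cnt$design,
    lengths = stats::setNames(ann$transcripts$transcripts$length,
                              ann$transcripts$transcripts$transcript_id),
    lib_sizes = cnt$lib_sizes)
  res <- run_identification(ann$transcripts, ann$reference, expr, seqs)
  expect_setequal(res$lnc$transcripts$transcript_id,
                  ann$truth[is_lnc == TRUE, id])
  # five steps, chained counts, monotone retention
  steps <- as.data.frame(res$report)
  expect_equal(nrow(steps), 5L)
  expect_true(all(steps$n_retained <= steps$n_input))
  expect_equal(steps$n_input[-1], steps$n_retained[-5])

  # degenerate threshold still yields a full five-step report
  res0 <- run_identification(ann$transcripts, ann$reference, expr, seqs,
                             config = list(min_len = 1e9))
  expect_equal(n_transcripts(res0$lnc), 0L)
  expect_equal(nrow(as.data.frame(res0$report)), 5L)

  # idempotence: survivors resubmitted survive unchanged
  res2 <- run_identification(res$lnc, ann$reference, expr,
                             seqs[res$lnc$transcripts$transcript_id])
  expect_setequal(res2$lnc$transcripts$transcript_id,
                  res$lnc$transcripts$transcript_id)

  # order stability: shuffling the exon table does not change the survivors
  shuf <- annotation_set(ann$transcripts$exons[sample(.N)])
  res3 <- run_identification(shuf, ann$reference, expr, seqs)
  expect_setequal(res3$lnc$transcripts$transcript_id,
                  res$lnc$transcripts$transcript_id)
})
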
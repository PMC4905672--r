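# Five-step filtration of assembled transcripts into high-confidence lncRNAs:
#   1. size/exon screen (>= 200 nt spliced length by default)
#   2. expression screen (FPKM floor in enough replicates of one condition)
#   3. removal of same-strand exonic overlaps with known coding transcripts
#   4. ORF screen (longest complete ORF under a coding-length threshold)
#   5. coding-potential screen (CPC label / Pfam domain evidence, union rule)

#' Default filtration configuration
#'
#' @return Named list of thresholds: `min_len` (nt, 200), `min_exons` (1),
#'   `min_fpkm` (0.5), `min_reps` (3), `orf_threshold_nt` (300),
#'   `pfam_evalue` (0.001).
#' @export
filter_config <- function() {
  list(min_len = 200L, min_exons = 1L, min_fpkm = 0.5, min_reps = 3L,
       orf_threshold_nt = 300L, pfam_evalue = 1e-3)
}

new_report_entry <- function(step, input_ids, retained_ids) {
  list(step = step,
       n_input = length(input_ids),
       n_retained = length(retained_ids),
       removed_ids = setdiff(input_ids, retained_ids))
}

#' Assemble a filtration report from step entries
#' @param entries list of step entries as produced by the step functions
#' @return `filtration_report` object; validates that each step's retained
#'   count equals the next step's input count.
#' @export
filtration_report <- function(entries) {
  if (length(entries) > 1L) {
    for (k in seq_len(length(entries) - 1L)) {
      if (entries[[k]]$n_retained != entries[[k + 1L]]$n_input)
        stop("filtration chain broken between steps ", entries[[k]]$step,
             " and ", entries[[k + 1L]]$step)
    }
  }
  structure(entries, class = "filtration_report")
}

#' @export
print.filtration_report <- function(x, ...) {
  for (e in x)
    cat(sprintf("%-16s %6d -> %6d (removed %d)\n",
                e$step, e$n_input, e$n_retained, e$n_input - e$n_retained))
  invisible(x)
}

#' Filtration report as a data frame
#' @param x filtration_report
#' @param ... unused
#' @export
as.data.frame.filtration_report <- function(x, ...) {
  data.frame(step = vapply(x, `[[`, "", "step"),
             n_input = vapply(x, `[[`, 0L, "n_input"),
             n_retained = vapply(x, `[[`, 0L, "n_retained"))
}

#' Step 1: size / exon-count screen
#'
#' Retains transcripts whose spliced length is at least `min_len` (the
#' defining 200 nt floor for lncRNAs). Single-exon transcripts are retained
#' by default; `min_exons` is exposed for stricter runs.
#'
#' @param ann annotation_set of candidate transcripts
#' @param min_len minimum spliced length in nt
#' @param min_exons minimum exon count
#' @return list(retained = character ids, entry = report entry)
#' @export
step1_size_exon <- function(ann, min_len = 200L, min_exons = 1L) {
  tx <- ann$transcripts
  keep <- tx[length >= min_len & n_exons >= min_exons, transcript_id]
  list(retained = keep, entry = new_report_entry("size_exon", tx$transcript_id, keep))
}

#' Step 2: expression screen
#'
#' Retains transcripts with FPKM >= `min_fpkm` in at least `min_reps`
#' replicates of at least one condition.
#'
#' @param ids candidate transcript ids
#' @param expr an [expression_matrix()] covering all candidates
#' @param min_fpkm FPKM floor
#' @param min_reps replicate count floor within a single condition
#' @return list(retained, entry)
#' @export
step2_expression <- function(ids, expr, min_fpkm = 0.5, min_reps = 3L) {
  missing_ids <- setdiff(ids, rownames(expr$counts))
  if (length(missing_ids))
    stop("transcripts missing from expression matrix: ",
         paste(utils::head(missing_ids, 5L), collapse = ", "))
  # FPKM only for the candidates, so gene-level rows without lengths are fine
  fpkm <- compute_fpkm(expr$counts[ids, , drop = FALSE],
                       expr$lengths[ids], expr$lib_sizes)
  conds <- unique(expr$design$condition)
  pass <- rep(FALSE, length(ids))
  for (cn in conds) {
    cols <- expr$design$sample_id[expr$design$condition == cn]
    nhit <- rowSums(fpkm[, cols, drop = FALSE] >= min_fpkm)
    pass <- pass | (nhit >= min_reps)
  }
  keep <- ids[pass]
  list(retained = keep, entry = new_report_entry("expression", ids, keep))
}

#' Step 3: removal of known coding-isoform overlaps
#'
#' Removes candidates with >= 1 bp same-strand exonic overlap with an exon of
#' a coding reference transcript: such candidates are putative mRNA isoforms.
#' Opposite-strand overlaps and intron-contained candidates survive for
#' positional classing.
#'
#' @param ann annotation_set holding the candidates
#' @param ids candidate transcript ids
#' @param reference annotation_set of the known annotation (genes with
#'   biotype `"coding"` define the coding exon space)
#' @return list(retained, entry)
#' @export
step3_known_overlap <- function(ann, ids, reference) {
  coding_genes <- reference$genes[biotype == "coding", gene_id]
  ref_ex <- reference$exons[gene_id %in% coding_genes]
  if (!nrow(ref_ex) || !length(ids)) {
    return(list(retained = ids, entry = new_report_entry("known_overlap", ids, ids)))
  }
  cand_ex <- ann$exons[transcript_id %in% ids]
  cand_gr <- GenomicRanges::GRanges(cand_ex$chrom,
    IRanges::IRanges(cand_ex$start + 1L, cand_ex$end), strand = cand_ex$strand)
  ref_gr <- GenomicRanges::GRanges(ref_ex$chrom,
    IRanges::IRanges(ref_ex$start + 1L, ref_ex$end), strand = ref_ex$strand)
  hits <- .find_overlaps(cand_gr, ref_gr, ignore.strand = FALSE)
  overlapping <- unique(cand_ex$transcript_id[S4Vectors::queryHits(hits)])
  keep <- setdiff(ids, overlapping)
  list(retained = keep, entry = new_report_entry("known_overlap", ids, keep))
}

#' Coding-potential decision combining CPC, Pfam and ORF evidence
#'
#' Evidence mode (any table supplied): a transcript is called coding if its
#' CPC label is "coding" OR it has any Pfam domain hit passing the e-value
#' threshold — the union rule; a Pfam hit alone suffices for exclusion.
#' Fallback mode (no tables): coding iff the longest complete ORF reaches
#' `orf_threshold_nt`.
#'
#' @param ids transcript ids to call
#' @param cpc_records,pfam_records normalized hit records from
#'   [read_tool_table()], or `NULL`
#' @param orf_lengths named integer vector of longest-ORF lengths (nt);
#'   required in fallback mode
#' @param orf_threshold_nt ORF length at/above which a transcript is flagged
#'   as coding (default 300)
#' @param pfam_evalue Pfam e-value threshold (default 0.001, applied to both
#'   sequence and domain e-values as supplied in the table)
#' @return list(calls = data.table(transcript_id, cpc_coding, pfam_hit,
#'   orf_flag, final), venn = counts of CPC-only / Pfam-only / both among
#'   coding calls in evidence mode)
#' @export
coding_potential <- function(ids, cpc_records = NULL, pfam_records = NULL,
                             orf_lengths = NULL, orf_threshold_nt = 300L,
                             pfam_evalue = 1e-3) {
  evidence_mode <- !is.null(cpc_records) || !is.null(pfam_records)
  if (!evidence_mode && is.null(orf_lengths))
    stop("no CPC/Pfam tables and no sequences/ORF lengths: cannot call coding potential")
  cpc_coding <- rep(NA, length(ids))
  if (!is.null(cpc_records)) {
    coding_ids <- unique(cpc_records$query_id[cpc_records$label == "coding"])
    seen <- ids %in% cpc_records$query_id
    cpc_coding <- ifelse(seen, ids %in% coding_ids, NA)
  }
  pfam_hit <- rep(NA, length(ids))
  if (!is.null(pfam_records)) {
    hit_ids <- unique(pfam_records$query_id[pfam_records$e_value <= pfam_evalue])
    pfam_hit <- ids %in% hit_ids
  }
  orf_flag <- rep(NA, length(ids))
  if (!is.null(orf_lengths)) {
    orf_flag <- unname(orf_lengths[ids]) >= orf_threshold_nt
    if (anyNA(orf_flag))
      stop("ORF lengths missing for: ",
           paste(utils::head(ids[is.na(orf_flag)], 5L), collapse = ", "))
  }
  if (evidence_mode) {
    final <- ifelse((!is.na(cpc_coding) & cpc_coding) |
                    (!is.na(pfam_hit) & pfam_hit), "coding", "noncoding")
  } else {
    final <- ifelse(orf_flag, "coding", "noncoding")
  }
  cpc_t <- !is.na(cpc_coding) & cpc_coding
  pfam_t <- !is.na(pfam_hit) & pfam_hit
  venn <- c(cpc_only = sum(cpc_t & !pfam_t),
            pfam_only = sum(!cpc_t & pfam_t),
            both = sum(cpc_t & pfam_t))
  calls <- data.table::data.table(
    transcript_id = ids, cpc_coding = cpc_coding, pfam_hit = pfam_hit,
    orf_flag = orf_flag, final = final)
  list(calls = calls, venn = venn)
}

#' Run the full five-step lncRNA identification
#'
#' Applies, in order: size/exon -> expression -> known-isoform overlap ->
#' ORF -> coding potential. The returned report always has exactly five
#' steps with chained counts.
#'
#' @param ann annotation_set of assembled candidate transcripts
#' @param reference annotation_set of the known annotation
#' @param expr [expression_matrix()] covering the candidates
#' @param sequences named character vector of candidate transcript sequences
#' @param config list of thresholds, see [filter_config()]
#' @param cpc_records,pfam_records optional normalized tool tables; when both
#'   are absent the coding-potential step falls back to the ORF rule (and
#'   removes nothing beyond step 4)
#' @return list(lnc = annotation_set of surviving lncRNAs, report =
#'   [filtration_report()], coding = the [coding_potential()] result,
#'   orf_lengths = named vector for survivors of step 3)
#' @export
run_identification <- function(ann, reference, expr, sequences,
                               config = filter_config(),
                               cpc_records = NULL, pfam_records = NULL) {
  cfg <- utils::modifyList(filter_config(), config)
  s1 <- step1_size_exon(ann, min_len = cfg$min_len, min_exons = cfg$min_exons)
  s2 <- step2_expression(s1$retained, expr, min_fpkm = cfg$min_fpkm,
                         min_reps = cfg$min_reps)
  s3 <- step3_known_overlap(ann, s2$retained, reference)
  ids <- s3$retained
  missing_seq <- setdiff(ids, names(sequences))
  if (length(missing_seq))
    stop("sequences missing for: ", paste(utils::head(missing_seq, 5L), collapse = ", "))
  orf_len <- longest_orf_lengths(sequences[ids])
  keep4 <- ids[orf_len < cfg$orf_threshold_nt]
  s4 <- list(retained = keep4, entry = new_report_entry("orf", ids, keep4))
  cp <- coding_potential(keep4, cpc_records = cpc_records,
                         pfam_records = pfam_records,
                         orf_lengths = orf_len,
                         orf_threshold_nt = cfg$orf_threshold_nt,
                         pfam_evalue = cfg$pfam_evalue)
  keep5 <- cp$calls[final == "noncoding", transcript_id]
  s5 <- list(retained = keep5,
             entry = new_report_entry("coding_potential", keep4, keep5))
  report <- filtration_report(list(s1$entry, s2$entry, s3$entry, s4$entry, s5$entry))
  list(lnc = subset_transcripts(ann, keep5), report = report,
       coding = cp, orf_lengths = orf_len)
}
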
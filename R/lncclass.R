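# Positional classification of identified lncRNAs, subgenome attribution,
# class feature summaries and repeat/TE overlap statistics.
#
# Class precedence (each lncRNA gets exactly one class):
#   1. antisense: >= 1 bp exonic overlap with a coding exon on the OPPOSITE
#      strand (natural antisense transcript; complementarity of transcribed
#      sequence is the defining feature, so span overlap is not enough).
#   2. intronic: transcript span fully contained within a coding gene's span
#      with zero exonic overlap (i.e. it lives inside an intron); either
#      strand by default.
#   3. lincRNA: everything else (intergenic).
# Same-strand span overlaps that survive filtration are logged and classed
# lincRNA; a fourth "overlapping" class is deliberately not emitted.

#' Classify lncRNAs by position relative to coding genes
#'
#' @param lnc_ann annotation_set of identified lncRNAs
#' @param reference annotation_set of the known annotation; genes with
#'   biotype `"coding"` define the coding gene space
#' @param same_strand_intronic if `TRUE`, intronic calls additionally require
#'   the lncRNA to lie on the host gene's strand
#' @return data.table with `transcript_id`, `positional_class` (lincRNA /
#'   intronic / antisense), `host_gene_id` (`NA` for lincRNA), `chrom`,
#'   `strand`, span `start`/`end`, `length`, `n_exons`. Host ties are broken
#'   by largest exonic (antisense) or span (intronic) overlap, then
#'   lexicographically smallest `gene_id`. Transcripts with strand `"."` skip
#'   the antisense test with a warning.
#' @export
classify_lncrnas <- function(lnc_ann, reference, same_strand_intronic = FALSE) {
  tx <- data.table::copy(lnc_ann$transcripts)
  out <- tx[, list(transcript_id, chrom, strand, start, end, length, n_exons)]
  out[, positional_class := "lincRNA"]
  out[, host_gene_id := NA_character_]
  if (!nrow(out)) return(out[])
  if (any(out$strand == "."))
    warning("transcripts with strand '.' skip the antisense test: ",
            paste(utils::head(out[strand == ".", transcript_id], 3L), collapse = ", "))
  coding <- reference$genes[biotype == "coding"]
  if (!nrow(coding)) return(out[])
  ref_ex <- reference$exons[gene_id %in% coding$gene_id]

  lex <- lnc_ann$exons
  lnc_ex_gr <- GenomicRanges::GRanges(lex$chrom,
    IRanges::IRanges(lex$start + 1L, lex$end))
  ref_ex_gr <- GenomicRanges::GRanges(ref_ex$chrom,
    IRanges::IRanges(ref_ex$start + 1L, ref_ex$end))
  ex_hits <- .find_overlaps(lnc_ex_gr, ref_ex_gr)
  qh <- S4Vectors::queryHits(ex_hits); sh <- S4Vectors::subjectHits(ex_hits)
  ov_w <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(lnc_ex_gr)[qh], IRanges::ranges(ref_ex_gr)[sh]))
  exov <- data.table::data.table(
    transcript_id = lex$transcript_id[qh],
    lnc_strand = lex$strand[qh],
    gene_id = ref_ex$gene_id[sh],
    gene_strand = ref_ex$strand[sh],
    width = ov_w)

  # --- antisense: opposite-strand exon-exon overlap -------------------------
  anti <- exov[lnc_strand %in% c("+", "-") & gene_strand %in% c("+", "-") &
                 lnc_strand != gene_strand]
  if (nrow(anti)) {
    anti <- anti[, list(width = sum(width)), by = list(transcript_id, gene_id)]
    data.table::setorder(anti, transcript_id, -width, gene_id)
    host <- anti[, list(host_gene_id = gene_id[1L]), by = transcript_id]
    out[host, on = "transcript_id",
        `:=`(positional_class = "antisense", host_gene_id = i.host_gene_id)]
  }

  # --- intronic: span within gene span, zero exonic overlap ----------------
  todo <- out[positional_class == "lincRNA"]
  if (nrow(todo)) {
    span_gr <- GenomicRanges::GRanges(todo$chrom,
      IRanges::IRanges(todo$start + 1L, todo$end))
    gene_gr <- GenomicRanges::GRanges(coding$chrom,
      IRanges::IRanges(coding$start + 1L, coding$end))
    win <- .find_overlaps(span_gr, gene_gr, type = "within")
    if (length(win)) {
      cand <- data.table::data.table(
        transcript_id = todo$transcript_id[S4Vectors::queryHits(win)],
        lnc_strand = todo$strand[S4Vectors::queryHits(win)],
        lnc_len = todo$end[S4Vectors::queryHits(win)] -
                  todo$start[S4Vectors::queryHits(win)],
        gene_id = coding$gene_id[S4Vectors::subjectHits(win)],
        gene_strand = coding$strand[S4Vectors::subjectHits(win)])
      # disqualify hosts with any exon-level contact (either strand)
      cand <- cand[!exov[, list(transcript_id, gene_id)],
                   on = c("transcript_id", "gene_id")]
      if (same_strand_intronic)
        cand <- cand[lnc_strand == gene_strand]
      if (nrow(cand)) {
        data.table::setorder(cand, transcript_id, gene_id)
        host <- cand[, list(host_gene_id = gene_id[1L]), by = transcript_id]
        out[host, on = "transcript_id",
            `:=`(positional_class = "intronic", host_gene_id = i.host_gene_id)]
      }
    }
  }
  out[]
}

#' Classify a single transcript
#' @param lnc_ann annotation_set containing the transcript
#' @param transcript_id the transcript to classify
#' @param reference reference annotation_set
#' @return list(positional_class, host_gene_id)
#' @export
classify_position <- function(lnc_ann, transcript_id, reference) {
  sub <- subset_transcripts(lnc_ann, transcript_id)
  row <- classify_lncrnas(sub, reference)
  list(positional_class = row$positional_class[1L],
       host_gene_id = row$host_gene_id[1L])
}

#' Attribute chromosomes to subgenomes
#'
#' Allotetraploid upland cotton carries two subgenomes (At and Dt) plus
#' unplaced scaffolds. The default rule maps chromosome-name prefixes:
#' `At_*` to `At`, `Dt_*` to `Dt`, anything else to `Un`.
#'
#' @param chrom character vector of chromosome names
#' @param rule `NULL` for the prefix default, a named character vector of
#'   exact name -> label lookups (missing names fall back to `Un`), or a
#'   function `chrom -> label`
#' @return character vector over `{At, Dt, Un}`
#' @export
assign_subgenome <- function(chrom, rule = NULL) {
  if (is.function(rule)) return(as.character(rule(chrom)))
  if (!is.null(rule)) {
    out <- unname(rule[chrom])
    out[is.na(out)] <- "Un"
    return(out)
  }
  ifelse(grepl("^At_", chrom), "At", ifelse(grepl("^Dt_", chrom), "Dt", "Un"))
}

#' Round half-up
#' @param x numeric
#' @param digits decimal places
#' @export
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Format a percentage the way the summaries print it
#'
#' Half-up rounding; by default one decimal, two decimals for values under
#' 10 percent (the convention used for sub-10 class fractions).
#'
#' @param x percentage values (already on the 0-100 scale)
#' @param digits fixed decimal count, or `NULL` for the auto rule
#' @export
format_pct <- function(x, digits = NULL) {
  if (!is.null(digits)) return(round_half_up(x, digits))
  ifelse(x >= 10, round_half_up(x, 1L), round_half_up(x, 2L))
}

#' Summarize classified lncRNA records
#'
#' @param records data.table from [classify_lncrnas()], optionally with
#'   `subgenome` and `longest_orf_nt` columns
#' @param length_breaks,exon_breaks histogram bin edges
#' @param pct_digits passed to [format_pct()]
#' @return list with `counts` (named, per class), `percentages` (formatted),
#'   `length_stats` (min/mean/max per class), `histograms`, and
#'   `subgenome_counts` when available. Empty input yields zero counts and
#'   no percentages.
#' @export
summarize_classes <- function(records,
                              length_breaks = c(0, 200, 500, 1000, 2000, 5000, Inf),
                              exon_breaks = c(0.5, 1.5, 2.5, 3.5, 4.5, 9.5, Inf),
                              pct_digits = NULL) {
  classes <- c("lincRNA", "intronic", "antisense")
  if (!nrow(records)) {
    return(list(counts = stats::setNames(rep(0L, 3L), classes),
                percentages = NULL, length_stats = NULL,
                histograms = NULL, subgenome_counts = NULL))
  }
  records <- data.table::as.data.table(records)
  counts <- vapply(classes, function(cl) sum(records$positional_class == cl), 0L)
  total <- sum(counts)
  pct <- format_pct(100 * counts / total, digits = pct_digits)
  length_stats <- records[, list(
    n = .N, min_len = min(length), mean_len = mean(length),
    max_len = max(length)), by = positional_class]
  hists <- lapply(stats::setNames(classes, classes), function(cl) {
    sub <- records[positional_class == cl]
    if (!nrow(sub)) return(NULL)
    list(length = table(cut(sub$length, breaks = length_breaks, right = FALSE)),
         exons = table(cut(sub$n_exons, breaks = exon_breaks)))
  })
  sg <- NULL
  if ("subgenome" %in% names(records)) {
    sg <- records[, .N, by = list(subgenome, positional_class)]
    data.table::setorder(sg, subgenome, positional_class)
  }
  list(counts = counts, percentages = pct, length_stats = length_stats,
       histograms = hists, subgenome_counts = sg)
}

#' Repeat / transposable-element overlap summary
#'
#' A lncRNA "contains" a repeat family iff its genomic span overlaps an
#' interval of that family by at least 1 bp. Fractions are reported per
#' family overall and per subgenome.
#'
#' @param records data.table with `transcript_id`, `chrom`, `start`, `end`
#'   and optionally `subgenome`
#' @param repeats data.table with `chrom`, `start`, `end`, `label` (the
#'   repeat class string, e.g. `"LTR/Copia"`), as produced by
#'   [read_tool_table()] with dialect `"repeatmasker"`
#' @return data.table(family, subgenome, n_lnc, n_overlap, fraction); the
#'   pseudo-subgenome `"all"` rows carry the overall fractions.
#' @export
repeat_overlap_summary <- function(records, repeats) {
  records <- data.table::as.data.table(records)
  repeats <- data.table::as.data.table(repeats)
  if (!"label" %in% names(repeats) && "repeat_class" %in% names(repeats))
    repeats[, label := repeat_class]  # accept raw repeatmasker-dialect tables
  if (!"label" %in% names(repeats))
    stop("repeat table needs a 'label' (or 'repeat_class') column")
  if (!"subgenome" %in% names(records))
    records[, subgenome := assign_subgenome(chrom)]
  fams <- sort(unique(repeats$label))
  groups <- c("all", sort(unique(records$subgenome)))
  if (!nrow(repeats) || !nrow(records)) {
    return(data.table::data.table(
      family = rep(fams, each = length(groups)),
      subgenome = rep(groups, times = length(fams)),
      n_lnc = 0L, n_overlap = 0L, fraction = 0))
  }
  lnc_gr <- GenomicRanges::GRanges(records$chrom,
    IRanges::IRanges(records$start + 1L, records$end))
  res <- list()
  for (fam in fams) {
    rp <- repeats[label == fam]
    rp_gr <- GenomicRanges::GRanges(rp$chrom, IRanges::IRanges(rp$start + 1L, rp$end))
    hit <- .count_overlaps(lnc_gr, rp_gr) > 0L
    for (g in groups) {
      sel <- if (g == "all") rep(TRUE, nrow(records)) else records$subgenome == g
      res[[length(res) + 1L]] <- data.table::data.table(
        family = fam, subgenome = g, n_lnc = sum(sel),
        n_overlap = sum(hit & sel),
        fraction = if (sum(sel)) sum(hit & sel) / sum(sel) else 0)
    }
  }
  data.table::rbindlist(res)
}
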
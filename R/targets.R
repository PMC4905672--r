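# Target prediction for identified lncRNAs:
#   cis  — coding genes within fixed genomic windows of the lncRNA span
#   trans — coding genes strongly co-expressed with the lncRNA
# plus intronic lncRNA / host-gene concordance and the small-RNA precursor
# summary from ingested Rfam hits.

#' Cis target prediction by genomic window
#'
#' Pairs each lncRNA with every coding gene whose span lies within a window
#' of the lncRNA span on the same chromosome, in both directions and
#' strand-agnostically. Distance is the genomic gap between the two spans
#' (0 when they overlap). Each (lncRNA, gene) pair is reported once, at the
#' smallest qualifying window.
#'
#' @param lnc data.table with `transcript_id`, `chrom`, `start`, `end`
#' @param genes data.table with `gene_id`, `chrom`, `start`, `end`
#' @param windows window sizes in bp, default 10 kb and 100 kb
#' @return data.table(lnc_id, gene_id, mode, distance) with `mode` of the
#'   form `"cis10k"` / `"cis100k"`.
#' @export
cis_targets <- function(lnc, genes, windows = c(10000L, 100000L)) {
  lnc <- data.table::as.data.table(lnc)
  genes <- data.table::as.data.table(genes)
  windows <- sort(as.integer(windows))
  modes <- paste0("cis", ifelse(windows %% 1000L == 0L,
                                paste0(windows %/% 1000L, "k"), windows))
  empty <- data.table::data.table(lnc_id = character(), gene_id = character(),
                                  mode = character(), distance = integer())
  if (!nrow(lnc) || !nrow(genes)) return(empty)
  lnc_gr <- GenomicRanges::GRanges(lnc$chrom,
    IRanges::IRanges(lnc$start + 1L, lnc$end))
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
    IRanges::IRanges(genes$start + 1L, genes$end))
  hits <- .find_overlaps(lnc_gr, gene_gr,
                                      maxgap = max(windows), ignore.strand = TRUE)
  if (!length(hits)) return(empty)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  gap <- pmax(0L,
              pmax(lnc$start[qh], genes$start[sh]) -
              pmin(lnc$end[qh], genes$end[sh]))
  keep <- gap <= max(windows)
  qh <- qh[keep]; sh <- sh[keep]; gap <- gap[keep]
  mode <- modes[findInterval(gap, c(0L, windows[-length(windows)] + 1L))]
  out <- data.table::data.table(
    lnc_id = lnc$transcript_id[qh], gene_id = genes$gene_id[sh],
    mode = mode, distance = gap)
  data.table::setorder(out, lnc_id, distance, gene_id)
  out[]
}

#' Trans target prediction by expression correlation
#'
#' Pearson correlation of `log2(FPKM + 1)` profiles across samples; pairs at
#' `|r| >= r_threshold` are reported. Constant profiles have undefined
#' correlation and yield no pair.
#'
#' @param lnc_fpkm lncRNAs x samples FPKM matrix
#' @param gene_fpkm genes x samples FPKM matrix, same sample columns in the
#'   same order
#' @param r_threshold default 0.9
#' @return data.table(lnc_id, gene_id, mode = "trans", r)
#' @export
trans_targets <- function(lnc_fpkm, gene_fpkm, r_threshold = 0.9) {
  lnc_fpkm <- as.matrix(lnc_fpkm); gene_fpkm <- as.matrix(gene_fpkm)
  if (!identical(colnames(lnc_fpkm), colnames(gene_fpkm)))
    stop("sample order mismatch between lncRNA and gene profiles")
  if (ncol(lnc_fpkm) < 3L) stop("need >= 3 samples for correlation")
  la <- log2(lnc_fpkm + 1); ga <- log2(gene_fpkm + 1)
  keep_l <- apply(la, 1L, stats::sd) > 0
  keep_g <- apply(ga, 1L, stats::sd) > 0
  empty <- data.table::data.table(lnc_id = character(), gene_id = character(),
                                  mode = character(), r = numeric())
  if (!sum(keep_l) || !sum(keep_g)) return(empty)
  r <- stats::cor(t(la[keep_l, , drop = FALSE]), t(ga[keep_g, , drop = FALSE]))
  hit <- which(abs(r) >= r_threshold, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  out <- data.table::data.table(
    lnc_id = rownames(r)[hit[, 1L]],
    gene_id = colnames(r)[hit[, 2L]],
    mode = "trans", r = r[hit])
  data.table::setorder(out, lnc_id, gene_id)
  out[]
}

#' Concordance between intronic lncRNAs and their host genes
#'
#' A pair is concordant iff the lncRNA's differential-expression call equals
#' its host gene's call (up=up, down=down, ns=ns) in the supplied contrast.
#'
#' @param records data.table of classified lncRNAs; only rows with
#'   `positional_class == "intronic"` and a `host_gene_id` are used
#' @param res a `contrast_result` covering both the lncRNAs and the host
#'   genes (gene-level rows keyed by gene id)
#' @return list(fraction, pairs = data.table(lnc_id, host_gene_id, lnc_call,
#'   host_call, concordant), n_skipped). Pairs whose host is absent from the
#'   result are skipped with a warning.
#' @export
intronic_host_concordance <- function(records, res) {
  records <- data.table::as.data.table(records)
  pairs <- records[positional_class == "intronic" & !is.na(host_gene_id),
                   list(lnc_id = transcript_id, host_gene_id)]
  calls <- contrast_calls(res)
  known <- pairs$lnc_id %in% names(calls) & pairs$host_gene_id %in% names(calls)
  n_skipped <- sum(!known)
  if (n_skipped)
    warning(n_skipped, " intronic pair(s) skipped: member missing from contrast result")
  pairs <- pairs[known]
  pairs[, lnc_call := unname(calls[lnc_id])]
  pairs[, host_call := unname(calls[host_gene_id])]
  pairs[, concordant := lnc_call == host_call]
  list(fraction = if (nrow(pairs)) mean(pairs$concordant) else NA_real_,
       pairs = pairs[], n_skipped = n_skipped)
}

#' Small-RNA precursor summary from Rfam hits
#'
#' Hits are filtered at the e-value cutoff; each lncRNA keeps its single best
#' (lowest-e) family; families are tallied and percentages reported with
#' half-up rounding to one decimal.
#'
#' @param rfam_records normalized records from [read_tool_table()] with
#'   dialect `"rfam"` (columns `query_id`, `label`, `e_value`)
#' @param e_cutoff default 1e-5
#' @return list(total, table = data.table(family, n, pct))
#' @export
precursor_summary <- function(rfam_records, e_cutoff = 1e-5) {
  rec <- data.table::as.data.table(rfam_records)
  if (!"label" %in% names(rec) && "family_name" %in% names(rec))
    rec[, label := family_name]  # accept raw rfam-dialect tables too
  rec <- rec[!is.na(e_value) & e_value <= e_cutoff]
  if (!nrow(rec))
    return(list(total = 0L,
                table = data.table::data.table(family = character(),
                                               n = integer(), pct = numeric())))
  data.table::setorder(rec, query_id, e_value, label)
  best <- rec[, list(family = label[1L]), by = query_id]
  tab <- best[, list(n = .N), by = family]
  total <- sum(tab$n)
  tab[, pct := round_half_up(100 * n / total, 1L)]
  data.table::setorder(tab, -n, family)
  list(total = total, table = tab[])
}
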
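# End-to-end pipeline driver and summary reporting.

#' Default run configuration
#'
#' Input paths (as produced by [generate_dataset()] or supplied by the
#' user) plus every stage threshold. Unknown keys are rejected by
#' [run_all()].
#'
#' @return named list of defaults.
#' @export
run_config <- function() {
  c(list(
    ref_gtf = NULL, transcripts_gtf = NULL, fasta = NULL,
    counts = NULL, design = NULL, libsizes = NULL,
    cpc = NULL, pfam = NULL, rfam = NULL, repeats = NULL,
    min_lfc = 1, alpha = 0.05,
    cis_windows = c(10000L, 100000L), r_threshold = 0.9,
    rfam_evalue = 1e-5, same_strand_intronic = FALSE,
    subgenome_rule = NULL, pct_digits = NULL),
    filter_config())
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

read_counts_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  m <- as.matrix(dt[, -1L])
  rownames(m) <- dt[[1L]]
  m
}

#' Run the complete lncRNA pipeline
#'
#' Executes identification (five-step filtration), positional
#' classification with subgenome attribution, FPKM and differential
#' expression for the D_vs_C / ReW_vs_C / ReW_vs_D contrasts,
#' response-pattern categorization (D_vs_C paired with ReW_vs_C),
#' per-class directional fractions (D_vs_C and ReW_vs_D), cis and trans
#' target prediction, intronic/host concordance, and the precursor and
#' repeat summaries. Every threshold used is recorded in the report.
#'
#' @param config list overriding [run_config()]; the path entries
#'   `ref_gtf`, `transcripts_gtf`, `fasta`, `counts`, `design` are required
#' @param out_dir if non-NULL, artifact files are written there (lncRNA GTF,
#'   per-stage TSV tables, `report.json`, `config.json`)
#' @return `summary_report` list; its `tables` element holds the full
#'   per-transcript outputs.
#' @export
run_all <- function(config, out_dir = NULL) {
  defaults <- run_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  required <- c("ref_gtf", "transcripts_gtf", "fasta", "counts", "design")
  for (key in required)
    if (is.null(cfg[[key]])) stop("config is missing required input: ", key)
  for (key in required)
    if (!file.exists(cfg[[key]])) stop("input file not found (", key, "): ", cfg[[key]])
  reference <- .stage("read_reference", read_gtf(cfg$ref_gtf))
  ann <- .stage("read_transcripts", read_gtf(cfg$transcripts_gtf))
  seqs <- .stage("read_fasta", read_fasta(cfg$fasta))
  counts <- .stage("read_counts", read_counts_tsv(cfg$counts))
  design <- .stage("read_design", as.data.frame(data.table::fread(cfg$design)))
  lib_sizes <- if (!is.null(cfg$libsizes)) {
    ls <- data.table::fread(cfg$libsizes, sep = "\t")
    stats::setNames(ls$total, ls$sample_id)[colnames(counts)]
  } else colSums(counts)
  cpc <- if (!is.null(cfg$cpc)) read_tool_table(cfg$cpc, "cpc") else NULL
  pfam <- if (!is.null(cfg$pfam)) read_tool_table(cfg$pfam, "pfam") else NULL
  rfam <- if (!is.null(cfg$rfam)) read_tool_table(cfg$rfam, "rfam") else NULL
  repeats <- if (!is.null(cfg$repeats)) read_tool_table(cfg$repeats, "repeatmasker") else NULL

  # lengths: assembled transcripts by transcript id, reference genes by gene id
  tx_len <- stats::setNames(ann$transcripts$length, ann$transcripts$transcript_id)
  gene_len <- ann_gene_lengths(reference)
  lengths_all <- c(tx_len, gene_len)[rownames(counts)]
  expr <- .stage("expression_matrix",
                 expression_matrix(counts, design,
                                   lengths = lengths_all, lib_sizes = lib_sizes))

  ident <- .stage("identify",
    run_identification(ann, reference, expr, seqs,
                       config = cfg[c("min_len", "min_exons", "min_fpkm",
                                      "min_reps", "orf_threshold_nt",
                                      "pfam_evalue")],
                       cpc_records = cpc, pfam_records = pfam))
  lnc <- ident$lnc
  records <- .stage("classify",
    classify_lncrnas(lnc, reference,
                     same_strand_intronic = cfg$same_strand_intronic))
  records[, subgenome := assign_subgenome(chrom, rule = cfg$subgenome_rule)]
  orf <- ident$orf_lengths[records$transcript_id]
  records[, longest_orf_nt := unname(orf)]
  class_summary <- summarize_classes(records, pct_digits = cfg$pct_digits)

  de <- .stage("differential_expression", {
    lapply(list(D_vs_C = c("D", "C"), ReW_vs_C = c("ReW", "C"),
                ReW_vs_D = c("ReW", "D")),
           function(ctr) nb_de_test(counts, design, ctr,
                                    min_lfc = cfg$min_lfc, alpha = cfg$alpha))
  })
  lnc_ids <- records$transcript_id
  restrict <- function(res) {
    out <- res[res$transcript_id %in% lnc_ids, ]
    data.table::setattr(out, "contrast", attr(res, "contrast"))
    out
  }
  patterns <- .stage("patterns",
    categorize_patterns(restrict(de$D_vs_C), restrict(de$ReW_vs_C)))
  dir_frac <- .stage("directional_fractions",
    directional_fraction(records, list(D_vs_C = de$D_vs_C,
                                       ReW_vs_D = de$ReW_vs_D)))

  coding_genes <- reference$genes[biotype == "coding"]
  cis <- .stage("cis_targets",
    cis_targets(records, coding_genes, windows = cfg$cis_windows))
  fpkm <- expr_fpkm(expr)
  lnc_fpkm <- fpkm[intersect(lnc_ids, rownames(fpkm)), , drop = FALSE]
  gene_fpkm <- fpkm[intersect(coding_genes$gene_id, rownames(fpkm)), , drop = FALSE]
  trans <- .stage("trans_targets",
    trans_targets(lnc_fpkm, gene_fpkm, r_threshold = cfg$r_threshold))
  conc <- .stage("host_concordance",
    intronic_host_concordance(records, de$D_vs_C))
  prec <- if (!is.null(rfam))
    .stage("precursors", precursor_summary(rfam, e_cutoff = cfg$rfam_evalue))
  else NULL
  reps <- if (!is.null(repeats))
    .stage("repeat_overlap", repeat_overlap_summary(records, repeats))
  else NULL

  de_counts <- lapply(de, function(res)
    c(up = sum(res$call == "up"), down = sum(res$call == "down")))
  report <- structure(list(
    config = cfg[!vapply(cfg, is.null, TRUE)],
    filtration = as.data.frame(ident$report),
    n_lnc = nrow(records),
    class_counts = class_summary$counts,
    class_percentages = class_summary$percentages,
    subgenome_counts = as.data.frame(
      records[, .N, by = subgenome][order(subgenome)]),
    venn = ident$coding$venn,
    de_counts = de_counts,
    pattern_counts = patterns$counts,
    target_counts = c(table(cis$mode), trans = nrow(trans)),
    concordance = conc$fraction,
    precursors = prec,
    repeat_fractions = reps,
    tables = list(records = records, patterns = patterns$labels, de = de,
                  cis = cis, trans = trans, concordance_pairs = conc$pairs,
                  report_steps = ident$report)),
    class = "summary_report")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_gtf(subset_transcripts(ann, lnc_ids), file.path(out_dir, "lncRNA.gtf"))
    data.table::fwrite(records, file.path(out_dir, "lncRNA_classes.tsv"), sep = "\t")
    data.table::fwrite(patterns$labels, file.path(out_dir, "patterns.tsv"), sep = "\t")
    data.table::fwrite(cis, file.path(out_dir, "targets_cis.tsv"), sep = "\t")
    data.table::fwrite(trans, file.path(out_dir, "targets_trans.tsv"), sep = "\t")
    for (cn in names(de))
      data.table::fwrite(de[[cn]], file.path(out_dir, paste0("de_", cn, ".tsv")),
                         sep = "\t")
    render_report(report, format = "json", path = file.path(out_dir, "report.json"))
    render_report(report, format = "tsv", path = file.path(out_dir, "report.tsv"))
    jsonlite::write_json(cfg[!vapply(cfg, is.null, TRUE)],
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  report
}

ann_gene_lengths <- function(ann) {
  # gene length = spliced length of the union of its transcripts' exons
  len <- ann$exons[, {
    o <- order(start)
    s <- start[o]; e <- end[o]
    merged_end <- cummax(e)
    keep <- c(TRUE, s[-1L] >= utils::head(merged_end, -1L))
    grp <- cumsum(keep)
    list(len = sum(tapply(e, grp, max) - tapply(s, grp, min)))
  }, by = gene_id]
  stats::setNames(as.numeric(len$len), len$gene_id)
}

report_identities_ok <- function(report) {
  cc <- report$class_counts
  pc <- report$pattern_counts
  ok <- TRUE
  if (!is.null(cc)) ok <- ok && sum(cc) == report$n_lnc
  if (!is.null(pc)) {
    ok <- ok && pc[["A_up"]] == pc[["sustained_up"]] + pc[["specific_up"]]
    ok <- ok && pc[["B_up"]] == pc[["sustained_up"]] + pc[["delayed_up"]]
  }
  ok
}

#' Render a summary report
#'
#' Re-asserts the internal identities (class counts sum to the total;
#' pattern set identities) and writes the report in the requested format.
#'
#' @param report `summary_report` from [run_all()]
#' @param format one of `"json"`, `"tsv"`, `"markdown"`
#' @param path output file path
#' @return `path`, invisibly.
#' @export
render_report <- function(report, format = c("json", "tsv", "markdown"), path) {
  format <- match.arg(format)
  if (!report_identities_ok(report))
    stop("report identities violated: upstream state is corrupt")
  core <- report[setdiff(names(report), c("tables", "config"))]
  if (format == "json") {
    core$precursors <- if (!is.null(report$precursors))
      list(total = report$precursors$total,
           table = report$precursors$table) else NULL
    jsonlite::write_json(core, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "columns", force = TRUE)
  } else if (format == "tsv") {
    rows <- list(data.table::data.table(section = "total", name = "n_lnc",
                                        value = report$n_lnc))
    add <- function(section, keys, values)
      rows[[length(rows) + 1L]] <<- data.table::data.table(
        section = section, name = as.character(keys), value = as.numeric(values))
    if (!is.null(report$class_counts))
      add("class_counts", names(report$class_counts), report$class_counts)
    if (!is.null(report$class_percentages))
      add("class_pct", names(report$class_counts), report$class_percentages)
    if (!is.null(report$pattern_counts))
      add("patterns", names(report$pattern_counts), report$pattern_counts)
    for (cn in names(report$de_counts))
      add(paste0("de_", cn), names(report$de_counts[[cn]]), report$de_counts[[cn]])
    if (!is.null(report$target_counts))
      add("targets", names(report$target_counts), report$target_counts)
    if (!is.null(report$concordance) && !is.na(report$concordance))
      add("concordance", "intronic_host", report$concordance)
    data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t")
  } else {
    cc <- report$class_counts
    pct <- report$class_percentages
    lines <- c("# lncRNA pipeline summary", "",
               sprintf("Identified lncRNAs: %d", report$n_lnc), "")
    if (!is.null(cc) && !is.null(pct))
      lines <- c(lines, sprintf("- %s %d (%s%%)", names(cc), cc,
                                as.character(pct)))
    if (!is.null(report$pattern_counts)) {
      pcn <- report$pattern_counts
      lines <- c(lines, "", "## Response patterns",
                 sprintf("- %s: %d", names(pcn), pcn))
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' @export
print.summary_report <- function(x, ...) {
  cat("summary_report\n")
  cat("  lncRNAs:", x$n_lnc, "\n")
  if (!is.null(x$class_counts)) {
    cat("  classes:", paste(sprintf("%s=%d", names(x$class_counts),
                                    x$class_counts), collapse = ", "), "\n")
  }
  invisible(x)
}
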
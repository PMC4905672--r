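# Annotation I/O and interval machinery.
#
# Internal coordinate convention everywhere in this package: 0-based,
# half-open [start, end). GTF (1-based, closed) is converted at the I/O
# boundary and nowhere else.

#' Construct an annotation set from an exon table
#'
#' An `annotation_set` is the package's container for transcript models: a
#' validated exon table plus derived per-transcript and per-gene tables.
#' Coordinates are 0-based half-open.
#'
#' @param exons data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand` (one of `+`, `-`, `.`), `start`, `end` (0-based half-open).
#' @param biotypes optional named character vector mapping `gene_id` to one of
#'   `"coding"`, `"noncoding"`, `"unknown"`. Unlisted genes are `"unknown"`.
#' @return An object of class `annotation_set` with elements `exons`,
#'   `transcripts` (id, gene, chrom, strand, n_exons, spliced `length`, span
#'   start/end) and `genes` (span over all member transcripts, `biotype`).
#' @export
annotation_set <- function(exons, biotypes = NULL) {
  exons <- data.table::as.data.table(exons)
  req <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  miss <- setdiff(req, names(exons))
  if (length(miss)) stop("exon table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(exons)) {
    if (any(!exons$strand %in% c("+", "-", "."))) stop("invalid strand value")
    if (any(exons$start < 0L)) stop("negative exon start")
    if (any(exons$end <= exons$start)) stop("exon with end <= start")
  }
  exons <- exons[, req, with = FALSE]
  data.table::setorder(exons, transcript_id, start)
  if (nrow(exons)) {
    chk <- exons[, {
      ok_disjoint <- .N == 1L || all(start[-1L] >= end[-.N])
      list(ok = ok_disjoint && length(unique(chrom)) == 1L &&
             length(unique(strand)) == 1L && length(unique(gene_id)) == 1L)
    }, by = transcript_id]
    bad <- chk[!(ok), transcript_id]
    if (length(bad)) {
      stop("invalid transcript model (overlapping exons or mixed chrom/strand/gene): ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
  }
  if (nrow(exons)) {
    transcripts <- exons[, list(
      gene_id = gene_id[1L], chrom = chrom[1L], strand = strand[1L],
      n_exons = .N, length = sum(end - start),
      start = min(start), end = max(end)), by = transcript_id]
    data.table::setorder(transcripts, transcript_id)
    genes <- transcripts[, list(
      chrom = chrom[1L], strand = strand[1L],
      start = min(start), end = max(end)), by = gene_id]
    data.table::setorder(genes, gene_id)
  } else {
    transcripts <- data.table::data.table(
      transcript_id = character(), gene_id = character(), chrom = character(),
      strand = character(), n_exons = integer(), length = integer(),
      start = integer(), end = integer())
    genes <- data.table::data.table(
      gene_id = character(), chrom = character(), strand = character(),
      start = integer(), end = integer())
  }
  bt <- rep("unknown", nrow(genes))
  if (!is.null(biotypes) && nrow(genes)) {
    hit <- biotypes[genes$gene_id]
    bt[!is.na(hit)] <- unname(hit[!is.na(hit)])
  }
  if (length(bt) && any(!bt %in% c("coding", "noncoding", "unknown")))
    stop("biotype must be coding/noncoding/unknown")
  genes[, biotype := bt]
  structure(list(exons = exons, transcripts = transcripts, genes = genes),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d transcripts, %d genes, %d exons\n",
              nrow(x$transcripts), nrow(x$genes), nrow(x$exons)))
  invisible(x)
}

#' Number of transcripts in an annotation set
#' @param x annotation_set
#' @export
n_transcripts <- function(x) nrow(x$transcripts)

#' Subset an annotation set by transcript id
#' @param ann annotation_set
#' @param ids transcript ids to keep
#' @export
subset_transcripts <- function(ann, ids) {
  bt <- stats::setNames(ann$genes$biotype, ann$genes$gene_id)
  annotation_set(ann$exons[transcript_id %in% ids], biotypes = bt)
}

gtf_attr <- function(attr, key) {
  pat <- paste0('.*', key, ' "([^"]*)".*')
  out <- sub(pat, "\\1", attr)
  out[!grepl(paste0(key, ' "'), attr, fixed = TRUE)] <- NA_character_
  out
}

#' Read a GTF file into an annotation set
#'
#' Parses Ensembl-dialect GTF (9 tab-separated columns, attributes holding at
#' least `gene_id` and `transcript_id`). 1-based closed coordinates are
#' converted to the internal 0-based half-open convention. A `gene_biotype`
#' attribute of `"protein_coding"` marks a gene as coding, `"noncoding"` as
#' noncoding; anything else (or absence) yields `"unknown"`.
#'
#' @param path GTF file path.
#' @param feature_filter feature types (column 3) to ingest; exon rows carry
#'   the transcript structure.
#' @return An [annotation_set()].
#' @export
read_gtf <- function(path, feature_filter = "exon") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*($|#)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(annotation_set(empty_exon_table()))
  nf <- lengths(regmatches(lines, gregexpr("\t", lines, fixed = TRUE))) + 1L
  if (any(nf != 9L)) {
    bad <- which(nf != 9L)[1L]
    stop(sprintf("malformed GTF line %d: expected 9 tab-separated fields, got %d",
                 lineno[bad], nf[bad]))
  }
  parts <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  dt <- data.table::data.table(
    chrom = parts[[1L]], feature = parts[[3L]],
    start_raw = parts[[4L]], end_raw = parts[[5L]],
    strand = parts[[7L]], attr = parts[[9L]], line = lineno)
  dt <- dt[feature %in% feature_filter]
  if (!nrow(dt)) return(annotation_set(empty_exon_table()))
  s1 <- suppressWarnings(as.integer(dt$start_raw))
  e1 <- suppressWarnings(as.integer(dt$end_raw))
  bad <- which(is.na(s1) | is.na(e1))
  if (length(bad))
    stop(sprintf("malformed GTF line %d: non-numeric coordinates", dt$line[bad[1L]]))
  bad <- which(e1 < s1)
  if (length(bad))
    stop(sprintf("invalid GTF line %d: end < start", dt$line[bad[1L]]))
  exons <- data.table::data.table(
    transcript_id = gtf_attr(dt$attr, "transcript_id"),
    gene_id = gtf_attr(dt$attr, "gene_id"),
    chrom = dt$chrom, strand = dt$strand,
    start = s1 - 1L, end = e1)  # 1-based closed -> 0-based half-open
  bad <- which(is.na(exons$transcript_id) | is.na(exons$gene_id))
  if (length(bad))
    stop(sprintf("malformed GTF line %d: missing gene_id/transcript_id attribute",
                 dt$line[bad[1L]]))
  bt_raw <- gtf_attr(dt$attr, "gene_biotype")
  bt <- ifelse(is.na(bt_raw), "unknown",
        ifelse(bt_raw == "protein_coding", "coding",
        ifelse(bt_raw == "noncoding", "noncoding", "unknown")))
  bt_map <- tapply(bt, exons$gene_id, function(v) {
    u <- unique(v[v != "unknown"])
    if (length(u) == 1L) u else "unknown"
  })
  annotation_set(exons, biotypes = stats::setNames(as.character(bt_map), names(bt_map)))
}

empty_exon_table <- function() {
  data.table::data.table(transcript_id = character(), gene_id = character(),
                         chrom = character(), strand = character(),
                         start = integer(), end = integer())
}

#' Write an annotation set as GTF
#'
#' Emits one exon row per exon in Ensembl dialect; internal 0-based half-open
#' coordinates are converted back to GTF 1-based closed. Gene biotype is
#' round-tripped via the `gene_biotype` attribute (`coding` as
#' `protein_coding`; `unknown` omits the attribute).
#'
#' @param ann annotation_set
#' @param path output file path
#' @param source value for GTF column 2
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path, source = "lincseek") {
  ex <- ann$exons
  bt <- stats::setNames(ann$genes$biotype, ann$genes$gene_id)
  bts <- unname(bt[ex$gene_id])
  attr_bt <- ifelse(bts == "coding", ' gene_biotype "protein_coding";',
             ifelse(bts == "noncoding", ' gene_biotype "noncoding";', ""))
  lines <- sprintf('%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";%s',
                   ex$chrom, source, ex$start + 1L, ex$end, ex$strand,
                   ex$gene_id, ex$transcript_id, attr_bt)
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA file of transcript sequences
#'
#' Sequences are uppercased and U is converted to T; record ids are the first
#' whitespace-delimited token of each header. Duplicate ids and empty
#' sequences are errors.
#'
#' @param path FASTA file path.
#' @return Named character vector of nucleotide strings.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  seqs <- chartr("Uu", "Tt", toupper(as.character(ss)))
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for id: ", ids[nchar(seqs) == 0L][1L])
  stats::setNames(unname(seqs), ids)
}

#' Write sequences to FASTA
#' @param seqs named character vector of sequences
#' @param path output path
#' @param width line-wrap width
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

# GenomicRanges overlap helpers, muffling the benign warning emitted when
# query and subject share no sequence levels (a legitimate "no hits" case
# here, e.g. a transcript on a chromosome without any coding gene)
.quiet_seqlevels <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("sequence levels in common", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}
.find_overlaps <- function(...) .quiet_seqlevels(GenomicRanges::findOverlaps(...))
.count_overlaps <- function(...) .quiet_seqlevels(GenomicRanges::countOverlaps(...))

.tool_dialects <- c("cpc", "pfam", "rfam", "repeatmasker")

#' Read an external tool-output table into normalized hit records
#'
#' Supported dialects (tab-separated, header row):
#' \describe{
#'   \item{cpc}{`query_id`, `label` (coding/noncoding), `score`}
#'   \item{pfam}{`query_id`, `domain_acc`, `domain_name`, `e_value`}
#'   \item{rfam}{`query_id`, `family_acc`, `family_name`, `e_value`}
#'   \item{repeatmasker}{`chrom`, `start`, `end`, `repeat_class`}
#' }
#' Records are normalized to a single shape (`query_id`, `label`, `score`,
#' `e_value`, plus `chrom`/`start`/`end` for repeatmasker). No threshold
#' filtering is applied here; filters live downstream.
#'
#' @param path table path
#' @param dialect one of `"cpc"`, `"pfam"`, `"rfam"`, `"repeatmasker"`
#' @return data.table of normalized hit records.
#' @export
read_tool_table <- function(path, dialect) {
  if (!dialect %in% .tool_dialects)
    stop("unknown dialect: ", dialect)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1L))
  need <- switch(dialect,
    cpc = c("query_id", "label", "score"),
    pfam = c("query_id", "domain_acc", "domain_name", "e_value"),
    rfam = c("query_id", "family_acc", "family_name", "e_value"),
    repeatmasker = c("chrom", "start", "end", "repeat_class"))
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop(dialect, " table missing columns: ", paste(miss, collapse = ", "))
  check_evalue <- function(v) {
    ev <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(ev) & !is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric e-value at %s line %d", dialect, bad[1L] + 1L))
    ev
  }
  switch(dialect,
    cpc = data.table::data.table(
      query_id = as.character(dt$query_id), label = as.character(dt$label),
      score = suppressWarnings(as.numeric(dt$score)), e_value = NA_real_),
    pfam = data.table::data.table(
      query_id = as.character(dt$query_id), label = as.character(dt$domain_name),
      score = NA_real_, e_value = check_evalue(dt$e_value),
      domain_acc = as.character(dt$domain_acc)),
    rfam = data.table::data.table(
      query_id = as.character(dt$query_id), label = as.character(dt$family_name),
      score = NA_real_, e_value = check_evalue(dt$e_value),
      family_acc = as.character(dt$family_acc)),
    repeatmasker = data.table::data.table(
      query_id = NA_character_, label = as.character(dt$repeat_class),
      score = NA_real_, e_value = NA_real_,
      chrom = as.character(dt$chrom),
      start = as.integer(dt$start), end = as.integer(dt$end)))
}

#' Build a searchable interval index
#'
#' Wraps the intervals in a [GenomicRanges::GRanges] so overlap queries are
#' logarithmic rather than linear; results are guaranteed to equal a linear
#' scan (property-tested).
#'
#' @param chrom character vector of chromosome names
#' @param start,end integer vectors, 0-based half-open
#' @param payload optional vector of payloads (defaults to indices)
#' @return An object of class `interval_index`.
#' @export
build_index <- function(chrom, start, end, payload = NULL) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (length(start) && any(end <= start)) stop("invalid interval: end <= start")
  if (is.null(payload)) payload <- seq_along(chrom)
  gr <- GenomicRanges::GRanges(
    seqnames = if (length(chrom)) chrom else character(),
    ranges = IRanges::IRanges(start = start + 1L, end = end))
  structure(list(gr = gr, payload = payload), class = "interval_index")
}

#' Query an interval index
#'
#' @param idx interval_index from [build_index()]
#' @param chrom,start,end a single query interval (0-based half-open)
#' @return Payloads of all stored intervals overlapping the query by >= 1 bp,
#'   in storage order.
#' @export
query_index <- function(idx, chrom, start, end) {
  stopifnot(inherits(idx, "interval_index"))
  if (!length(idx$payload)) return(idx$payload[0L])
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  hits <- .find_overlaps(q, idx$gr)
  idx$payload[sort(S4Vectors::subjectHits(hits))]
}
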
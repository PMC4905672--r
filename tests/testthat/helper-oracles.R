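# Independent brute-force oracles. These deliberately share no code with the
# implementation: plain loops, no vectorized tricks.

# exhaustive ORF scan: every ATG in every frame, walked codon by codon
brute_orf <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  best_len <- 0L; best_off <- NA_integer_; best_frame <- NA_integer_
  for (fr in 0:2) {
    i <- fr + 1L
    while (i + 5L <= n) {
      if (substr(s, i, i + 2L) == "ATG") {
        j <- i
        while (j + 2L <= n) {
          cod <- substr(s, j, j + 2L)
          if (grepl("N", cod, fixed = TRUE)) break  # N anywhere voids the ORF
          if (j > i && cod %in% c("TAA", "TAG", "TGA")) {
            len <- j + 2L - i + 1L
            off <- i - 1L
            if (len > best_len || (len == best_len && off < best_off)) {
              best_len <- len; best_off <- off; best_frame <- fr
            }
            break
          }
          j <- j + 3L
        }
      }
      i <- i + 3L
    }
  }
  list(longest_orf_nt = best_len, frame = best_frame, start_offset = best_off)
}

# linear-scan interval overlap
brute_overlap <- function(ivs, qchrom, qstart, qend) {
  hit <- integer()
  for (i in seq_len(nrow(ivs))) {
    if (ivs$chrom[i] == qchrom && ivs$start[i] < qend && qstart < ivs$end[i])
      hit <- c(hit, i)
  }
  hit
}

# BH from the definition: adj_i = min over {k : p_(k) >= p_i} of m * p_(k) / k
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# all-pairs cis window check
brute_cis <- function(lnc, genes, windows) {
  rows <- list()
  for (i in seq_len(nrow(lnc))) {
    for (j in seq_len(nrow(genes))) {
      if (lnc$chrom[i] != genes$chrom[j]) next
      gap <- max(0L, max(lnc$start[i], genes$start[j]) -
                     min(lnc$end[i], genes$end[j]))
      w <- windows[windows >= gap]
      if (!length(w)) next
      rows[[length(rows) + 1L]] <- data.frame(
        lnc_id = lnc$transcript_id[i], gene_id = genes$gene_id[j],
        window = min(w), distance = gap, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame(lnc_id = character(), gene_id = character(),
                                       window = integer(), distance = integer()))
  do.call(rbind, rows)
}

random_seq <- function(len, n_frac = 0) {
  alpha <- c("A", "C", "G", "T")
  s <- sample(alpha, len, replace = TRUE)
  if (n_frac > 0) {
    k <- rbinom(1, len, n_frac)
    if (k > 0) s[sample.int(len, k)] <- "N"
  }
  paste(s, collapse = "")
}

# single-exon transcript rows for quick annotation_set construction
simple_exons <- function(ids, chrom = "At_chr1", strand = "+",
                         starts = NULL, lens = 500L, gene_ids = NULL) {
  n <- length(ids)
  if (is.null(starts)) starts <- seq(0L, by = 10000L, length.out = n)
  lens <- rep_len(lens, n)
  if (is.null(gene_ids)) gene_ids <- paste0("g_", ids)
  data.table::data.table(transcript_id = ids, gene_id = gene_ids,
                         chrom = rep_len(chrom, n), strand = rep_len(strand, n),
                         start = as.integer(starts),
                         end = as.integer(starts + lens))
}

# a contrast_result-shaped table from explicit calls
fake_contrast <- function(ids, calls, contrast = "D_vs_C") {
  res <- data.table::data.table(
    transcript_id = ids,
    log2fc = ifelse(calls == "up", 2, ifelse(calls == "down", -2, 0)),
    p_value = ifelse(calls == "ns", 0.8, 1e-6),
    padj = ifelse(calls == "ns", 0.9, 1e-5),
    call = calls)
  data.table::setattr(res, "contrast", contrast)
  res
}
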
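# Open reading frame detection on the sense strand.

.stop_codons <- c("TAA", "TAG", "TGA")

#' Find the longest complete open reading frame in a transcript
#'
#' Scans the three sense-strand frames for ATG-initiated, stop-terminated
#' codon runs. An ORF is complete only if it ends at an in-frame stop codon
#' (TAA/TAG/TGA); its reported length includes the stop codon. Candidate ORFs
#' containing an ambiguous base (N) in any codon are skipped. Ties on length
#' are broken by the smallest start offset, then the smallest frame.
#'
#' @param sequence nucleotide string over `{A,C,G,T,N}` (lowercase accepted)
#' @return A list with `longest_orf_nt` (0 when no complete ORF exists),
#'   `frame` (0/1/2), and `start_offset` (0-based position of the A of ATG;
#'   `NA` when no ORF).
#' @export
find_longest_orf <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    stop("empty sequence")
  s <- toupper(sequence)
  if (grepl("[^ACGTN]", s)) stop("sequence alphabet must be A/C/G/T/N")
  n <- nchar(s)
  best <- list(longest_orf_nt = 0L, frame = NA_integer_, start_offset = NA_integer_)
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3L
    if (ncod < 2L) next
    codons <- substring(s, frame + 1L + 3L * (seq_len(ncod) - 1L),
                        frame + 3L * seq_len(ncod))
    starts <- which(codons == "ATG")
    if (!length(starts)) next
    stops <- which(codons %in% .stop_codons)
    if (!length(stops)) next
    has_n <- grepl("N", codons, fixed = TRUE)
    cum_n <- cumsum(has_n)
    # first stop at or after each start
    nxt <- stops[findInterval(starts - 1L, stops) + 1L]
    ok <- !is.na(nxt)
    if (!any(ok)) next
    starts <- starts[ok]; nxt <- nxt[ok]
    # skip ORFs with an N anywhere between start and stop codon (inclusive)
    n_in <- cum_n[nxt] - c(0L, cum_n)[starts]
    ok <- n_in == 0L
    if (!any(ok)) next
    starts <- starts[ok]; nxt <- nxt[ok]
    lens <- (nxt - starts + 1L) * 3L
    offs <- frame + 3L * (starts - 1L)
    o <- order(-lens, offs)[1L]
    cand <- list(longest_orf_nt = lens[o], frame = frame, start_offset = offs[o])
    if (cand$longest_orf_nt > best$longest_orf_nt ||
        (cand$longest_orf_nt == best$longest_orf_nt && !is.na(best$start_offset) &&
         cand$start_offset < best$start_offset)) {
      best <- cand
    }
  }
  best
}

#' Longest-ORF lengths for a set of sequences
#' @param seqs named character vector of sequences
#' @return Named integer vector of longest complete ORF lengths (nt).
#' @export
longest_orf_lengths <- function(seqs) {
  vapply(seqs, function(s) find_longest_orf(s)$longest_orf_nt, integer(1L))
}
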
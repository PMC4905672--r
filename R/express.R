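# Expression quantification and differential expression.
#
# The DE test is a declared, testable stand-in for the negative-binomial
# machinery of the original tooling: median-of-ratios normalization,
# method-of-moments dispersion shrunk 50/50 toward a fitted mean-dispersion
# trend, and a Wald-style test on log2 fold change under NB variance, with
# Benjamini-Hochberg adjustment.

#' Build an expression matrix with its design
#'
#' @param counts integer matrix, transcripts x samples, non-negative
#' @param design data.frame with `sample_id`, `condition`, `replicate`;
#'   must cover every column of `counts`
#' @param lengths named numeric vector of transcript lengths (nt), needed for
#'   FPKM
#' @param lib_sizes named numeric vector of per-sample total mapped
#'   fragments; defaults to column sums
#' @return `expression_matrix` object
#' @export
expression_matrix <- function(counts, design, lengths = NULL, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  design <- as.data.frame(design)
  if (!all(c("sample_id", "condition", "replicate") %in% names(design)))
    stop("design needs sample_id, condition, replicate")
  if (!all(colnames(counts) %in% design$sample_id))
    stop("design does not cover all samples")
  design <- design[match(colnames(counts), design$sample_id), ]
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(lib_sizes <= 0)) stop("zero library size")
  structure(list(counts = counts, design = design,
                 lengths = lengths, lib_sizes = lib_sizes,
                 fpkm = NULL),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d transcripts x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$design$condition), collapse = "/")))
  invisible(x)
}

#' Fragments per kilobase of exon per million mapped fragments
#'
#' `fpkm[t, s] = counts[t, s] / ((length_t / 1e3) * (total_s / 1e6))`.
#'
#' @param counts transcripts x samples count matrix
#' @param lengths transcript lengths in nt (> 0), recycled by row
#' @param totals per-sample total mapped fragments (> 0)
#' @return FPKM matrix of the same shape.
#' @export
compute_fpkm <- function(counts, lengths, totals) {
  counts <- as.matrix(counts)
  if (any(lengths <= 0)) stop("transcript lengths must be > 0")
  if (any(totals <= 0)) stop("zero library size")
  if (length(lengths) != nrow(counts)) lengths <- lengths[rownames(counts)]
  if (anyNA(lengths)) stop("lengths missing for some transcripts")
  sweep(counts / (as.numeric(lengths) / 1e3), 2L, as.numeric(totals) / 1e6, "/")
}

expr_fpkm <- function(expr) {
  if (is.null(expr$lengths)) stop("expression matrix has no transcript lengths")
  compute_fpkm(expr$counts, expr$lengths, expr$lib_sizes)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Implements the step-up rule directly: sorted p-values are scaled by m/rank
#' and a running minimum from the largest rank down enforces monotonicity.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA passed through)
#' @return adjusted values in `[0, 1]`, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric())
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(pv[o] * m / (m:1)))[ro]
  out[ok] <- adj
  out
}

# DESeq-style size factors: median of ratios to the geometric reference,
# over transcripts nonzero in all samples. Falls back to library-size
# scaling when no such transcript exists.
size_factors <- function(counts) {
  nz <- rowSums(counts == 0) == 0
  if (sum(nz) >= 1L) {
    logref <- rowMeans(log(counts[nz, , drop = FALSE]))
    sf <- apply(counts[nz, , drop = FALSE], 2L, function(col) {
      exp(stats::median(log(col) - logref))
    })
  } else {
    cs <- colSums(counts)
    sf <- cs / exp(mean(log(cs)))
  }
  sf
}

#' Negative-binomial differential expression between two groups
#'
#' Counts are normalized by median-of-ratios size factors (computed over all
#' supplied samples); per-transcript dispersion is estimated by the method of
#' moments within groups and shrunk 50/50 toward a fitted `a0 + a1/mean`
#' trend; a Wald-style z test is run on the log2 fold change with the
#' delta-method NB variance; p-values are BH-adjusted. A transcript is
#' called `up` when `padj < alpha` and `log2fc >= min_lfc`, `down`
#' symmetrically, else `ns`. With fewer than two replicates in either group,
#' calls are made on `|log2fc| >= min_lfc` alone and `padj` is `NA`.
#'
#' @param counts transcripts x samples count matrix
#' @param design data.frame(sample_id, condition, replicate)
#' @param contrast character pair `c(groupB, groupA)`: fold change is
#'   B over A (e.g. `c("D", "C")` gives the drought-vs-control contrast)
#' @param min_lfc minimum |log2 fold change| for a call (default 1)
#' @param alpha adjusted-p threshold (default 0.05)
#' @return `contrast_result`: data.table(transcript_id, log2fc, p_value,
#'   padj, call) with attribute `contrast` (e.g. `"D_vs_C"`).
#' @export
nb_de_test <- function(counts, design, contrast, min_lfc = 1, alpha = 0.05) {
  counts <- as.matrix(counts)
  design <- as.data.frame(design)
  gB <- contrast[1L]; gA <- contrast[2L]
  for (g in c(gA, gB))
    if (!g %in% design$condition) stop("group absent from design: ", g)
  sf <- size_factors(counts)
  norm <- sweep(counts, 2L, sf, "/")
  colsA <- design$sample_id[design$condition == gA]
  colsB <- design$sample_id[design$condition == gB]
  nA <- length(colsA); nB <- length(colsB)
  xA <- norm[, colsA, drop = FALSE]
  xB <- norm[, colsB, drop = FALSE]
  mA <- rowMeans(xA); mB <- rowMeans(xB)
  eps <- 0.5
  l2fc <- log2((mB + eps) / (mA + eps))
  replicated <- nA >= 2L && nB >= 2L
  if (replicated) {
    vA <- apply(xA, 1L, stats::var); vB <- apply(xB, 1L, stats::var)
    # pooled method-of-moments dispersion: var = mu + phi mu^2
    num <- (nA - 1L) * (vA - mA) + (nB - 1L) * (vB - mB)
    den <- (nA - 1L) * mA^2 + (nB - 1L) * mB^2
    phi_mom <- ifelse(den > 0, pmax(num / den, 1e-8), 1e-8)
    phi_mom <- pmin(phi_mom, 10)
    mu <- (mA + mB) / 2
    use <- mu > 0
    phi_trend <- rep(1e-8, length(mu))
    if (sum(use) >= 10L) {
      fit <- stats::lm(phi_mom[use] ~ I(1 / mu[use]))
      pred <- pmax(stats::predict(fit), 1e-8)
      phi_trend[use] <- pred
    } else {
      phi_trend[use] <- stats::median(phi_mom[use])
    }
    phi <- 0.5 * phi_mom + 0.5 * phi_trend
    # delta-method variance of log2 mean under NB sampling
    vlA <- (mA + phi * mA^2) / nA / (mA + eps)^2
    vlB <- (mB + phi * mB^2) / nB / (mB + eps)^2
    se <- sqrt(vlA + vlB) / log(2)
    z <- ifelse(se > 0, l2fc / se, 0)
    p <- 2 * stats::pnorm(-abs(z))
    zero <- mA == 0 & mB == 0
    p[zero] <- 1
    l2fc[zero] <- 0
    padj <- bh_adjust(p)
    call <- ifelse(padj < alpha & l2fc >= min_lfc, "up",
            ifelse(padj < alpha & l2fc <= -min_lfc, "down", "ns"))
  } else {
    p <- rep(NA_real_, length(l2fc))
    padj <- rep(NA_real_, length(l2fc))
    l2fc[mA == 0 & mB == 0] <- 0
    call <- ifelse(l2fc >= min_lfc, "up",
            ifelse(l2fc <= -min_lfc, "down", "ns"))
  }
  res <- data.table::data.table(
    transcript_id = rownames(counts), log2fc = l2fc,
    p_value = p, padj = padj, call = call)
  data.table::setattr(res, "contrast", paste0(gB, "_vs_", gA))
  data.table::setattr(res, "class", c("contrast_result", class(res)))
  res
}

contrast_calls <- function(res) {
  stats::setNames(res$call, res$transcript_id)
}

#' Categorize response patterns across two contrasts against control
#'
#' With contrast A = stress vs control and contrast B = recovery vs control:
#' sustained = DE in both, stress-specific = DE in A only, delayed = DE in B
#' only, separately for up and down. The set identities
#' `|A_up| = sustained_up + specific_up` and
#' `|B_up| = sustained_up + delayed_up` are asserted before returning.
#'
#' @param resA,resB `contrast_result` objects over the same transcript
#'   universe (e.g. D_vs_C and ReW_vs_C)
#' @return `pattern_table`: list(`labels` = per-transcript data.table with
#'   the A/B calls and a pattern label, `counts` = named category counts).
#'   Transcripts up in one contrast and down in the other are counted in
#'   both direction families and labelled `"mixed"`.
#' @export
categorize_patterns <- function(resA, resB) {
  idsA <- sort(resA$transcript_id); idsB <- sort(resB$transcript_id)
  if (!identical(idsA, idsB)) {
    diff <- c(setdiff(idsA, idsB), setdiff(idsB, idsA))
    stop("transcript universes differ between contrasts: ",
         paste(utils::head(diff, 5L), collapse = ", "),
         if (length(diff) > 5L) sprintf(" (+%d more)", length(diff) - 5L) else "")
  }
  a <- contrast_calls(resA)
  b <- contrast_calls(resB)[names(a)]
  upA <- a == "up"; upB <- b == "up"
  dnA <- a == "down"; dnB <- b == "down"
  counts <- c(
    A_up = sum(upA), B_up = sum(upB),
    A_down = sum(dnA), B_down = sum(dnB),
    sustained_up = sum(upA & upB),
    specific_up = sum(upA & !upB),
    delayed_up = sum(!upA & upB),
    sustained_down = sum(dnA & dnB),
    specific_down = sum(dnA & !dnB),
    delayed_down = sum(!dnA & dnB))
  stopifnot(counts[["A_up"]] == counts[["sustained_up"]] + counts[["specific_up"]],
            counts[["B_up"]] == counts[["sustained_up"]] + counts[["delayed_up"]],
            counts[["A_down"]] == counts[["sustained_down"]] + counts[["specific_down"]],
            counts[["B_down"]] == counts[["sustained_down"]] + counts[["delayed_down"]])
  label <- rep("none", length(a))
  label[upA & upB] <- "sustained_up"
  label[upA & !upB & !dnB] <- "specific_up"
  label[!upA & !dnA & upB] <- "delayed_up"
  label[dnA & dnB] <- "sustained_down"
  label[dnA & !dnB & !upB] <- "specific_down"
  label[!dnA & !upA & dnB] <- "delayed_down"
  label[(upA & dnB) | (dnA & upB)] <- "mixed"
  labels <- data.table::data.table(
    transcript_id = names(a), call_A = unname(a), call_B = unname(b),
    pattern = label)
  structure(list(labels = labels, counts = counts), class = "pattern_table")
}

#' Per-class up/down fractions for a contrast pair
#'
#' @param records data.table with `transcript_id` and `positional_class`
#' @param results named list of `contrast_result` objects (e.g.
#'   `list(D_vs_C = ..., ReW_vs_D = ...)`)
#' @return data.table(contrast, positional_class, n, frac_up, frac_down);
#'   classes with zero members in a contrast's universe are reported with
#'   `NA` fractions rather than 0/0.
#' @export
directional_fraction <- function(records, results) {
  records <- data.table::as.data.table(records)
  classes <- c("lincRNA", "intronic", "antisense")
  out <- list()
  for (cn in names(results)) {
    calls <- contrast_calls(results[[cn]])
    for (cl in classes) {
      ids <- records[positional_class == cl, transcript_id]
      ids <- ids[ids %in% names(calls)]
      n <- length(ids)
      out[[length(out) + 1L]] <- data.table::data.table(
        contrast = cn, positional_class = cl, n = n,
        frac_up = if (n) mean(calls[ids] == "up") else NA_real_,
        frac_down = if (n) mean(calls[ids] == "down") else NA_real_)
    }
  }
  data.table::rbindlist(out)
}
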
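# Synthetic-data generator with planted ground truth.
#
# Emulates the inputs of a polyploid (two-subgenome) drought RNA-seq study:
# a chromosome set named At_chr*/Dt_chr*/scaffold*, protein-coding genes with
# introns, assembled transcripts containing planted lncRNAs of the three
# positional classes alongside decoys (known-isoform overlaps, sub-200 nt
# fragments, silent transcripts, protein-coding novel transcripts),
# negative-binomial counts over a 3 condition x 3 replicate design with
# planted response patterns, and consistent CPC/Pfam/Rfam/RepeatMasker-style
# evidence tables. Every planted fact is recorded in a truth table so each
# pipeline stage can be scored against it.

.derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

#' Synthetic-dataset configuration
#'
#' Defaults describe a desk-scale genome (~2,000 expression features) with
#' the anchors of the emulated study: lncRNA lengths lognormal with mean
#' about 686 nt clamped to 200..12,057 nt, about 46% single-exon lncRNAs,
#' NB dispersion 0.1 with 4-fold planted condition effects, and an intronic
#' lncRNA / host-gene concordance rate of 75.95%.
#'
#' @param seed integer; fixes all randomness of every generator stage
#' @param ... overrides for any default field (unknown names are an error)
#' @return `synth_config` list. Fields include chromosome counts
#'   (`n_at`, `n_dt`, `n_scaffold`), feature counts (`n_coding_genes`,
#'   `n_linc`, `n_intronic`, `n_anti`, `n_isoform`, `n_short`, `n_silent`,
#'   `n_coding_novel`), length/exon-count distributions, NB parameters
#'   (`mu_grid`, `dispersion`, `effect_multiplier`), `pattern_props`,
#'   `concordance_rate`, `n_trans_pairs`, `repeat_density`,
#'   `precursor_counts`, `evidence_split`, `evidence_noise`.
#' @export
synth_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_at = 3L, n_dt = 3L, n_scaffold = 2L,
    chrom_length = 4e8,
    n_coding_genes = 500L,
    n_linc = 400L, n_intronic = 50L, n_anti = 80L,
    n_isoform = 120L, n_short = 80L, n_silent = 100L, n_coding_novel = 120L,
    # lncRNA spliced length: lognormal, mean ~686 nt, clamped 200..12057
    lnc_meanlog = log(686) - 0.245, lnc_sdlog = 0.7,
    lnc_len_range = c(200L, 12057L),
    # ~46% single-exon, tail out to 9 exons
    exon_count_probs = c(0.46, 0.24, 0.12, 0.07, 0.04, 0.03, 0.02, 0.01, 0.01),
    gene_exon_range = c(2L, 8L),
    gap_range = c(3000L, 30000L),
    mu_grid = c(30, 60, 120, 250, 500),
    dispersion = 0.1,
    effect_multiplier = 4,
    pattern_props = c(none = 0.53, sustained_up = 0.12, specific_up = 0.08,
                      delayed_up = 0.08, sustained_down = 0.08,
                      specific_down = 0.06, delayed_down = 0.05),
    concordance_rate = 0.7595,
    n_trans_pairs = 20L,
    repeat_density = c("Satellite" = 0.53, "LTR/Copia" = 0.30,
                       "LTR/Gypsy" = 0.10),
    n_repeat_background = 50L,
    precursor_counts = c(miRNA = 14L, tRNA = 4L, other = 22L),
    n_rfam_decoys = 30L,
    evidence_split = c(both = 0.6, cpc_only = 0.25, pfam_only = 0.15),
    evidence_noise = 0,
    orf_threshold_nt = 300L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (abs(sum(cfg$pattern_props) - 1) > 1e-8) stop("pattern_props must sum to 1")
  if (any(cfg$pattern_props < 0)) stop("pattern_props must be in [0,1]")
  if (cfg$n_coding_genes < cfg$n_intronic + cfg$n_anti)
    stop("need at least n_intronic + n_anti coding genes to host attached lncRNAs")
  structure(cfg, class = "synth_config")
}

# split a spliced length into n exon lengths (min 30 nt each)
split_len <- function(total, n) {
  if (n == 1L) return(total)
  w <- stats::runif(n, 0.5, 1.5)
  lens <- pmax(30L, as.integer(floor(total * w / sum(w))))
  lens[n] <- total - sum(lens[-n])
  if (lens[n] < 30L) { # rebalance from the largest exon
    k <- which.max(lens[-n])
    lens[k] <- lens[k] - (30L - lens[n])
    lens[n] <- 30L
  }
  lens
}

draw_lnc_len <- function(n, cfg) {
  len <- as.integer(round(stats::rlnorm(n, cfg$lnc_meanlog, cfg$lnc_sdlog)))
  pmin(pmax(len, cfg$lnc_len_range[1L]), cfg$lnc_len_range[2L])
}

draw_exon_count <- function(n, lens, cfg) {
  ne <- sample.int(length(cfg$exon_count_probs), n, replace = TRUE,
                   prob = cfg$exon_count_probs)
  pmin(ne, pmax(1L, lens %/% 60L))
}

# exon rows for a transcript laid out left-to-right from `start`
lay_exons <- function(tid, gid, chrom, strand, start, ex_lens, introns) {
  sts <- start + c(0L, cumsum(ex_lens[-length(ex_lens)] + introns))
  data.table::data.table(transcript_id = tid, gene_id = gid, chrom = chrom,
                         strand = strand, start = sts, end = sts + ex_lens)
}

#' Generate a synthetic reference annotation and assembled transcripts
#'
#' Coding genes are placed sequentially (no same-strand overlap by
#' construction); intronic lncRNAs are embedded in an enlarged first intron
#' of their host; antisense lncRNAs start inside the host's first exon on
#' the opposite strand; lincRNAs and the decoy families occupy the gaps.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg [synth_config()]
#' @return list(`reference` = annotation_set of coding genes, `transcripts`
#'   = annotation_set of assembled transcripts, `truth` = data.table with
#'   one row per assembled transcript and per gene: `id`, `feature`,
#'   `role` (lincRNA/intronic/antisense/isoform/short/silent/codn/gene),
#'   `is_lnc`, `class`, `host_gene_id`, `coding`, `expressed`, `pattern`,
#'   `trans_partner`, `precursor_family`).
#' @export
generate_annotation <- function(cfg) {
  set.seed(.derive_seed(cfg$seed, 1L))
  ng <- cfg$n_coding_genes
  gene_ids <- sprintf("G%05d", seq_len(ng))

  # ---- attached lncRNA structures ----------------------------------------
  n_int <- cfg$n_intronic; n_anti <- cfg$n_anti
  int_host <- if (n_int) seq_len(n_int) else integer()
  anti_host <- if (n_anti) n_int + seq_len(n_anti) else integer()
  int_len <- draw_lnc_len(n_int, cfg)
  int_nex <- pmin(draw_exon_count(n_int, int_len, cfg), 2L)
  anti_len <- draw_lnc_len(n_anti, cfg)
  anti_nex <- pmin(draw_exon_count(n_anti, anti_len, cfg), 3L)

  # ---- gene structures ----------------------------------------------------
  gene_struct <- vector("list", ng)
  host_of_int <- integer(ng); host_of_int[int_host] <- seq_len(n_int)
  host_of_anti <- integer(ng); host_of_anti[anti_host] <- seq_len(n_anti)
  for (g in seq_len(ng)) {
    n_ex <- sample(cfg$gene_exon_range[1L]:cfg$gene_exon_range[2L], 1L)
    ex <- pmax(100L, as.integer(round(stats::rlnorm(n_ex, log(220), 0.45))))
    intr <- sample(300:2500, n_ex - 1L, replace = TRUE)
    if (host_of_int[g]) {
      i <- host_of_int[g]
      span <- int_len[i] + if (int_nex[i] == 2L) 400L else 0L
      intr[1L] <- span + 400L
    }
    gene_struct[[g]] <- list(ex = ex, intr = intr,
                             strand = sample(c("+", "-"), 1L))
  }
  iso_genes <- if (cfg$n_isoform)
    sort(sample.int(ng, min(cfg$n_isoform, ng))) else integer()

  # ---- intergenic transcript structures -----------------------------------
  mk_free <- function(prefix, n, lens) {
    if (!n) return(NULL)
    nex <- draw_exon_count(n, lens, cfg)
    lapply(seq_len(n), function(i) {
      ex <- split_len(lens[i], nex[i])
      list(id = sprintf("%s%05d", prefix, i), ex = ex,
           intr = if (nex[i] > 1L) sample(200:2000, nex[i] - 1L, replace = TRUE)
                  else integer(),
           strand = sample(c("+", "-"), 1L))
    })
  }
  linc <- mk_free("LINC", cfg$n_linc, draw_lnc_len(cfg$n_linc, cfg))
  shorts <- mk_free("SHORT", cfg$n_short,
                    if (cfg$n_short) sample(100:199, cfg$n_short, TRUE) else integer())
  silents <- mk_free("SILENT", cfg$n_silent, draw_lnc_len(cfg$n_silent, cfg))
  codn_len <- if (cfg$n_coding_novel)
    pmax(draw_lnc_len(cfg$n_coding_novel, cfg), 450L) else integer()
  codn <- mk_free("CODN", cfg$n_coding_novel, codn_len)

  # ---- chromosome assignment and placement --------------------------------
  chroms <- c(sprintf("At_chr%d", seq_len(cfg$n_at)),
              sprintf("Dt_chr%d", seq_len(cfg$n_dt)),
              sprintf("scaffold%d", seq_len(cfg$n_scaffold)))
  # scaffolds get a light share, the two subgenomes split the rest
  w <- c(rep(0.45 / cfg$n_at, cfg$n_at), rep(0.45 / cfg$n_dt, cfg$n_dt),
         rep(0.10 / cfg$n_scaffold, cfg$n_scaffold))
  items <- c(lapply(seq_len(ng), function(g) list(type = "gene", idx = g)),
             lapply(seq_along(linc), function(i) list(type = "linc", idx = i)),
             lapply(seq_along(shorts), function(i) list(type = "short", idx = i)),
             lapply(seq_along(silents), function(i) list(type = "silent", idx = i)),
             lapply(seq_along(codn), function(i) list(type = "codn", idx = i)))
  items <- items[sample.int(length(items))]
  item_chrom <- sample(chroms, length(items), replace = TRUE, prob = w)

  ref_rows <- list(); asm_rows <- list(); truth_rows <- list()
  add_truth <- function(id, feature, role, class = NA_character_,
                        host = NA_character_, coding = FALSE, expressed = TRUE) {
    truth_rows[[length(truth_rows) + 1L]] <<- data.table::data.table(
      id = id, feature = feature, role = role,
      is_lnc = role %in% c("lincRNA", "intronic", "antisense"),
      class = class, host_gene_id = host, coding = coding,
      expressed = expressed)
  }
  for (ch in chroms) {
    cursor <- 1000L
    for (k in which(item_chrom == ch)) {
      it <- items[[k]]
      gap <- sample(cfg$gap_range[1L]:cfg$gap_range[2L], 1L)
      start <- cursor + gap
      if (it$type == "gene") {
        g <- it$idx; gs <- gene_struct[[g]]; gid <- gene_ids[g]
        rows <- lay_exons(paste0(gid, ".t1"), gid, ch, gs$strand, start,
                          gs$ex, gs$intr)
        ref_rows[[length(ref_rows) + 1L]] <- rows
        add_truth(gid, "gene", "gene")
        g_end <- max(rows$end)
        cursor <- g_end
        if (g %in% iso_genes) {
          keep <- if (length(gs$ex) > 2L) seq_len(length(gs$ex) - 1L)
                  else seq_along(gs$ex)
          iso <- lay_exons(sprintf("ISO%05d", g), sprintf("XISO%05d", g), ch,
                           gs$strand, start, gs$ex[keep],
                           gs$intr[utils::head(keep, -1L)])
          asm_rows[[length(asm_rows) + 1L]] <- iso
          add_truth(sprintf("ISO%05d", g), "transcript", "isoform")
        }
        if (host_of_int[g]) {
          i <- host_of_int[g]
          id <- sprintf("INTR%05d", i)
          ex1_end <- rows$end[1L]
          ex <- split_len(int_len[i], int_nex[i])
          intr <- if (int_nex[i] == 2L) 400L else integer()
          lrow <- lay_exons(id, paste0("X", id), ch,
                            sample(c("+", "-"), 1L), ex1_end + 200L, ex, intr)
          asm_rows[[length(asm_rows) + 1L]] <- lrow
          add_truth(id, "transcript", "intronic", class = "intronic", host = gid)
        }
        if (host_of_anti[g]) {
          i <- host_of_anti[g]
          id <- sprintf("ANTI%05d", i)
          astrand <- if (gs$strand == "+") "-" else "+"
          astart <- rows$start[1L] + gs$ex[1L] %/% 2L
          ex <- split_len(anti_len[i], anti_nex[i])
          intr <- if (anti_nex[i] > 1L)
            sample(200:1500, anti_nex[i] - 1L, replace = TRUE) else integer()
          lrow <- lay_exons(id, paste0("X", id), ch, astrand, astart, ex, intr)
          asm_rows[[length(asm_rows) + 1L]] <- lrow
          add_truth(id, "transcript", "antisense", class = "antisense", host = gid)
          cursor <- max(cursor, max(lrow$end))
        }
      } else {
        st <- switch(it$type, linc = linc, short = shorts,
                     silent = silents, codn = codn)[[it$idx]]
        rows <- lay_exons(st$id, paste0("X", st$id), ch, st$strand, start,
                          st$ex, st$intr)
        asm_rows[[length(asm_rows) + 1L]] <- rows
        role <- switch(it$type, linc = "lincRNA", short = "short",
                       silent = "silent", codn = "codn")
        add_truth(st$id, "transcript", role,
                  class = if (role == "lincRNA") "lincRNA" else NA_character_,
                  coding = role == "codn", expressed = role != "silent")
        cursor <- max(rows$end)
      }
      if (cursor > cfg$chrom_length)
        stop("infeasible packing on ", ch,
             ": increase chrom_length or reduce feature counts")
    }
  }
  ref_ex <- data.table::rbindlist(ref_rows)
  asm_ex <- data.table::rbindlist(asm_rows)
  truth <- data.table::rbindlist(truth_rows)

  # ---- planted response patterns, trans pairs, precursors -----------------
  pats <- names(cfg$pattern_props)
  lnc_ids <- truth[is_lnc == TRUE, id]
  truth[, pattern := "none"]
  truth[feature == "transcript" & expressed & is_lnc,
        pattern := sample(pats, .N, replace = TRUE, prob = cfg$pattern_props)]
  truth[feature == "gene",
        pattern := sample(pats, .N, replace = TRUE, prob = cfg$pattern_props)]
  # intronic host concordance: host matches the lncRNA's stress-contrast
  # direction with probability concordance_rate
  d_call <- function(p) ifelse(p %in% c("sustained_up", "specific_up"), "up",
                       ifelse(p %in% c("sustained_down", "specific_down"),
                              "down", "ns"))
  ipairs <- truth[role == "intronic", list(id, host_gene_id, pattern)]
  if (nrow(ipairs)) {
    conc <- stats::runif(nrow(ipairs)) < cfg$concordance_rate
    host_pat <- ifelse(conc, ipairs$pattern,
                ifelse(d_call(ipairs$pattern) == "up", "sustained_down",
                ifelse(d_call(ipairs$pattern) == "down", "sustained_up",
                       "specific_up")))
    truth[match(ipairs$host_gene_id, id), pattern := host_pat]
  }
  truth[, trans_partner := NA_character_]
  free_genes <- truth[feature == "gene" &
                        !id %in% truth$host_gene_id, id]
  n_tp <- min(cfg$n_trans_pairs, length(free_genes),
              sum(truth$role == "lincRNA"))
  # co-expression is only detectable when expression varies: partner
  # responsive lncRNAs
  tp_pool <- truth[role == "lincRNA" & pattern != "none", id]
  if (!length(tp_pool)) tp_pool <- truth[role == "lincRNA", id]
  n_tp <- min(n_tp, length(tp_pool))
  if (n_tp > 0L) {
    tp_lnc <- sample(tp_pool, n_tp)
    tp_gene <- sample(free_genes, n_tp)
    truth[match(tp_lnc, id), trans_partner := tp_gene]
  }
  truth[, precursor_family := NA_character_]
  pc <- cfg$precursor_counts
  n_prec <- sum(pc)
  pool <- setdiff(lnc_ids, character())
  if (n_prec > 0L && length(pool) >= n_prec) {
    prec_ids <- sample(pool, n_prec)
    truth[match(prec_ids, id),
          precursor_family := rep(names(pc), times = pc)]
  }

  coding_bt <- stats::setNames(rep("coding", ng), gene_ids)
  list(reference = annotation_set(ref_ex, biotypes = coding_bt),
       transcripts = annotation_set(asm_ex),
       truth = truth[])
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(0.30, 0.20, 0.20, 0.30)), collapse = "")
}

# break any complete ORF reaching `limit` by an in-frame TAA at its midpoint
suppress_orfs <- function(seq, limit) {
  for (iter in seq_len(200L)) {
    orf <- find_longest_orf(seq)
    if (orf$longest_orf_nt < limit) return(seq)
    ncod <- orf$longest_orf_nt %/% 3L
    pos <- orf$start_offset + 3L * (ncod %/% 2L) # codon near the middle
    substr(seq, pos + 1L, pos + 3L) <- "TAA"
  }
  stop("failed to suppress ORFs") # nocov
}

#' Generate transcript sequences consistent with planted coding flags
#'
#' Planted-coding transcripts carry an ATG-initiated complete ORF of at
#' least `cfg$orf_threshold_nt`; all other transcripts are guaranteed a
#' longest complete ORF strictly below the threshold (long ORFs arising by
#' chance are broken with in-frame stop codons).
#'
#' @param ann result of [generate_annotation()]
#' @param cfg [synth_config()]
#' @return named character vector, one sequence per assembled transcript,
#'   each of the transcript's spliced length.
#' @export
generate_sequences <- function(ann, cfg) {
  set.seed(.derive_seed(cfg$seed, 2L))
  tx <- ann$transcripts$transcripts
  truth <- ann$truth
  coding <- stats::setNames(truth$coding, truth$id)
  out <- character(nrow(tx))
  names(out) <- tx$transcript_id
  thr <- cfg$orf_threshold_nt
  non_stop <- setdiff(c(outer(c(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                      paste0)), c("A", "C", "G", "T"), paste0)),
                      .stop_codons)
  for (i in seq_len(nrow(tx))) {
    len <- tx$length[i]
    id <- tx$transcript_id[i]
    if (isTRUE(coding[id]) && len >= thr + 40L) {
      lead <- sample(0:9, 1L) * 3L
      k <- (thr %/% 3L) - 2L + sample(0:30, 1L)  # coding codons between ATG and stop
      k <- min(k, (len - lead - 6L) %/% 3L - 1L)
      body <- paste(sample(non_stop, k, replace = TRUE), collapse = "")
      core <- paste0(random_dna(lead), "ATG", body, "TGA")
      tail_len <- len - nchar(core)
      out[i] <- paste0(core, random_dna(tail_len))
    } else {
      s <- random_dna(len)
      if (len >= thr) s <- suppress_orfs(s, thr)
      out[i] <- s
    }
  }
  out
}

#' Generate NB counts over the 3 x 3 drought design
#'
#' Planted patterns act as multiplicative effects on the condition means
#' (`effect_multiplier`, default 4; down patterns use its reciprocal);
#' planted-silent transcripts are all-zero; trans-partner genes mirror their
#' lncRNA's realized counts so co-expression survives sampling noise.
#'
#' @param ann result of [generate_annotation()]
#' @param cfg [synth_config()]
#' @return list(`counts` = feature x 9 integer matrix (transcripts then
#'   genes), `design` = data.frame(sample_id, condition, replicate),
#'   `lib_sizes` = named column totals).
#' @export
generate_counts <- function(ann, cfg) {
  set.seed(.derive_seed(cfg$seed, 3L))
  truth <- ann$truth
  design <- data.frame(
    sample_id = c(paste0("C_", 1:3), paste0("D_", 1:3), paste0("ReW_", 1:3)),
    condition = rep(c("C", "D", "ReW"), each = 3L),
    replicate = rep(1:3, times = 3L))
  m <- cfg$effect_multiplier
  mult <- list(none = c(1, 1, 1),
               sustained_up = c(1, m, m), specific_up = c(1, m, 1),
               delayed_up = c(1, 1, m),
               sustained_down = c(1, 1 / m, 1 / m),
               specific_down = c(1, 1 / m, 1),
               delayed_down = c(1, 1, 1 / m))
  ids <- truth$id
  n <- length(ids)
  mu0 <- sample(cfg$mu_grid, n, replace = TRUE)
  eff <- do.call(rbind, mult[truth$pattern])
  mu <- mu0 * eff[, rep(1:3, each = 3L), drop = FALSE]
  counts <- matrix(stats::rnbinom(n * 9L, mu = as.numeric(mu),
                                  size = 1 / cfg$dispersion),
                   nrow = n, dimnames = list(ids, design$sample_id))
  counts[!truth$expressed, ] <- 0L
  tp <- truth[!is.na(trans_partner)]
  for (j in seq_len(nrow(tp))) {
    base <- counts[tp$id[j], ]
    counts[tp$trans_partner[j], ] <-
      stats::rnbinom(9L, mu = 2 * (base + 1), size = 1 / 0.02)
  }
  storage.mode(counts) <- "integer"
  list(counts = counts, design = design, lib_sizes = colSums(counts))
}

#' Generate synthetic CPC / Pfam / Rfam / RepeatMasker evidence tables
#'
#' CPC labels and Pfam hits are consistent with the planted coding flags
#' (`evidence_split` apportions coding transcripts among CPC-only,
#' Pfam-only and both; `evidence_noise` flips calls at the given rate);
#' Rfam hits cover the planted precursor lncRNAs at e-values at or below
#' 1e-5 with decoy hits above the cutoff; repeat intervals overlap each
#' lncRNA with the planted per-family density.
#'
#' @param ann result of [generate_annotation()]
#' @param cfg [synth_config()]
#' @return list of data.tables: `cpc`, `pfam`, `rfam`, `repeats` (column
#'   layouts match the [read_tool_table()] dialects).
#' @export
generate_aux_tables <- function(ann, cfg) {
  set.seed(.derive_seed(cfg$seed, 4L))
  truth <- ann$truth
  tx <- truth[feature == "transcript"]
  coding <- tx$coding
  noise <- stats::runif(nrow(tx)) < cfg$evidence_noise
  eff_coding <- xor(coding, noise)
  # apportion evidence among coding transcripts deterministically
  idx <- which(eff_coding)
  n_both <- round(length(idx) * cfg$evidence_split[["both"]])
  n_cpc <- round(length(idx) * cfg$evidence_split[["cpc_only"]])
  ev <- rep("pfam_only", length(idx))
  ev[seq_len(n_both)] <- "both"
  if (n_cpc) ev[n_both + seq_len(n_cpc)] <- "cpc_only"
  cpc_pos <- idx[ev %in% c("both", "cpc_only")]
  pfam_pos <- idx[ev %in% c("both", "pfam_only")]
  cpc <- data.table::data.table(
    query_id = tx$id,
    label = ifelse(seq_len(nrow(tx)) %in% cpc_pos, "coding", "noncoding"),
    score = round(stats::runif(nrow(tx), 0.5, 6), 3))
  pfam <- if (length(pfam_pos)) data.table::data.table(
    query_id = tx$id[pfam_pos],
    domain_acc = sprintf("PF%05d", sample(10000:19999, length(pfam_pos), TRUE)),
    domain_name = sample(c("PK_domain", "LRR", "Myb_DNA_bind", "ABC_tran"),
                         length(pfam_pos), TRUE),
    e_value = signif(10^-stats::runif(length(pfam_pos), 4, 10), 4))
  else data.table::data.table(query_id = character(), domain_acc = character(),
                              domain_name = character(), e_value = numeric())
  prec <- truth[!is.na(precursor_family)]
  fam_acc <- c(miRNA = "RF00451", tRNA = "RF00005", other = "RF01960")
  rfam_hit <- if (nrow(prec)) data.table::data.table(
    query_id = prec$id,
    family_acc = unname(fam_acc[prec$precursor_family]),
    family_name = prec$precursor_family,
    e_value = signif(10^-stats::runif(nrow(prec), 6, 12), 4))
  else data.table::data.table(query_id = character(), family_acc = character(),
                              family_name = character(), e_value = numeric())
  decoy_pool <- setdiff(truth[is_lnc == TRUE, id], prec$id)
  n_dec <- min(cfg$n_rfam_decoys, length(decoy_pool))
  rfam_dec <- if (n_dec) data.table::data.table(
    query_id = sample(decoy_pool, n_dec),
    family_acc = "RF01960",
    family_name = sample(c("miRNA", "other"), n_dec, TRUE),
    e_value = signif(10^-stats::runif(n_dec, 1, 4.8), 4))
  else NULL
  rfam <- data.table::rbindlist(list(rfam_hit, rfam_dec))
  # repeats: planted per-family Bernoulli overlap inside each lncRNA span
  lnc <- ann$transcripts$transcripts[
    transcript_id %in% truth[is_lnc == TRUE, id]]
  rep_rows <- list()
  fams <- names(cfg$repeat_density)
  for (fi in seq_along(fams)) {
    hit <- stats::runif(nrow(lnc)) < cfg$repeat_density[[fi]]
    if (any(hit)) {
      off <- 5L + 50L * (fi - 1L)
      rep_rows[[length(rep_rows) + 1L]] <- data.table::data.table(
        chrom = lnc$chrom[hit], start = lnc$start[hit] + off,
        end = lnc$start[hit] + off + 40L, repeat_class = fams[fi])
    }
  }
  if (cfg$n_repeat_background) {
    chroms <- unique(ann$reference$exons$chrom)
    # background intervals live far beyond the populated region
    hi <- max(ann$transcripts$transcripts$end, ann$reference$genes$end)
    bg_start <- as.integer(round(stats::runif(cfg$n_repeat_background,
                                              hi + 1e6, hi + 2e6)))
    rep_rows[[length(rep_rows) + 1L]] <- data.table::data.table(
      chrom = sample(chroms, cfg$n_repeat_background, TRUE),
      start = bg_start, end = bg_start + sample(100:5000, cfg$n_repeat_background, TRUE),
      repeat_class = sample(fams, cfg$n_repeat_background, TRUE))
  }
  repeats <- data.table::rbindlist(rep_rows)
  data.table::setorder(repeats, chrom, start, end, repeat_class)
  list(cpc = cpc, pfam = pfam, rfam = rfam, repeats = repeats)
}

#' Generate and write a complete synthetic dataset
#'
#' Runs all generator stages and writes: `ref.gtf`, `transcripts.gtf`,
#' `transcripts.fa`, `counts.tsv`, `design.csv`, `libsizes.tsv`,
#' `truth.tsv`, `cpc.tsv`, `pfam.tsv`, `rfam.tsv`, `repeats.tsv`.
#' Byte-identical across reruns with the same configuration.
#'
#' @param cfg [synth_config()]
#' @param dir output directory (created if needed)
#' @return invisibly, a list with the in-memory objects and file `paths`.
#' @export
generate_dataset <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ann <- generate_annotation(cfg)
  seqs <- generate_sequences(ann, cfg)
  cnt <- generate_counts(ann, cfg)
  aux <- generate_aux_tables(ann, cfg)
  p <- function(f) file.path(dir, f)
  write_gtf(ann$reference, p("ref.gtf"))
  write_gtf(ann$transcripts, p("transcripts.gtf"))
  write_fasta(seqs, p("transcripts.fa"))
  counts_dt <- data.table::data.table(transcript_id = rownames(cnt$counts))
  counts_dt <- cbind(counts_dt, data.table::as.data.table(cnt$counts))
  data.table::fwrite(counts_dt, p("counts.tsv"), sep = "\t")
  data.table::fwrite(cnt$design, p("design.csv"))
  data.table::fwrite(data.table::data.table(sample_id = names(cnt$lib_sizes),
                                            total = unname(cnt$lib_sizes)),
                     p("libsizes.tsv"), sep = "\t")
  data.table::fwrite(ann$truth, p("truth.tsv"), sep = "\t")
  data.table::fwrite(aux$cpc, p("cpc.tsv"), sep = "\t")
  data.table::fwrite(aux$pfam, p("pfam.tsv"), sep = "\t")
  data.table::fwrite(aux$rfam, p("rfam.tsv"), sep = "\t")
  data.table::fwrite(aux$repeats, p("repeats.tsv"), sep = "\t")
  invisible(list(ann = ann, sequences = seqs, counts = cnt, aux = aux,
                 paths = stats::setNames(
                   p(c("ref.gtf", "transcripts.gtf", "transcripts.fa",
                       "counts.tsv", "design.csv", "libsizes.tsv", "truth.tsv",
                       "cpc.tsv", "pfam.tsv", "rfam.tsv", "repeats.tsv")),
                   c("ref_gtf", "transcripts_gtf", "fasta", "counts", "design",
                     "libsizes", "truth", "cpc", "pfam", "rfam", "repeats"))))
}
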
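test_that("cis windows classify by gap distance with overlap = 0", {
  lnc <- data.table::data.table(transcript_id = "l1", chrom = "At_chr1",
                                start = 100000L, end = 101000L)
  genes <- data.table::data.table(
    gene_id = c("near", "mid", "far", "other_chrom", "touching"),
    chrom = c(rep("At_chr1", 3), "Dt_chr1", "At_chr1"),
    start = c(106000L, 151000L, 300000L, 106000L, 100500L),
    end = c(108000L, 153000L, 302000L, 108000L, 102000L))
  out <- cis_targets(lnc, genes)
  expect_equal(out[gene_id == "near", mode], "cis10k")
  expect_equal(out[gene_id == "near", distance], 5000L)
  expect_equal(out[gene_id == "mid", mode], "cis100k")
  expect_equal(out[gene_id == "touching", distance], 0L)
  expect_false("far" %in% out$gene_id)
  expect_false("other_chrom" %in% out$gene_id)
})

test_that("cis prediction equals all-pairs brute force and nests by window", {
  set.seed(14)
  genes <- data.table::data.table(
    gene_id = sprintf("g%03d", 1:100),
    chrom = sample(c("At_chr1", "Dt_chr1"), 100, TRUE),
    start = sample.int(1000000L, 100))
  genes[, end := start + sample(1000:20000, 100, TRUE)]
  lnc <- data.table::data.table(
    transcript_id = sprintf("l%02d", 1:30),
    chrom = sample(c("At_chr1", "Dt_chr1"), 30, TRUE),
    start = sample.int(1000000L, 30))
  lnc[, end := start + sample(200:3000, 30, TRUE)]
  windows <- c(10000L, 100000L)
  got <- cis_targets(lnc, genes, windows)
  want <- brute_cis(lnc, genes, windows)
  key <- function(d) sort(paste(d$lnc_id, d$gene_id, d$distance))
  expect_equal(key(got), key(want))
  # window labels agree with the smallest qualifying window
  merged <- merge(got, want, by = c("lnc_id", "gene_id"))
  expect_equal(merged$mode == "cis10k", merged$window == 10000L)
  # nesting: every 10k pair is also within 100k
  pairs10 <- got[mode == "cis10k", paste(lnc_id, gene_id)]
  all100 <- cis_targets(lnc, genes, windows = 100000L)
  expect_true(all(pairs10 %in% all100[, paste(lnc_id, gene_id)]))
})

test_that("trans prediction handles exact dependence and constants", {
  samples <- sprintf("s%d", 1:9)
  lnc <- matrix(c(1, 4, 9, 20, 45, 80, 150, 260, 400), 1,
                dimnames = list("l1", samples))
  genes <- rbind(2 * lnc, matrix(5, 1, 9))
  rownames(genes) <- c("gdep", "gconst")
  out <- trans_targets(lnc, genes)
  expect_true("gdep" %in% out$gene_id)
  expect_gt(out[gene_id == "gdep", r], 0.99)
  expect_false("gconst" %in% out$gene_id)
  expect_false(anyNA(out$r))

  expect_error(trans_targets(lnc, genes[, rev(samples)]), "sample order")
})

test_that("trans prediction is symmetric and monotone in the threshold", {
  set.seed(21)
  samples <- sprintf("s%d", 1:9)
  a <- matrix(rlnorm(5 * 9, 3, 1), 5, 9, dimnames = list(sprintf("a%d", 1:5), samples))
  b <- matrix(rlnorm(6 * 9, 3, 1), 6, 9, dimnames = list(sprintf("b%d", 1:6), samples))
  ab <- trans_targets(a, b, r_threshold = 0.3)
  ba <- trans_targets(b, a, r_threshold = 0.3)
  expect_equal(sort(paste(ab$lnc_id, ab$gene_id, round(ab$r, 10))),
               sort(paste(ba$gene_id, ba$lnc_id, round(ba$r, 10))))
  strict <- trans_targets(a, b, r_threshold = 0.8)
  expect_true(all(paste(strict$lnc_id, strict$gene_id) %in%
                  paste(ab$lnc_id, ab$gene_id)))
})

test_that("planted co-expressed pairs are recalled at the default threshold", {
  set.seed(121)
  samples <- sprintf("s%d", 1:9)
  n_lnc <- 25; n_gene <- 500
  lnc <- matrix(rlnorm(n_lnc * 9, 3, 1.2), n_lnc, 9,
                dimnames = list(sprintf("l%02d", 1:n_lnc), samples))
  genes <- matrix(rlnorm(n_gene * 9, 3, 1.2), n_gene, 9,
                  dimnames = list(sprintf("g%03d", 1:n_gene), samples))
  # 20 planted partners: scaled copies with lognormal noise, sd 0.1
  planted <- sprintf("g%03d", 1:20)
  genes[planted, ] <- 2 * lnc[1:20, ] * matrix(rlnorm(20 * 9, 0, 0.1), 20, 9)
  out <- trans_targets(lnc, genes)
  hit <- paste(sprintf("l%02d", 1:20), planted) %in% paste(out$lnc_id, out$gene_id)
  expect_gte(mean(hit), 0.9)
})

test_that("intronic-host concordance compares call categories", {
  rec <- data.table::data.table(
    transcript_id = c("i1", "i2", "i3"), positional_class = "intronic",
    host_gene_id = c("g1", "g2", "g3"))
  res <- fake_contrast(c("i1", "i2", "i3", "g1", "g2"),
                       c("up", "up", "ns", "up", "down"))
  expect_warning(out <- intronic_host_concordance(rec, res), "skipped")
  expect_equal(out$n_skipped, 1L)
  expect_equal(out$fraction, 0.5)  # i1/g1 concordant, i2/g2 not

  # a set against itself is fully concordant
  self <- data.table::data.table(transcript_id = c("a", "b"),
                                 positional_class = "intronic",
                                 host_gene_id = c("a", "b"))
  res2 <- fake_contrast(c("a", "b"), c("up", "down"))
  expect_equal(intronic_host_concordance(self, res2)$fraction, 1.0)
})

test_that("planted concordance rates are recovered within the binomial band", {
  set.seed(88)
  n <- 80
  rec <- data.table::data.table(
    transcript_id = sprintf("i%02d", 1:n), positional_class = "intronic",
    host_gene_id = sprintf("g%02d", 1:n))
  lnc_call <- sample(c("up", "down", "ns"), n, TRUE)
  conc <- runif(n) < 0.75
  host_call <- ifelse(conc, lnc_call,
                      ifelse(lnc_call == "up", "down", "up"))
  res <- fake_contrast(c(rec$transcript_id, rec$host_gene_id),
                       c(lnc_call, host_call))
  out <- intronic_host_concordance(rec, res)
  band <- 1.96 * sqrt(0.75 * 0.25 / n)
  expect_lt(abs(out$fraction - 0.75), band + 1e-9)
})

test_that("precursor summary filters, keeps best hits and sums to 100", {
  rec <- data.table::data.table(
    query_id = c("l1", "l1", "l2", "l3"),
    label = c("miRNA", "tRNA", "tRNA", "snoRNA"),
    score = NA_real_,
    e_value = c(1e-8, 1e-6, 1e-7, 1e-2))
  out <- precursor_summary(rec)
  expect_equal(out$total, 2L)  # l3 fails the cutoff; l1 counted once
  expect_equal(out$table[family == "miRNA", n], 1L)  # l1's best family
  expect_false("snoRNA" %in% out$table$family)
  expect_equal(sum(out$table$pct), 100, tolerance = 0.2)

  none <- precursor_summary(rec[e_value > 1e-3])
  expect_equal(none$total, 0L)
})
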
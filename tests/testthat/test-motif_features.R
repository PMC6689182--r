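test_that("kmer_frequencies counts overlapping k-mers", {
  f <- kmer_frequencies("AUGAUG", 3L)
  expect_equal(unname(f[c("AUG", "UGA", "GAU")]), c(2, 1, 1) / 4)
  expect_equal(sum(f), 1)
  expect_equal(sum(kmer_frequencies("ACGU", 2L)), 1)
  expect_true(all(kmer_frequencies("", 3L) == 0))
  expect_true(all(kmer_frequencies("AU", 3L) == 0))
  # vectorized path agrees with the scalar contract
  set.seed(5)
  strs <- vapply(1:20, function(i) random_rna(sample(0:30, 1)), character(1))
  M <- teseq:::.kmer_freq_set(strs, 3L)
  for (i in seq_along(strs))
    expect_equal(unname(M[i, ]), unname(kmer_frequencies(strs[i], 3L)))
})

test_that("build_pwm normalizes, pseudocounts, and respects coverage", {
  # identical sequences: consensus base dominates (0.5 pseudocount)
  rows <- do.call(rbind, lapply(1:8, function(i)
    make_record(utr = "AACGU", cds = "AUGGCUUAA", gene_id = paste0("g", i))))
  d <- te_dataset(rows, quiet = TRUE)
  pwm <- build_pwm(d, d$records$gene_id, -5L, -1L)
  expect_equal(rowSums(pwm$freqs), rep(1, 5), ignore_attr = TRUE)
  expect_equal(colnames(pwm$freqs)[apply(pwm$freqs, 1, which.max)],
               c("A", "A", "C", "G", "U"))
  expect_equal(unname(pwm$freqs[1, "A"]), 8.5 / 10)  # (8+.5)/(8+4*.5)
  # positions beyond a gene's UTR draw only on covering genes
  rows2 <- rbind(make_record(utr = "GGAAA", cds = "AUGGCUUAA", gene_id = "a"),
                 make_record(utr = "CCCCCAAAAA", cds = "AUGGCUUAA",
                             gene_id = "b"))
  d2 <- te_dataset(rows2, quiet = TRUE)
  pwm2 <- build_pwm(d2, c("a", "b"), -7L, -1L)
  # position -7: only gene b covers it (C) -> C = 1.5/3
  expect_equal(unname(pwm2$freqs["-7", "C"]), 1.5 / 3)
  expect_error(build_pwm(d2, c("a", "b"), -20L, -1L), "covered by no gene")
})

test_that("pwm_score is a contained log10 likelihood and is log-additive", {
  uni <- structure(list(anchor = "iaug", from_pos = -10L, to_pos = -1L,
                        positions = seq(-10L, -1L),
                        freqs = matrix(0.25, 10, 4,
                          dimnames = list(NULL, c("A", "C", "G", "U")))),
                   class = "te_pwm")
  rec <- make_dataset(1, utr_len = 20, seed = 2)$records[1, ]
  expect_equal(pwm_score(rec, uni), 10 * log10(0.25))
  # containment: utr too short -> missing
  rec4 <- make_dataset(1, utr_len = 4, seed = 2)$records[1, ]
  expect_true(is.na(pwm_score(rec4, uni)))
  # log-additivity over a split
  d <- make_dataset(12, utr_len = 30, seed = 6)
  pwm <- build_pwm(d, d$records$gene_id, -12L, 6L)
  lo <- pwm; lo$to_pos <- -5L; lo$positions <- seq(-12L, -5L)
  lo$freqs <- pwm$freqs[1:8, , drop = FALSE]
  hi <- pwm; hi$from_pos <- -4L; hi$positions <- setdiff(seq(-4L, 6L), 0L)
  hi$freqs <- pwm$freqs[9:18, , drop = FALSE]
  r <- d$records[1, ]
  expect_equal(pwm_score(r, pwm), pwm_score(r, lo) + pwm_score(r, hi))
  # vectorized scorer agrees
  expect_equal(teseq:::.pwm_score_vec(d, pwm),
               vapply(seq_len(12), function(g)
                 pwm_score(d$records[g, ], pwm), numeric(1)))
})

test_that("cap_pwm is cap-anchored with the containment rule", {
  d <- make_dataset(10, utr_len = 12, seed = 9)
  pwm <- cap_pwm(d, d$records$gene_id)
  expect_equal(nrow(pwm$freqs), 5L)
  rec <- d$records[1, ]
  expect_equal(pwm_score(rec, pwm),
               sum(log10(pwm$freqs[cbind(1:5,
                 match(strsplit(substr(rec$seq, 1, 5), "")[[1]],
                       colnames(pwm$freqs)))])))
  rec3 <- make_dataset(1, utr_len = 3, seed = 9)$records[1, ]
  expect_true(is.na(pwm_score(rec3, pwm)))
})

test_that("scan_ape_boundaries recovers a planted iAUG-context signal", {
  # TR driven only by similarity of -6..-1 to an A-rich context
  # n large enough that the high-TR cohort's self-scoring inflation on
  # signal-free flank positions stays below the planted-signal gain
  set.seed(77)
  n <- 1000
  rows <- lapply(seq_len(n), function(i) {
    strong <- runif(1)
    ctx <- sample(c("A", "G"), 6, replace = TRUE,
                  prob = c(0.2 + 0.7 * strong, 0.8 - 0.7 * strong))
    utr <- paste0(random_rna(24, prob = c(0.45, 0.05, 0.05, 0.45)),
                  paste(ctx, collapse = ""))
    make_record(utr = utr, cds = paste0("AUG", strrep("GCA", 10), "UAA"),
                gene_id = sprintf("g%04d", i),
                tr = 10^(strong + rnorm(1, 0, 0.2)))
  })
  d <- te_dataset(do.call(rbind, rows), quiet = TRUE)
  scan <- scan_ape_boundaries(d, from_grid = seq(-5L, -30L, by = -5L),
                              to_grid = c(-1L, 8L))
  expect_true(all(c("from", "to", "r2") %in% names(scan$grid)))
  expect_true(any(scan$grid$from == -5 & scan$grid$to == -1))
  # argmax 5' extent covers the planted -6..-1 signal within 5 nt
  expect_lte(scan$ape_bounds[1], -5L)
  expect_gte(scan$ape_bounds[1], -15L)
})

test_that("trinuc ratio tables behave under null and planted signal", {
  d <- make_dataset(60, utr_len = 30, n_codons = 20, seed = 12)
  # identical cohorts: force high and low to the same gene set
  co_same <- list(high = d$records$gene_id[1:6], low = d$records$gene_id[1:6])
  rt <- trinuc_ratio_table(d, "UTR5", c(-35L, 28L), co_same)
  expect_true(all(abs(rt$ratios[!is.na(rt$ratios)] - 1) < 1e-12))
  # uAUG-planted generator: AUG ratio < 1 in the 5'UTR
  g <- generate_dataset(generator_config(
    n_genes = 600, seed = 42, target_r2 = 0.7,
    effect_weights = c(uaug = 1)))
  rt2 <- trinuc_ratio_table(g$dataset, "UTR5", c(-35L, 28L))
  expect_lt(rt2$ratios["AUG"], 1)
  expect_equal(ratio_correlation(rt2, rt2), 1)
  # too few shared trinucleotides -> error
  rt3 <- rt2; rt3$ratios[] <- NA_real_; rt3$ratios[1:2] <- 1
  expect_error(ratio_correlation(rt2, rt3), "fewer than 3")
})

test_that("build_motif_sets scores parts with part-appropriate uAPE PWMs", {
  set.seed(19)
  n <- 120
  rows <- lapply(seq_len(n), function(i) {
    u <- sample(c(8, 25, 60), 1)
    make_record(utr = random_rna(u),
                cds = paste0("AUG", paste(sample(sense_codons(), 30,
                  replace = TRUE), collapse = ""), "UAA"),
                gene_id = sprintf("g%03d", i), tr = rlnorm(1))
  })
  d <- te_dataset(do.call(rbind, rows), scheme = "three_part_cerevisiae",
                  quiet = TRUE)
  ms <- suppressWarnings(build_motif_sets(d, c(-35L, 28L)))
  expect_equal(ms$pwms$uAPE$part1_short$from_pos, -5L)
  expect_equal(ms$pwms$uAPE$part2_mid$from_pos, -20L)
  expect_equal(ms$pwms$uAPE$part3_long$from_pos, -35L)
  # selected-set sizes within the candidate pool bound
  for (reg in c("uAPE", "dAPE", "five_prime_of_APE"))
    expect_lte(length(ms[[reg]]$fit$selected), 81L)
  # short-UTR genes scored (not NA) thanks to the -5..-1 PWM
  short <- d$records$utr5_len < 20 & d$records$utr5_len >= 5
  expect_true(all(!is.na(ms$uAPE$candidates[short, "uAPE.pwm"])))
})

test_that("uAPE selection finds a planted AUG-density signal", {
  # TR depends only on AUG count in the 35 nt upstream of the iAUG
  set.seed(55)
  n <- 300
  rows <- lapply(seq_len(n), function(i) {
    k <- sample(0:4, 1)
    utr <- strsplit(random_rna(50), "")[[1]]
    for (j in seq_len(k)) {
      pos <- 16 + 9 * j   # inside -35..-1
      utr[pos:(pos + 2)] <- c("A", "U", "G")
    }
    make_record(utr = paste(utr, collapse = ""),
                cds = paste0("AUG", strrep("GAC", 12), "UAA"),
                gene_id = sprintf("g%03d", i),
                tr = 10^(-0.5 * k + rnorm(1, 0, 0.3)))
  })
  d <- te_dataset(do.call(rbind, rows), quiet = TRUE)
  ms <- suppressWarnings(build_motif_sets(d, c(-35L, 28L)))
  expect_true("uAPE.AUG" %in% ms$uAPE$fit$selected)
})
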
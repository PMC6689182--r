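test_that("rank_features uses nearest-rank percentiles", {
  e <- c(-10, -8, -6, -4, -2)
  rf <- rank_features(e)
  expect_equal(unname(rf["rank_min"]), -10)
  expect_equal(unname(rf["rank_max"]), -2)
  expect_equal(unname(rf["rank_25"]), -8)   # ceil(0.25*5) = 2nd smallest
  expect_equal(unname(rf["rank_10"]), -10)  # ceil(0.1*5) = 1st
  # single window: all ranks equal it
  expect_true(all(rank_features(-3.5) == -3.5))
  # brute force on random profiles
  set.seed(31)
  for (i in 1:200) {
    e <- round(rnorm(sample(1:40, 1), -5, 3), 2)
    rf <- rank_features(e)
    s <- sort(e)
    expect_equal(unname(rf[c("rank_10", "rank_25", "rank_75", "rank_90")]),
                 s[pmax(1, ceiling(c(.1, .25, .75, .9) * length(e)))])
  }
  expect_true(all(is.na(rank_features(numeric(0)))))
})

test_that("location features respect UTR length and window existence", {
  d <- make_dataset(1, utr_len = 100, n_codons = 40, seed = 4)
  w <- enumerate_windows(d$records[1, ], 20L)
  lf <- location_features(w, 100L)
  expect_true(all(!is.na(lf)))
  d30 <- make_dataset(1, utr_len = 30, n_codons = 40, seed = 4)
  w30 <- enumerate_windows(d30$records[1, ], 20L)
  lf30 <- location_features(w30, 30L)
  expect_true(is.na(lf30["loc_-65"]))
  expect_equal(unname(lf30["loc_-30"]), unname(lf30["loc_5cap"]))
})

test_that("threshold features score non-qualifying genes 0, not missing", {
  th <- dataset_thresholds(c(-10, -9, -8, -7, -6, -5, -4, -3, -2, -1))
  expect_equal(unname(th["q20"]), -9)  # nearest rank: 2nd of 10
  tf_none <- threshold_features(c(-1.5, -1.2), th)   # nothing <= q20
  expect_equal(unname(tf_none["pct_le20"]), 0)
  expect_equal(unname(tf_none["sum_le20"]), 0)
  tf_all <- threshold_features(c(-10, -9.5), th)
  expect_equal(unname(tf_all["pct_le20"]), 100)
  # brute-force sums on random data
  set.seed(37)
  pool <- round(rnorm(500, -5, 2), 3)
  th <- dataset_thresholds(pool)
  for (i in 1:50) {
    e <- sample(pool, 20)
    tf <- threshold_features(e, th)
    expect_equal(unname(tf["sum_le10"]), sum(e[e <= th["q10"]]))
    expect_equal(unname(tf["sum_ge80"]), sum(e[e >= th["q80"]]))
    expect_true(all(tf[c("pct_le20", "pct_ge80", "pct_ge90")] >= 0 &
                      tf[c("pct_le20", "pct_ge80", "pct_ge90")] <= 100))
  }
})

test_that("whole_feature equals folding the cap..+35 subsequence", {
  rec <- make_dataset(1, utr_len = 25, n_codons = 30, seed = 8)$records[1, ]
  expect_equal(whole_feature(rec),
               fold_window(substr(rec$seq, 1, rec$utr5_len + 35))$delta_g)
  rec0 <- make_record(utr = "", cds = paste0("AUG", strrep("GCU", 20), "UAA"))
  expect_equal(whole_feature(rec0),
               fold_window(substr(rec0$seq, 1, 35))$delta_g)
})

test_that("nonoverlap_min_windows selects greedily without overlap", {
  # geometry: utr 10, L 35 -> only one window can fit
  rec <- make_dataset(1, utr_len = 10, n_codons = 40, seed = 2)$records[1, ]
  w <- enumerate_windows(rec, 35L)
  sel <- nonoverlap_min_windows(w, 2L, 10L)
  expect_equal(nrow(sel), 1L)
  # constructed windows; oracle = exhaustive search over non-overlap pairs
  wins <- data.frame(start = c(-100L, -90L, -60L, -20L),
                     length = 20L, delta_g = c(-9, -8.5, -7, -5))
  sel <- nonoverlap_min_windows(wins, 3L, 120L)
  expect_equal(sel$start, c(-100L, -60L, -20L))  # -90 overlaps -100
  # energy ties -> 5'-most start
  tie <- data.frame(start = c(-50L, -80L), length = 10L, delta_g = c(-4, -4))
  expect_equal(nonoverlap_min_windows(tie, 1L, 100L)$start, -80L)
})

test_that("build_fold_matrix has the documented shape and ordering", {
  d <- make_dataset(12, utr_len = 40, n_codons = 30, seed = 16)
  lens <- c(10L, 35L)
  X <- build_fold_matrix(d, lens)
  expect_equal(ncol(X), 2 * 21 + 1)  # families per length + whole
  expect_equal(rownames(X), d$records$gene_id)
  expect_true("fold.whole" %in% colnames(X))
  # rank_min is the most negative rank feature per gene
  rk <- X[, paste0("fold.L35.rank_", c("min", "10", "25", "75", "90", "max"))]
  expect_true(all(rk[, 1] <= rk[, -1] + 1e-12))
  # pombe constraint: windows past +30 removed, whole dropped
  Xp <- build_fold_matrix(d, lens, pombe_3prime30_constraint = TRUE)
  expect_false("fold.whole" %in% colnames(Xp))
  # a 35-nt window starting at -1 reaches +34 > +30: loc_-1 missing
  expect_true(all(is.na(Xp[, "fold.L35.loc_-1"])))
  expect_false(all(is.na(Xp[, "fold.L35.loc_-35"])))
})

test_that("dataset thresholds are invariant to gene order", {
  d <- make_dataset(15, utr_len = 30, n_codons = 20, seed = 21)
  X1 <- build_fold_matrix(d, 15L, include_whole = FALSE)
  d2 <- d; d2$records <- d$records[rev(seq_len(15)), ]
  X2 <- build_fold_matrix(d2, 15L, include_whole = FALSE)
  expect_equal(X1, X2[rownames(X1), ])
})

test_that("impute_features fills NAs with column means and keeps the mask", {
  X <- matrix(c(1, NA, 3, NA, NA, NA), 3, 2,
              dimnames = list(NULL, c("a", "b")))
  Xi <- impute_features(X)
  expect_equal(unname(Xi[2, "a"]), 2)
  expect_equal(unname(Xi[, "b"]), c(0, 0, 0))  # all-missing column -> 0
  expect_equal(sum(attr(Xi, "mask")), 4)
})
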
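test_that("single-part single-feature fit equals the textbook regression", {
  set.seed(1)
  x <- rnorm(50); y <- 2 + 3 * x + rnorm(50)
  f <- fit_multipart(matrix(x, dimnames = list(NULL, "x")), y)
  ref <- lm(y ~ x)
  expect_equal(unname(f$coefficients$part1), unname(coef(ref)))
  expect_equal(f$r2, summary(ref)$r.squared)
  # exact linear response
  f2 <- fit_multipart(matrix(x, dimnames = list(NULL, "x")), 1 + 2 * x)
  expect_equal(f2$r2, 1)
})

test_that("pooled R2 equals squared Pearson(obs, pred) to 1e-10", {
  set.seed(2)
  for (i in 1:20) {
    n <- 120
    X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- rnorm(n)
    parts <- sample(c("p1", "p2", "p3"), n, replace = TRUE)
    f <- fit_multipart(X, y, parts)
    expect_equal(f$r2, cor(y, f$fitted)^2, tolerance = 1e-10)
    # nesting within parts
    f2 <- fit_multipart(X[, 1:2], y, parts)
    expect_gte(f$r2, f2$r2 - 1e-9)
  }
})

test_that("fit_multipart guards undersized parts and aliased columns", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(10)
  expect_error(fit_multipart(X, y, parts = c(rep("p1", 8), rep("tiny", 2))),
               "tiny")
  Xa <- cbind(X, a2 = X[, 1])  # aliased
  expect_warning(f <- fit_multipart(Xa, y), "aliased")
  expect_equal(f$k, 3L)  # intercept + 2 estimable columns
})

test_that("BIC forward selection finds signal among noise and stops on null", {
  set.seed(3)
  n <- 400
  signal <- rnorm(n)
  X <- cbind(sig = signal, matrix(rnorm(n * 6), n, 6,
             dimnames = list(NULL, paste0("noise", 1:6))))
  y <- 1.5 * signal + rnorm(n, 0, 0.8)
  f <- forward_select_bic(X, y)
  expect_true("sig" %in% f$selected)
  expect_lte(length(f$selected), 3L)
  # duplicated column changes nothing
  X2 <- cbind(X, sig_dup = X[, "sig"])
  f2 <- suppressWarnings(forward_select_bic(X2, y))
  expect_equal(f2$bic, f$bic)
  # null response: nothing selected
  f0 <- forward_select_bic(X, rnorm(n))
  expect_length(f0$selected, 0L)
})

test_that("forward selection matches exhaustive-subset BIC on small cases", {
  exhaustive_bic <- function(X, y, parts = NULL) {
    best <- fit_multipart(X[, integer(0), drop = FALSE], y, parts)$bic
    p <- ncol(X)
    for (m in seq_len(p)) {
      combos <- utils::combn(p, m)
      for (j in seq_len(ncol(combos))) {
        b <- fit_multipart(X[, combos[, j], drop = FALSE], y, parts)$bic
        if (b < best) best <- b
      }
    }
    best
  }
  set.seed(4)
  for (i in 1:10) {
    n <- 150
    p <- sample(4:7, 1)
    k <- sample(1:2, 1)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    beta <- c(runif(k, 0.5, 1.5), rep(0, p - k))
    y <- X %*% beta + rnorm(n)
    f <- forward_select_bic(X, y)
    expect_equal(f$bic, exhaustive_bic(X, y), tolerance = 1e-9)
  }
})

test_that("bootstrap_r2 is seeded, degenerate at B = 1, and covers", {
  set.seed(5)
  n <- 150
  X <- matrix(rnorm(n), dimnames = list(NULL, "x"))
  y <- X[, 1] + rnorm(n, 0, 0.7)
  b1 <- bootstrap_r2(X, y, B = 1, seed = 9)
  expect_equal(b1$lo, b1$hi)
  b <- bootstrap_r2(X, y, B = 200, seed = 9)
  expect_identical(b, bootstrap_r2(X, y, B = 200, seed = 9))
  full <- fit_multipart(X, y)$r2
  # CI contains the full-data r2 in most repetitions
  hits <- vapply(1:10, function(i) {
    Xi <- matrix(rnorm(n), dimnames = list(NULL, "x"))
    yi <- Xi[, 1] + rnorm(n, 0, 0.7)
    ci <- bootstrap_r2(Xi, yi, B = 200, seed = i)
    r2i <- fit_multipart(Xi, yi)$r2
    ci$lo <= r2i && r2i <= ci$hi
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  expect_true(b$lo <= full && full <= b$hi)
})

test_that("collinearity overlap: identical, orthogonal, shared latent", {
  set.seed(6)
  n <- 500
  x <- rnorm(n); z <- rnorm(n)
  y <- x + z + rnorm(n, 0, 0.5)
  A <- matrix(x, dimnames = list(NULL, "x"))
  B <- matrix(z, dimnames = list(NULL, "z"))
  expect_equal(collinearity_overlap(A, A, y)$overlap_pct, 100)
  expect_lt(collinearity_overlap(A, B, y)$overlap_pct, 15)
  # two noisy readouts of one latent: high overlap
  lat <- rnorm(n)
  y2 <- lat + rnorm(n, 0, 0.5)
  A2 <- matrix(lat + rnorm(n, 0, 0.3), dimnames = list(NULL, "a"))
  B2 <- matrix(lat + rnorm(n, 0, 0.3), dimnames = list(NULL, "b"))
  ov <- collinearity_overlap(A2, B2, y2)
  expect_gt(ov$overlap_pct, 60)
  expect_gte(ov$r2_ab, max(ov$r2_a, ov$r2_b) - 1e-9)
  # zero-signal set is undefined
  expect_true(is.na(collinearity_overlap(
    matrix(rep(1, n), dimnames = list(NULL, "const")), B, y)$overlap_pct))
})

test_that("overlap invariants hold on random designs", {
  set.seed(7)
  for (i in 1:50) {
    n <- 150
    A <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a1", "a2")))
    B <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("b1", "b2")))
    y <- rowSums(A) + rowSums(B) * 0.5 + rnorm(n)
    ov <- collinearity_overlap(A, B, y)
    expect_gte(ov$r2_ab, max(ov$r2_a, ov$r2_b) - 1e-9)
    if (!is.na(ov$overlap_pct))
      expect_true(ov$overlap_pct >= 0 && ov$overlap_pct <= 100)
  }
})

test_that("combined_model nests its member sets", {
  set.seed(8)
  n <- 300
  sets <- list(s1 = matrix(rnorm(n), dimnames = list(NULL, "x1")),
               s2 = matrix(rnorm(n), dimnames = list(NULL, "x2")))
  y <- sets$s1[, 1] - sets$s2[, 1] + rnorm(n)
  cm <- combined_model(sets, y, bootstrap = 50, seed = 2)
  expect_gte(cm$r2, max(cm$set_r2) - 1e-9)
  expect_true(cm$ci$lo <= cm$ci$hi)
  cm2 <- combined_model(sets, y, reselect = TRUE)
  expect_lte(length(cm2$selected), 2L)
})

test_that("UTR-length increment is non-negative and zero for duplicates", {
  set.seed(9)
  n <- 200
  u <- sample(5:200, n, replace = TRUE)
  X <- matrix(rnorm(n), dimnames = list(NULL, "f"))
  y <- X[, 1] + 0.1 * log10(u) + rnorm(n)
  inc <- utr_length_increment(X, u, y)
  expect_gte(inc$delta_pct_points, 0)
  # adding a duplicate of an existing feature
  Xd <- cbind(X, dup = X[, 1])
  f1 <- fit_multipart(X, y)
  f2 <- suppressWarnings(fit_multipart(Xd, y))
  expect_equal(f1$r2, f2$r2, tolerance = 1e-12)
})
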
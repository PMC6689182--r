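#' Multipart ordinary least squares fit
#'
#' One OLS model per part (group of genes), with intercept and coefficients
#' free to differ between parts; predictions are pooled across parts and the
#' model R^2 is the square of the Pearson correlation between observed and
#' pooled predicted responses.
#'
#' @param X numeric feature matrix (may have zero columns: intercept-only),
#'   no NAs (see [impute_features()]).
#' @param y response (log10 TR).
#' @param parts character vector of part labels, one per gene; NULL = one
#'   part.
#' @return object of class `te_fit`: list with `selected` (colnames of X),
#'   `coefficients` (per part), `r2`, `n`, `k` (estimable parameters),
#'   `bic`, `fitted`, `rss`, `parts`.
#' @export
fit_multipart <- function(X, y, parts = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n || ncol(X) == 0)
  if (ncol(X) == 0) X <- matrix(numeric(0), nrow = n, ncol = 0)
  if (anyNA(X)) stop("X contains NAs; impute or subset first")
  if (is.null(parts)) parts <- rep("part1", n)
  stopifnot(length(parts) == n)
  fitted <- numeric(n)
  k_tot <- 0L
  coefs <- list()
  for (p in unique(parts)) {
    idx <- which(parts == p)
    Xp <- cbind(`(Intercept)` = 1, X[idx, , drop = FALSE])
    if (length(idx) <= ncol(X) + 1L)
      stop("part '", p, "' has ", length(idx),
           " genes for ", ncol(X), " features; undersized part")
    f <- lm.fit(Xp, y[idx])
    if (f$rank < ncol(Xp))
      warning("part '", p, "': rank-deficient design, ",
              ncol(Xp) - f$rank, " aliased column(s) dropped")
    fitted[idx] <- f$fitted.values
    k_tot <- k_tot + f$rank
    coefs[[p]] <- f$coefficients
  }
  rss <- sum((y - fitted)^2)
  # an effectively constant prediction (e.g. aliased constant column) has
  # no explanatory power; the tolerance guards float noise in lm.fit
  r2 <- if (stats::sd(fitted) > 1e-9 * max(1, stats::sd(y)) &&
            stats::sd(y) > 0) cor(y, fitted)^2 else 0
  structure(list(selected = colnames(X), coefficients = coefs,
                 r2 = r2, n = n, k = k_tot,
                 bic = n * log(rss / n) + k_tot * log(n),
                 fitted = fitted, rss = rss, parts = parts),
            class = "te_fit")
}

#' @export
print.te_fit <- function(x, ...) {
  cat("te_fit: ", length(x$selected), " feature(s), ",
      length(x$coefficients), " part(s), n = ", x$n,
      ", R2 = ", signif(x$r2, 4), ", BIC = ", signif(x$bic, 6), "\n",
      sep = "")
  invisible(x)
}

#' Forward feature selection by Bayesian Information Criterion
#'
#' BIC = n*ln(RSS_pooled/n) + k*ln(n) with k the total number of estimable
#' parameters across parts.  Starting from the intercept-only model, the
#' candidate whose addition gives the lowest BIC is added greedily; selection
#' stops when no addition lowers BIC.  Ties go to the earlier column.
#'
#' @param X candidate feature matrix (named columns; NAs imputed first).
#' @param y response.
#' @param parts part labels (see [fit_multipart()]).
#' @param max_features optional cap on the number selected.
#' @param trace log each step via `message()`.
#' @return a `te_fit` for the selected subset (zero features if nothing
#'   improves on the intercept-only model).
#' @export
forward_select_bic <- function(X, y, parts = NULL, max_features = Inf,
                               trace = FALSE) {
  X <- as.matrix(X)
  stopifnot(ncol(X) >= 1)
  if (anyNA(X)) X <- impute_features(X)
  sel <- integer(0)
  cur <- fit_multipart(X[, sel, drop = FALSE], y, parts)
  np <- length(unique(if (is.null(parts)) "part1" else parts))
  repeat {
    if (length(sel) >= max_features) break
    cand <- setdiff(seq_len(ncol(X)), sel)
    # a part must keep more genes than features + intercept
    min_part <- min(as.integer(table(
      if (is.null(parts)) rep("part1", length(y)) else parts)))
    if (length(sel) + 2L >= min_part) break
    if (!length(cand)) break
    bics <- vapply(cand, function(j)
      fit_multipart(X[, c(sel, j), drop = FALSE], y, parts)$bic, numeric(1))
    best <- which.min(bics)
    if (bics[best] >= cur$bic - 1e-9) break
    sel <- c(sel, cand[best])
    cur <- fit_multipart(X[, sel, drop = FALSE], y, parts)
    if (trace)
      message("BIC step ", length(sel), ": + ", colnames(X)[cand[best]],
              " (BIC ", signif(cur$bic, 6), ", R2 ", signif(cur$r2, 4), ")")
  }
  cur
}

#' Bootstrap confidence interval for a fitted model's R^2
#'
#' Genes are resampled with replacement within each part, coefficients are
#' refitted with the selected features frozen, and the pooled R^2 is
#' recomputed; the CI is the 2.5/97.5 percentile of the B bootstrap values.
#'
#' @param X selected-feature matrix (no NAs).
#' @param y response.
#' @param parts part labels.
#' @param B number of bootstrap resamples (paper convention: 1000).
#' @param seed RNG seed.
#' @return list with `lo`, `hi`, `r2_boot` (the B values).
#' @export
bootstrap_r2 <- function(X, y, parts = NULL, B = 1000, seed = 1) {
  X <- as.matrix(X)
  n <- length(y)
  if (is.null(parts)) parts <- rep("part1", n)
  set.seed(seed)
  idx_by_part <- split(seq_len(n), parts)
  r2b <- numeric(B)
  for (b in seq_len(B)) {
    idx <- unlist(lapply(idx_by_part, function(ii)
      ii[sample.int(length(ii), length(ii), replace = TRUE)]),
      use.names = FALSE)
    r2b[b] <- fit_multipart(X[idx, , drop = FALSE], y[idx], parts[idx])$r2
  }
  ci <- quantile(r2b, c(0.025, 0.975), names = FALSE)
  list(lo = ci[1], hi = ci[2], r2_boot = r2b)
}

#' Collinearity overlap between two feature sets
#'
#' For feature sets A and B, fits A, B and the union AB on the same genes
#' and reports `100 * max((R2A + R2B - R2AB)/R2A, (R2A + R2B - R2AB)/R2B)`,
#' the percent of regulatory control in overlap, clipped to [0, 100] after a
#' 1e-6 numerical tolerance.  Undefined (NA) when R2A or R2B <= 0.
#'
#' @param XA,XB numeric matrices for the two sets (same gene rows; NAs
#'   imputed; genes missing in either set should be dropped upstream).
#' @param y response.
#' @param parts part labels.
#' @return list with `r2_a`, `r2_b`, `r2_ab`, `overlap_pct`.
#' @export
collinearity_overlap <- function(XA, XB, y, parts = NULL) {
  XA <- impute_features(as.matrix(XA))
  XB <- impute_features(as.matrix(XB))
  fa <- fit_multipart(XA, y, parts)
  fb <- fit_multipart(XB, y, parts)
  XAB <- cbind(XA, XB)
  colnames(XAB) <- make.unique(c(colnames(XA), colnames(XB)))
  fab <- fit_multipart(XAB, y, parts)
  r2a <- fa$r2; r2b <- fb$r2; r2ab <- fab$r2
  if (r2a <= 0 || r2b <= 0)
    return(list(r2_a = r2a, r2_b = r2b, r2_ab = r2ab,
                overlap_pct = NA_real_))
  ov <- 100 * max((r2a + r2b - r2ab) / r2a, (r2a + r2b - r2ab) / r2b)
  if (ov > 100 && ov < 100 + 1e-6 * 100) ov <- 100
  ov <- min(max(ov, 0), 100)
  list(r2_a = r2a, r2_b = r2b, r2_ab = r2ab, overlap_pct = ov)
}

#' Combined model over several pre-selected feature sets
#'
#' Concatenates the (already BIC-selected) feature sets and fits one
#' multipart OLS; with `reselect = TRUE` BIC forward selection is re-run over
#' the union instead.  Optionally bootstraps the R^2 CI.
#'
#' @param sets named list of numeric matrices (same gene rows).
#' @param y response.
#' @param parts part labels.
#' @param reselect re-run BIC selection over the union.
#' @param bootstrap number of bootstrap resamples (0 = none).
#' @param seed bootstrap seed.
#' @return a `te_fit`, with elements `ci` (lo/hi) if bootstrapped and
#'   `set_r2` (named univariate-set R^2 values).
#' @export
combined_model <- function(sets, y, parts = NULL, reselect = FALSE,
                           bootstrap = 0, seed = 1) {
  stopifnot(is.list(sets), length(sets) >= 1)
  sets <- lapply(sets, function(s) impute_features(as.matrix(s)))
  set_r2 <- vapply(sets, function(s) fit_multipart(s, y, parts)$r2,
                   numeric(1))
  X <- do.call(cbind, sets)
  colnames(X) <- make.unique(unlist(lapply(sets, colnames)))
  fit <- if (reselect) forward_select_bic(X, y, parts)
         else fit_multipart(X, y, parts)
  fit$set_r2 <- set_r2
  if (bootstrap > 0) {
    Xs <- X[, fit$selected, drop = FALSE]
    fit$ci <- bootstrap_r2(Xs, y, parts, B = bootstrap, seed = seed)[c("lo", "hi")]
  }
  fit
}

#' Variance increment from adding 5'UTR length
#'
#' Percentage points of R^2 gained by adding log10(5'UTR length) to a base
#' model (a diagnostic: the paper found 0.03-0.62 points and dropped the
#' feature).  Genes with a 0-length UTR contribute log10(1).
#'
#' @param X base-model feature matrix (no NAs).
#' @param utr5_len integer vector of 5'UTR lengths.
#' @param y response.
#' @param parts part labels.
#' @return list with `r2_base`, `r2_plus`, `delta_pct_points`.
#' @export
utr_length_increment <- function(X, utr5_len, y, parts = NULL) {
  X <- impute_features(as.matrix(X))
  base <- fit_multipart(X, y, parts)
  Xp <- cbind(X, UTR5len = log10(pmax(utr5_len, 1L)))
  plus <- fit_multipart(Xp, y, parts)
  list(r2_base = base$r2, r2_plus = plus$r2,
       delta_pct_points = 100 * (plus$r2 - base$r2))
}
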
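#' Default window-length grid for fold features
#'
#' Twenty-one lengths from 6 to 100 nt, densest where the per-species optima
#' of the most-folded-window feature lie (25-60 nt).
#' @export
default_length_grid <- function() {
  c(6L, 8L, 10L, 15L, 20L, 25L, 30L, 35L, 40L, 45L, 50L, 55L, 60L,
    65L, 70L, 75L, 80L, 85L, 90L, 95L, 100L)
}

.fold_families <- function() {
  c("loc_5cap", "loc_-65", "loc_-35", "loc_-30", "loc_-6", "loc_-1",
    "rank_min", "rank_10", "rank_25", "rank_75", "rank_90", "rank_max",
    "mean", "pct_le20", "pct_ge80", "pct_ge90",
    "sum_le5", "sum_le10", "sum_le20", "sum_ge80", "sum_ge90")
}

#' Nearest-rank quantile
#'
#' The ceiling(p*n)-th smallest value; used for both per-gene rank features
#' and pooled dataset thresholds.
#' @param x numeric vector.
#' @param p probability in (0, 1].
#' @export
nearest_rank_quantile <- function(x, p) {
  x <- sort(x)
  x[max(1L, ceiling(p * length(x)))]
}

#' Rank-based window features of one gene
#'
#' min, 10%, 25%, 75%, 90% and max of the gene's window free energies, the
#' percentiles by nearest rank.  Windows for different rank features may
#' overlap; no exclusion is applied.
#'
#' @param delta_g numeric vector of window energies (one gene, one length).
#' @return named numeric vector over the rank families (NA if no windows).
#' @export
rank_features <- function(delta_g) {
  fam <- c("rank_min", "rank_10", "rank_25", "rank_75", "rank_90", "rank_max")
  if (!length(delta_g)) return(setNames(rep(NA_real_, 6L), fam))
  setNames(c(min(delta_g),
             nearest_rank_quantile(delta_g, 0.10),
             nearest_rank_quantile(delta_g, 0.25),
             nearest_rank_quantile(delta_g, 0.75),
             nearest_rank_quantile(delta_g, 0.90),
             max(delta_g)), fam)
}

#' Location-based window features of one gene
#'
#' Free energy of the window whose 5' nucleotide lies at the 5' cap or at
#' iAUG coordinates -65, -35, -30, -6, -1.  A feature is missing when the
#' 5'UTR is too short for that window to exist (or when the window was
#' dropped, e.g. by the +30 constraint).
#'
#' @param windows data.frame from [enumerate_windows()].
#' @param utr5_len the gene's 5'UTR length.
#' @return named numeric vector over the location families.
#' @export
location_features <- function(windows, utr5_len) {
  fam <- c("loc_5cap", "loc_-65", "loc_-35", "loc_-30", "loc_-6", "loc_-1")
  pos <- c(-utr5_len, -65L, -35L, -30L, -6L, -1L)
  val <- windows$delta_g[match(pos, windows$start)]
  val[utr5_len == 0L] <- NA_real_
  setNames(val, fam)
}

#' Pooled dataset thresholds for window energies
#'
#' Nearest-rank percentiles (5, 10, 20, 80, 90) of the free energies of all
#' windows of all genes, computed once per (dataset, window length).
#'
#' @param all_delta_g energies pooled over genes.
#' @return named numeric vector `q5, q10, q20, q80, q90`.
#' @export
dataset_thresholds <- function(all_delta_g) {
  ps <- c(q5 = 0.05, q10 = 0.10, q20 = 0.20, q80 = 0.80, q90 = 0.90)
  vapply(ps, function(p) nearest_rank_quantile(all_delta_g, p), numeric(1))
}

#' Threshold-based window features of one gene
#'
#' Percent of the gene's windows at or beyond a pooled threshold, and sums of
#' the qualifying energies.  A gene with no qualifying windows scores 0, not
#' missing; a gene with no windows at all is missing.
#'
#' @param delta_g the gene's window energies.
#' @param thresholds from [dataset_thresholds()].
#' @return named numeric vector over the threshold families plus `mean`.
#' @export
threshold_features <- function(delta_g, thresholds) {
  fam <- c("mean", "pct_le20", "pct_ge80", "pct_ge90",
           "sum_le5", "sum_le10", "sum_le20", "sum_ge80", "sum_ge90")
  if (!length(delta_g)) return(setNames(rep(NA_real_, length(fam)), fam))
  th <- thresholds
  setNames(c(mean(delta_g),
             100 * mean(delta_g <= th["q20"]),
             100 * mean(delta_g >= th["q80"]),
             100 * mean(delta_g >= th["q90"]),
             sum(delta_g[delta_g <= th["q5"]]),
             sum(delta_g[delta_g <= th["q10"]]),
             sum(delta_g[delta_g <= th["q20"]]),
             sum(delta_g[delta_g >= th["q80"]]),
             sum(delta_g[delta_g >= th["q90"]])), fam)
}

#' Free energy of the whole 5' region (cap to +35)
#'
#' @param rec one record.
#' @param backend folding backend.
#' @return dG in kcal/mol.
#' @export
whole_feature <- function(rec, backend = "builtin_simplified") {
  end <- rec$utr5_len + min(35L, rec$cds_len)
  fold_window(substr(rec$seq, 1L, end), backend)$delta_g
}

#' Greedy non-overlapping most-folded windows
#'
#' Selects the window with the global minimum free energy, then repeatedly
#' the minimum among windows sharing no nucleotide with any already selected,
#' up to `k` windows.  Ties are broken toward the 5'-most start.  Fewer than
#' `k` rows are returned when the 5' region is too short.
#'
#' @param windows data.frame from [enumerate_windows()] (one gene, one L).
#' @param k number of windows (2 or 3 in the collinearity analyses).
#' @param utr5_len the gene's 5'UTR length (to place windows on the
#'   transcript).
#' @return subset of `windows`, in selection order.
#' @export
nonoverlap_min_windows <- function(windows, k, utr5_len) {
  sel <- integer(0)
  if (!nrow(windows)) return(windows[sel, , drop = FALSE])
  i0 <- iaug_to_index(windows$start, utr5_len)
  i1 <- i0 + windows$length - 1L
  avail <- rep(TRUE, nrow(windows))
  while (length(sel) < k && any(avail)) {
    cand <- which(avail)
    best <- cand[order(windows$delta_g[cand], windows$start[cand])][1]
    sel <- c(sel, best)
    avail <- avail & (i1 < i0[best] | i0 > i1[best])
  }
  windows[sel, , drop = FALSE]
}

#' Window energy profiles for every gene of a dataset
#'
#' @param d a [te_dataset].
#' @param lengths window-length grid.
#' @param backend folding backend.
#' @param pombe_3prime30_constraint drop windows extending 3' of +30.
#' @return nested list `profiles[[L]][[gene]]` of data.frames (`start`,
#'   `delta_g`); used by [build_fold_matrix()] and the window-collinearity
#'   analyses.
#' @export
fold_profiles <- function(d, lengths = default_length_grid(),
                          backend = "builtin_simplified",
                          pombe_3prime30_constraint = FALSE) {
  recs <- d$records
  pars <- rna_energy_params()
  bk <- .check_backend(backend)
  out <- lapply(lengths, function(L) {
    per_gene <- vector("list", nrow(recs))
    for (g in seq_len(nrow(recs))) {
      u <- recs$utr5_len[g]
      if (u == 0L) {
        per_gene[[g]] <- list(start = integer(0), delta_g = numeric(0))
        next
      }
      if (is.function(bk)) {
        w <- enumerate_windows(recs[g, ], L, bk, structures = FALSE)
        start <- w$start; dg <- w$delta_g
      } else {
        region_len <- min(u + recs$cds_len[g], u + L - 1L)
        dg <- .fold_windows_cpp(substr(recs$seq[g], 1L, region_len),
                                as.integer(L), u, pars, FALSE)$delta_g
        keep <- which(!is.na(dg))
        start <- keep - u - 1L   # index_to_iaug for UTR positions
        dg <- dg[keep]
      }
      if (pombe_3prime30_constraint && length(start)) {
        ok <- (start + u + 1L) + L - 1L <= u + 30L  # window end index
        start <- start[ok]; dg <- dg[ok]
      }
      per_gene[[g]] <- list(start = start, delta_g = dg)
    }
    names(per_gene) <- recs$gene_id
    per_gene
  })
  names(out) <- as.character(lengths)
  out
}

#' Build the RNA-folding feature matrix
#'
#' One column per (window length, family) pair, named
#' `fold.L{length}.{family}`, plus `fold.whole` (free energy of the cap..+35
#' fold) unless suppressed.  With the S. pombe constraint every window
#' extending 3' of +30 is removed before features are computed and the
#' `whole` column is omitted.
#'
#' @inheritParams fold_profiles
#' @param include_whole include the `fold.whole` column.
#' @param profiles optional precomputed result of [fold_profiles()].
#' @return numeric matrix, rows = genes (dataset order), `NA` = missing.
#' @export
build_fold_matrix <- function(d, lengths = default_length_grid(),
                              backend = "builtin_simplified",
                              pombe_3prime30_constraint = FALSE,
                              include_whole = TRUE,
                              profiles = NULL) {
  recs <- d$records
  if (is.null(profiles))
    profiles <- fold_profiles(d, lengths, backend, pombe_3prime30_constraint)
  if (pombe_3prime30_constraint) include_whole <- FALSE
  fams <- .fold_families()
  cols <- unlist(lapply(lengths, function(L) paste0("fold.L", L, ".", fams)))
  if (include_whole) cols <- c(cols, "fold.whole")
  X <- matrix(NA_real_, nrow(recs), length(cols),
              dimnames = list(recs$gene_id, cols))
  for (li in seq_along(lengths)) {
    L <- lengths[li]
    prof <- profiles[[as.character(L)]]
    pooled <- unlist(lapply(prof, `[[`, "delta_g"), use.names = FALSE)
    th <- if (length(pooled)) dataset_thresholds(pooled) else
      setNames(rep(NA_real_, 5), c("q5", "q10", "q20", "q80", "q90"))
    for (g in seq_len(nrow(recs))) {
      w <- prof[[g]]
      vals <- c(location_features(w, recs$utr5_len[g]),
                rank_features(w$delta_g),
                threshold_features(w$delta_g, th))
      X[g, paste0("fold.L", L, ".", names(vals))] <- vals
    }
  }
  if (include_whole)
    X[, "fold.whole"] <- vapply(seq_len(nrow(recs)), function(g)
      whole_feature(recs[g, ], backend), numeric(1))
  X
}

#' Impute missing feature values with column means
#'
#' Dataset-mean imputation keeps genes in multivariate fits; under centering
#' an imputed value has zero effect.  Columns that are entirely missing are
#' imputed with 0.  The missingness mask is attached as attribute `"mask"`.
#'
#' @param X numeric matrix with NAs.
#' @return imputed matrix.
#' @export
impute_features <- function(X) {
  mask <- is.na(X)
  mu <- colMeans(X, na.rm = TRUE)
  mu[!is.finite(mu)] <- 0
  for (j in which(colSums(mask) > 0L)) X[mask[, j], j] <- mu[j]
  attr(X, "mask") <- mask
  X
}
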
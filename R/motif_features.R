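#' Overlapping k-mer frequencies of an RNA string
#'
#' Counts of all overlapping k-mers divided by `max(length - k + 1, 1)`;
#' a sequence shorter than k (including "") gives the all-zero vector.
#'
#' @param seq RNA string.
#' @param k 2 or 3.
#' @return named numeric vector of length 16 (k = 2) or 64 (k = 3).
#' @export
kmer_frequencies <- function(seq, k) {
  stopifnot(k %in% c(2L, 3L))
  b <- c("A", "C", "G", "U")
  kmers <- if (k == 2L) as.vector(t(outer(b, b, paste0)))
           else as.vector(aperm(outer(outer(b, b, paste0), b, paste0)))
  kmers <- sort(kmers)
  n <- nchar(seq)
  if (n < k) return(setNames(rep(0, length(kmers)), kmers))
  obs <- substring(seq, seq_len(n - k + 1L), seq(k, n))
  cnt <- table(factor(obs, levels = kmers))
  setNames(as.numeric(cnt) / (n - k + 1L), kmers)
}

# Vectorized overlapping k-mer frequencies for many strings (Biostrings);
# rows for strings shorter than k are all-zero, matching kmer_frequencies().
.kmer_freq_set <- function(strs, k) {
  n <- nchar(strs)
  cnt <- Biostrings::oligonucleotideFrequency(
    Biostrings::RNAStringSet(strs), width = k)
  denom <- pmax(n - k + 1L, 1L)
  cnt / denom
}

#' Build a position weight matrix anchored at the iAUG
#'
#' Per-position nucleotide frequencies over the genes of a cohort (by
#' convention the high-TR cohort), aligned so position +1 is the A of the
#' iAUG (no position 0).  A gene contributes only to the positions it
#' contains, so short-5'UTR genes still inform the positions they cover.  A
#' pseudocount of 0.5 per nucleotide is added before normalizing so that
#' bases unseen in the cohort score finitely.
#'
#' @param d a [te_dataset].
#' @param gene_ids cohort gene ids.
#' @param from_pos,to_pos iAUG coordinates (from < to, neither 0).
#' @return object of class `te_pwm`: list with `anchor = "iaug"`,
#'   `from_pos`, `to_pos`, `positions`, `freqs` (positions x ACGU matrix,
#'   rows summing to 1).
#' @export
build_pwm <- function(d, gene_ids, from_pos, to_pos) {
  stopifnot(from_pos <= to_pos, from_pos != 0L, to_pos != 0L)
  recs <- d$records[d$records$gene_id %in% gene_ids, , drop = FALSE]
  if (!nrow(recs)) stop("empty cohort")
  positions <- setdiff(seq.int(from_pos, to_pos), 0L)
  freqs <- matrix(NA_real_, length(positions), 4,
                  dimnames = list(as.character(positions),
                                  c("A", "C", "G", "U")))
  for (pi in seq_along(positions)) {
    p <- positions[pi]
    covered <- if (p < 0L) recs$utr5_len >= -p else recs$cds_len >= p
    if (!any(covered))
      stop("PWM position ", p, " covered by no gene in the cohort")
    idx <- iaug_to_index(p, recs$utr5_len[covered])
    base <- substr(recs$seq[covered], idx, idx)
    cnt <- table(factor(base, levels = c("A", "C", "G", "U"))) + 0.5
    freqs[pi, ] <- as.numeric(cnt) / sum(cnt)
  }
  structure(list(anchor = "iaug", from_pos = from_pos, to_pos = to_pos,
                 positions = positions, freqs = freqs),
            class = "te_pwm")
}

#' Build the 5'cap PWM (first five transcript nucleotides)
#'
#' Anchored at the 5' cap, not the iAUG; built from the high-TR cohort.
#'
#' @param d a [te_dataset].
#' @param gene_ids cohort gene ids.
#' @param width PWM width (default 5).
#' @return a `te_pwm` with `anchor = "cap"`.
#' @export
cap_pwm <- function(d, gene_ids, width = 5L) {
  recs <- d$records[d$records$gene_id %in% gene_ids, , drop = FALSE]
  if (!nrow(recs)) stop("empty cohort")
  freqs <- matrix(NA_real_, width, 4,
                  dimnames = list(as.character(seq_len(width)),
                                  c("A", "C", "G", "U")))
  for (p in seq_len(width)) {
    covered <- recs$utr5_len + recs$cds_len >= p
    if (!any(covered)) stop("cap PWM position ", p, " covered by no gene")
    base <- substr(recs$seq[covered], p, p)
    cnt <- table(factor(base, levels = c("A", "C", "G", "U"))) + 0.5
    freqs[p, ] <- as.numeric(cnt) / sum(cnt)
  }
  structure(list(anchor = "cap", from_pos = 1L, to_pos = width,
                 positions = seq_len(width), freqs = freqs),
            class = "te_pwm")
}

#' @export
print.te_pwm <- function(x, ...) {
  cat("te_pwm (", x$anchor, "-anchored) positions ", x$from_pos, "..",
      x$to_pos, "\n", sep = "")
  invisible(x)
}

#' Score a gene against a PWM
#'
#' The score is the sum over PWM positions of log10 of the frequency of the
#' gene's nucleotide; genes that do not completely contain the PWM extent
#' are missing (NA).  Cap-anchored PWMs additionally require
#' `utr5_len >= width` (the motif describes the 5'UTR start).
#'
#' @param rec one record.
#' @param pwm a `te_pwm`.
#' @return numeric log10-likelihood score, or NA.
#' @export
pwm_score <- function(rec, pwm) {
  if (pwm$anchor == "cap") {
    if (rec$utr5_len < pwm$to_pos) return(NA_real_)
    idx <- pwm$positions
  } else {
    if (pwm$from_pos < 0L && rec$utr5_len < -pwm$from_pos) return(NA_real_)
    if (pwm$to_pos > 0L && rec$cds_len < pwm$to_pos) return(NA_real_)
    idx <- iaug_to_index(pwm$positions, rec$utr5_len)
  }
  base <- substring(rec$seq, idx, idx)
  sum(log10(pwm$freqs[cbind(seq_along(idx), match(base, colnames(pwm$freqs)))]))
}

# Vectorized pwm_score over the records of a dataset (or a records
# data.frame); same containment contract as pwm_score().
.pwm_score_vec <- function(d, pwm) {
  recs <- if (inherits(d, "te_dataset")) d$records else d
  n <- nrow(recs)
  if (pwm$anchor == "cap") {
    ok <- recs$utr5_len >= pwm$to_pos
  } else {
    ok <- rep(TRUE, n)
    if (pwm$from_pos < 0L) ok <- ok & recs$utr5_len >= -pwm$from_pos
    if (pwm$to_pos > 0L) ok <- ok & recs$cds_len >= pwm$to_pos
  }
  score <- ifelse(ok, 0, NA_real_)
  lf <- log10(pwm$freqs)
  for (pi in seq_along(pwm$positions)) {
    p <- pwm$positions[pi]
    idx <- if (pwm$anchor == "cap") rep(p, n) else iaug_to_index(p, recs$utr5_len)
    base <- substr(recs$seq, idx, idx)
    score[ok] <- score[ok] + lf[pi, match(base[ok], colnames(pwm$freqs))]
  }
  score
}

#' Scan APE boundary extents for the best PWM
#'
#' For each (5' extent, 3' extent) pair a PWM is built from the high-TR
#' cohort, all genes completely containing it are scored, and log10 TR is
#' regressed on the score (single-part); the extent maximizing R^2 defines
#' the APE bounds.  The default grids instantiate the 5-nucleotide-step
#' scan: 5' in {-5, -10, ..., -100}, 3' in {-1 (5'UTR-only), +8, +13, +18,
#' +23, +28, +33}.
#'
#' @param d a [te_dataset].
#' @param cohorts from [split_cohorts()].
#' @param from_grid candidate 5' extents (negative iAUG coordinates).
#' @param to_grid candidate 3' extents (-1 means no CDS part).
#' @param min_genes minimum scored genes for a grid cell.
#' @return list with `grid` (data.frame from/to/r2/n) and `ape_bounds`
#'   (c(from, to) at the R^2 argmax).
#' @export
scan_ape_boundaries <- function(d, cohorts = split_cohorts(d),
                                from_grid = seq(-5L, -100L, by = -5L),
                                to_grid = c(-1L, 8L, 13L, 18L, 23L, 28L, 33L),
                                min_genes = 10L) {
  y_all <- log10(d$records$tr)
  grid <- expand.grid(from = from_grid, to = to_grid)
  r2 <- n <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    to <- grid$to[i]
    pwm <- build_pwm(d, cohorts$high, grid$from[i],
                     if (to == -1L) -1L else to)
    sc <- .pwm_score_vec(d, pwm)
    ok <- !is.na(sc)
    n[i] <- sum(ok)
    r2[i] <- if (sum(ok) >= min_genes && stats::sd(sc[ok]) > 0)
      fit_multipart(matrix(sc[ok], dimnames = list(NULL, "pwm")),
                    y_all[ok])$r2 else NA_real_
  }
  grid$r2 <- r2; grid$n <- n
  best <- which.max(r2)
  list(grid = grid,
       ape_bounds = c(grid$from[best],
                      if (grid$to[best] == -1L) 4L else grid$to[best]))
}

#' Tri-nucleotide high-TR/low-TR ratio table for a region
#'
#' Per-gene tri-nucleotide frequencies of the region, averaged within the
#' high- and low-TR cohorts (genes with an empty region excluded from that
#' region's means), then the elementwise ratio of the means.  Ratios are
#' undefined (NA) where the low-TR mean is 0.
#'
#' @param d a [te_dataset].
#' @param region region name, see [extract_region()].
#' @param ape_bounds APE bounds, e.g. from [scan_ape_boundaries()].
#' @param cohorts from [split_cohorts()].
#' @return object of class `te_ratio_table`: list with `region`, `ratios`
#'   (named 64-vector), `mean_high`, `mean_low`, `n_high`, `n_low`.
#' @export
trinuc_ratio_table <- function(d, region, ape_bounds = c(-35L, 28L),
                               cohorts = split_cohorts(d)) {
  freq_mat <- function(ids) {
    recs <- d$records[d$records$gene_id %in% ids, , drop = FALSE]
    strs <- .extract_region_vec(recs, region, ape_bounds)
    .kmer_freq_set(strs, 3L)[nchar(strs) >= 3, , drop = FALSE]
  }
  fh <- freq_mat(cohorts$high); fl <- freq_mat(cohorts$low)
  mh <- colMeans(fh); ml <- colMeans(fl)
  ratios <- ifelse(ml > 0, mh / ml, NA_real_)
  structure(list(region = region, ratios = ratios,
                 mean_high = mh, mean_low = ml,
                 n_high = nrow(fh), n_low = nrow(fl)),
            class = "te_ratio_table")
}

#' Pearson correlation between two ratio tables
#'
#' Computed over the tri-nucleotides with defined ratios in both tables.
#'
#' @param tA,tB `te_ratio_table` objects.
#' @return Pearson r.
#' @export
ratio_correlation <- function(tA, tB) {
  ok <- !is.na(tA$ratios) & !is.na(tB$ratios)
  if (sum(ok) < 3) stop("fewer than 3 tri-nucleotides defined in both tables")
  cor(tA$ratios[ok], tB$ratios[ok])
}

.part_upwm_from <- function(scheme, ape_from) {
  # 5' extents of the part-specific uAPE PWMs, closed-upper convention
  switch(scheme,
    one_part = c(part1 = ape_from),
    two_part_arabidopsis = c(part1_short = max(ape_from, -5L),
                             part2_long = ape_from),
    three_part_cerevisiae = c(part1_short = max(ape_from, -5L),
                              part2_mid = max(ape_from, -20L),
                              part3_long = ape_from))
}

#' Build the BIC-selected 5' motif feature sets
#'
#' Candidate pools: uAPE = part-appropriate uAPE PWM score + 16 dinucleotide
#' + 64 trinucleotide frequencies of the uAPE region; dAPE = dAPE PWM
#' (+4..APE 3') + k-mer frequencies of the dAPE; 5'ofAPE = 5-nt cap PWM +
#' k-mer frequencies of the region from cap to just 5' of the APE.  Each
#' pool is reduced by multipart BIC forward selection, and the union of the
#' three selected sets is the "5'motifs" feature set.  In multipart schemes
#' genes in short-UTR parts are scored with shorter uAPE PWMs (e.g. -5..-1),
#' following the part thresholds of [assign_parts()].
#'
#' @param d a [te_dataset].
#' @param ape_bounds APE bounds (5' negative, 3' positive).
#' @param cohorts from [split_cohorts()].
#' @param parts from [assign_parts()] (recomputed if NULL).
#' @return list with one element per region (`uAPE`, `dAPE`,
#'   `five_prime_of_APE`) each holding `candidates`, `fit`, `X` (selected
#'   columns), plus `fiveprime_motifs` = list(`X`, `fit`) for the union.
#' @export
build_motif_sets <- function(d, ape_bounds, cohorts = split_cohorts(d),
                             parts = NULL) {
  recs <- d$records
  y <- log10(recs$tr)
  if (is.null(parts)) parts <- assign_parts(d)
  if (!is.null(names(parts))) parts <- unname(parts[recs$gene_id])
  stopifnot(length(parts) == nrow(recs), !anyNA(parts))
  ape_from <- as.integer(ape_bounds[1]); ape_to <- as.integer(ape_bounds[2])

  region_kmers <- function(region) {
    strs <- .extract_region_vec(recs, region, c(ape_from, ape_to))
    cbind(.kmer_freq_set(strs, 2L), .kmer_freq_set(strs, 3L))
  }

  # --- uAPE: part-specific PWM widths ---
  upwm_from <- .part_upwm_from(d$scheme, ape_from)
  upwms <- lapply(upwm_from, function(f) build_pwm(d, cohorts$high, f, -1L))
  upwm_score <- rep(NA_real_, nrow(recs))
  for (p in names(upwms)) {
    idx <- which(parts == p)
    if (length(idx))
      upwm_score[idx] <- .pwm_score_vec(recs[idx, , drop = FALSE], upwms[[p]])
  }
  Xu <- cbind(uAPE.pwm = upwm_score, region_kmers("uAPE"))
  colnames(Xu) <- c("uAPE.pwm", paste0("uAPE.", colnames(Xu)[-1]))

  # --- dAPE ---
  dpwm <- build_pwm(d, cohorts$high, 4L, max(ape_to, 4L))
  Xd <- cbind(dAPE.pwm = .pwm_score_vec(d, dpwm), region_kmers("dAPE"))
  colnames(Xd) <- c("dAPE.pwm", paste0("dAPE.", colnames(Xd)[-1]))

  # --- 5'ofAPE ---
  cpwm <- cap_pwm(d, cohorts$high, 5L)
  Xc <- cbind(cap.pwm = .pwm_score_vec(d, cpwm),
              region_kmers("five_prime_of_APE"))
  colnames(Xc) <- c("cap.pwm", paste0("c5ape.", colnames(Xc)[-1]))

  select_region <- function(X) {
    fit <- forward_select_bic(impute_features(X), y, parts)
    list(candidates = X, fit = fit,
         X = impute_features(X)[, fit$selected, drop = FALSE])
  }
  uape <- select_region(Xu)
  dape <- select_region(Xd)
  c5 <- select_region(Xc)
  Xm <- cbind(uape$X, dape$X, c5$X)
  motifs_fit <- fit_multipart(Xm, y, parts)
  list(uAPE = uape, dAPE = dape, five_prime_of_APE = c5,
       fiveprime_motifs = list(X = Xm, fit = motifs_fit),
       pwms = list(uAPE = upwms, dAPE = dpwm, cap = cpwm),
       ape_bounds = c(ape_from, ape_to))
}

#' Write a PWM as a TSV table
#' @param pwm a `te_pwm`.
#' @param path output path.
#' @export
write_pwm_tsv <- function(pwm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# anchor=", pwm$anchor, " from_pos=", pwm$from_pos,
                    " to_pos=", pwm$to_pos), con)
  df <- data.frame(position = rownames(pwm$freqs), pwm$freqs,
                   check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
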
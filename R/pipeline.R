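#' Pipeline configuration
#'
#' @param lengths fold window-length grid.
#' @param backend folding backend.
#' @param pombe_3prime30_constraint drop fold windows extending 3' of +30.
#' @param include_whole include the cap..+35 whole-region fold feature.
#' @param ape_bounds fixed APE bounds, or NULL to scan (see
#'   [scan_ape_boundaries()]).
#' @param bootstrap bootstrap resamples for the combined model (0 = none).
#' @param reselect re-run BIC over the union in the combined model.
#' @param seed seed for the bootstrap.
#' @param out_dir optional directory for TSV reports.
#' @return list of class `te_run_config`.
#' @export
run_config <- function(lengths = default_length_grid(),
                       backend = "builtin_simplified",
                       pombe_3prime30_constraint = FALSE,
                       include_whole = TRUE,
                       ape_bounds = NULL,
                       bootstrap = 0, reselect = FALSE, seed = 1,
                       out_dir = NULL) {
  structure(list(lengths = as.integer(lengths), backend = backend,
                 pombe_3prime30_constraint = pombe_3prime30_constraint,
                 include_whole = include_whole, ape_bounds = ape_bounds,
                 bootstrap = bootstrap, reselect = reselect, seed = seed,
                 out_dir = out_dir),
            class = "te_run_config")
}

.overlap_row <- function(name_a, name_b, ov) {
  data.frame(set_a = name_a, set_b = name_b,
             r2_a = ov$r2_a, r2_b = ov$r2_b, r2_ab = ov$r2_ab,
             overlap_pct = ov$overlap_pct, stringsAsFactors = FALSE)
}

# overlap that degrades to NA when the dataset is too small for the joint
# fit (e.g. 61 + 61 codon-half features need > 123 genes per part)
.safe_overlap <- function(XA, XB, y, parts) {
  tryCatch(collinearity_overlap(XA, XB, y, parts),
           error = function(e) {
             warning("overlap skipped: ", conditionMessage(e))
             list(r2_a = NA_real_, r2_b = NA_real_, r2_ab = NA_real_,
                  overlap_pct = NA_real_)
           })
}

#' Run the full analysis pipeline on a dataset
#'
#' Stages: fold features and BIC-selected "RNAfold" set; APE boundary scan
#' (unless bounds fixed) and the BIC-selected "5'motifs" set; uAUG, CDS
#' length and codon features; the combined five-set model with optional
#' bootstrap CI; collinearity overlaps ("5'motifs" vs uAUG / RNAfold /
#' 5'biochem; all pairs of the four biochemical sets; min vs non-overlapping
#' 2nd/3rd most-folded windows; N- vs C-half codons; AA vs syn.codon); and
#' tri-nucleotide high/low-TR ratio tables with cross-region correlations.
#' Deterministic given (dataset, config).
#'
#' @param d a [te_dataset].
#' @param config a [run_config()].
#' @return list of class `te_run` with elements `fold`, `motifs`, `simple`,
#'   `sets` (selected matrices), `fits`, `combined`, `overlaps`
#'   (data.frame), `ratio_tables`, `ratio_cors`, `ape_bounds`,
#'   `min_window_overlaps`.
#' @export
run_pipeline <- function(d, config = run_config()) {
  stopifnot(inherits(d, "te_dataset"), inherits(config, "te_run_config"))
  recs <- d$records
  y <- log10(recs$tr)
  parts <- unname(assign_parts(d)[recs$gene_id])
  cohorts <- split_cohorts(d)

  # --- fold features / RNAfold set ---
  profiles <- fold_profiles(d, config$lengths, config$backend,
                            config$pombe_3prime30_constraint)
  Xfold <- build_fold_matrix(d, config$lengths, config$backend,
                             config$pombe_3prime30_constraint,
                             config$include_whole, profiles = profiles)
  fit_fold <- forward_select_bic(impute_features(Xfold), y, parts)
  X_rnafold <- impute_features(Xfold)[, fit_fold$selected, drop = FALSE]

  # --- motif features ---
  if (is.null(config$ape_bounds)) {
    scan <- scan_ape_boundaries(d, cohorts)
    ape_bounds <- scan$ape_bounds
  } else {
    scan <- NULL
    ape_bounds <- config$ape_bounds
  }
  motifs <- build_motif_sets(d, ape_bounds, cohorts, parts)
  X_motifs <- motifs$fiveprime_motifs$X

  # --- simple features ---
  simple <- build_simple_features(d)
  X_uaug <- simple$uaug
  X_cdslen <- simple$cdslen
  X_codon <- impute_features(simple$codon)

  sets <- list(RNAfold = X_rnafold, fivemotifs = X_motifs, uAUG = X_uaug,
               CDSlen = X_cdslen, codon = X_codon)
  fits <- lapply(sets, function(X) fit_multipart(impute_features(X), y, parts))

  combined <- combined_model(sets, y, parts, reselect = config$reselect,
                             bootstrap = config$bootstrap,
                             seed = config$seed)

  # --- collinearity: 5'motifs vs biochemical sets (Fig 7 style) ---
  X_biochem <- cbind(X_rnafold, X_uaug)
  overlaps <- rbind(
    .overlap_row("fivemotifs", "uAUG",
                 .safe_overlap(X_motifs, X_uaug, y, parts)),
    .overlap_row("fivemotifs", "RNAfold",
                 .safe_overlap(X_motifs, X_rnafold, y, parts)),
    .overlap_row("fivemotifs", "fivebiochem",
                 .safe_overlap(X_motifs, X_biochem, y, parts)))
  # --- pairwise overlaps among the four biochemical processes (Fig 9) ---
  four <- list(RNAfold = X_rnafold, uAUG = X_uaug, CDSlen = X_cdslen,
               codon = X_codon)
  nm <- names(four)
  for (a in seq_along(four)) for (b in seq_along(four)) if (a < b)
    overlaps <- rbind(overlaps, .overlap_row(nm[a], nm[b],
      .safe_overlap(four[[a]], four[[b]], y, parts)))

  # --- min vs 2nd/3rd most-folded non-overlapping windows (Fig 10a,b) ---
  min_ov <- min_window_overlaps(d, profiles, y, parts)

  # --- N vs C codon halves (Fig 10c) ---
  ov_nc <- .safe_overlap(impute_features(simple$ncodon),
                         impute_features(simple$ccodon), y, parts)
  overlaps <- rbind(overlaps, .overlap_row("Ncodon", "Ccodon", ov_nc))

  # --- AA vs syn.codon on genes with all 20 amino acids (Fig 11b) ---
  ok <- simple$has_all_aa
  ov_aa <- if (sum(ok) > 85L)
    .safe_overlap(simple$aa[ok, , drop = FALSE],
                  simple$syn[ok, , drop = FALSE],
                  y[ok], parts[ok]) else
    list(r2_a = NA, r2_b = NA, r2_ab = NA, overlap_pct = NA)
  overlaps <- rbind(overlaps, .overlap_row("AA", "syn.codon", ov_aa))

  # --- tri-nucleotide ratio tables and cross-region correlations ---
  regions <- c("five_prime_of_APE", "uAPE", "dAPE", "CDS_3prime_of_APE")
  ratio_tables <- lapply(regions, function(r)
    trinuc_ratio_table(d, r, ape_bounds, cohorts))
  names(ratio_tables) <- regions
  ratio_cors <- matrix(NA_real_, 4, 4, dimnames = list(regions, regions))
  for (a in 1:4) for (b in 1:4)
    ratio_cors[a, b] <- tryCatch(
      ratio_correlation(ratio_tables[[a]], ratio_tables[[b]]),
      error = function(e) NA_real_)

  run <- structure(list(fold = list(matrix = Xfold, fit = fit_fold),
                        motifs = motifs, scan = scan, simple = simple,
                        sets = sets, fits = fits, combined = combined,
                        overlaps = overlaps, min_window_overlaps = min_ov,
                        ratio_tables = ratio_tables, ratio_cors = ratio_cors,
                        ape_bounds = ape_bounds, cohorts = cohorts),
                   class = "te_run")
  if (!is.null(config$out_dir)) write_run_reports(run, d, config$out_dir)
  run
}

#' Collinearity of the most-folded window with the 2nd/3rd most folded
#'
#' Uses the window length whose rank_min feature best explains log10 TR,
#' selects per gene the greedy non-overlapping most-folded windows, and
#' computes the overlap statistic between the min window energy and the
#' 2nd (and 3rd) window energies on the genes long enough to contain them.
#'
#' @param d a [te_dataset].
#' @param profiles from [fold_profiles()].
#' @param y log10 TR.
#' @param parts part labels.
#' @return list with `L` (chosen length), `pct_genes_2nd`, `pct_genes_3rd`,
#'   `overlap_2nd`, `overlap_3rd`.
#' @export
min_window_overlaps <- function(d, profiles, y, parts = NULL) {
  recs <- d$records
  # choose L by univariate R2 of rank_min
  best <- list(L = NA_integer_, r2 = -Inf)
  for (L in names(profiles)) {
    v <- vapply(profiles[[L]], function(w)
      if (length(w$delta_g)) min(w$delta_g) else NA_real_, numeric(1))
    ok <- !is.na(v)
    if (sum(ok) < 20) next
    r2 <- if (sd(v[ok]) > 0) cor(v[ok], y[ok])^2 else 0
    if (r2 > best$r2) best <- list(L = as.integer(L), r2 = r2)
  }
  if (is.na(best$L))
    return(list(L = NA_integer_, pct_genes_2nd = 0, pct_genes_3rd = 0,
                overlap_2nd = NA_real_, overlap_3rd = NA_real_))
  prof <- profiles[[as.character(best$L)]]
  e1 <- e2 <- e3 <- rep(NA_real_, nrow(recs))
  for (g in seq_len(nrow(recs))) {
    w <- prof[[g]]
    if (!length(w$delta_g)) next
    sel <- nonoverlap_min_windows(
      data.frame(start = w$start, length = best$L, delta_g = w$delta_g),
      3L, recs$utr5_len[g])
    if (nrow(sel) >= 1) e1[g] <- sel$delta_g[1]
    if (nrow(sel) >= 2) e2[g] <- sel$delta_g[2]
    if (nrow(sel) >= 3) e3[g] <- sel$delta_g[3]
  }
  ov <- function(eb) {
    ok <- !is.na(e1) & !is.na(eb)
    if (sum(ok) < 30) return(NA_real_)
    p <- if (is.null(parts)) NULL else parts[ok]
    collinearity_overlap(matrix(e1[ok], dimnames = list(NULL, "min")),
                         matrix(eb[ok], dimnames = list(NULL, "alt")),
                         y[ok], p)$overlap_pct
  }
  list(L = best$L,
       pct_genes_2nd = 100 * mean(!is.na(e2)),
       pct_genes_3rd = 100 * mean(!is.na(e3)),
       overlap_2nd = ov(e2), overlap_3rd = ov(e3))
}

#' Write pipeline reports as TSV files
#'
#' @param run a `te_run`.
#' @param d the dataset.
#' @param out_dir output directory (created if needed).
#' @export
write_run_reports <- function(run, d, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) write.table(x, file.path(out_dir, f), sep = "\t",
                                  quote = FALSE, row.names = FALSE)
  summ <- data.frame(
    model = c(names(run$fits), "combined"),
    r2 = c(vapply(run$fits, `[[`, numeric(1), "r2"), run$combined$r2),
    n_features = c(vapply(run$fits, function(f) length(f$selected),
                          integer(1)), length(run$combined$selected)))
  if (!is.null(run$combined$ci)) {
    summ$ci_lo <- c(rep(NA, length(run$fits)), run$combined$ci$lo)
    summ$ci_hi <- c(rep(NA, length(run$fits)), run$combined$ci$hi)
  }
  w(summ, "model_summary.tsv")
  w(run$overlaps, "overlaps.tsv")
  ratios <- do.call(rbind, lapply(names(run$ratio_tables), function(r)
    data.frame(region = r,
               trinucleotide = names(run$ratio_tables[[r]]$ratios),
               ratio = unname(run$ratio_tables[[r]]$ratios))))
  w(ratios, "trinuc_ratios.tsv")
  sel <- do.call(rbind, lapply(names(run$fits), function(s)
    if (length(run$fits[[s]]$selected))
      data.frame(set = s, feature = run$fits[[s]]$selected) else NULL))
  w(sel, "selected_features.tsv")
  invisible(out_dir)
}
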
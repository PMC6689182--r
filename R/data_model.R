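#' iAUG-anchored coordinates
#'
#' Positions are anchored at the initiating AUG: the A of the iAUG is +1, the
#' nucleotide immediately 5' of it is -1, and there is no position 0.  The 5'
#' cap is position `-utr5_len`.
#'
#' @param pos integer vector of iAUG coordinates (no zeros).
#' @param utr5_len 5'UTR length in nucleotides.
#' @return `iaug_to_index()` returns 1-based string indices;
#'   `index_to_iaug()` returns iAUG coordinates.
#' @examples
#' iaug_to_index(c(-2, -1, 1, 2), utr5_len = 10)  # 9 10 11 12
#' @export
iaug_to_index <- function(pos, utr5_len) {
  if (any(pos == 0)) stop("iAUG coordinates have no position 0")
  ifelse(pos < 0, utr5_len + pos + 1L, utr5_len + pos)
}

#' @rdname iaug_to_index
#' @param idx 1-based string index into the transcript sequence.
#' @export
index_to_iaug <- function(idx, utr5_len) {
  ifelse(idx <= utr5_len, idx - utr5_len - 1L, idx - utr5_len)
}

normalize_rna <- function(seq) {
  chartr("tT", "uU", toupper(chartr("T", "U", seq)))
}

#' Construct a validated mRNA record table
#'
#' A dataset holds one row per gene: the transcript sequence (RNA alphabet;
#' `T` on input is mapped to `U`), the 5'UTR and CDS lengths, the translation
#' rate (TE/IE from ribosome profiling, arbitrary positive units) and mRNA
#' abundance (RPKM).  Records violating the invariants (iAUG present at the
#' annotated CDS start, CDS a positive multiple of 3, lengths within the
#' sequence) are dropped with a message.
#'
#' @param df data.frame with columns `gene_id`, `seq`, `utr5_len`, `cds_len`,
#'   `tr`, `rpkm`.
#' @param scheme regression-part scheme: `"one_part"`,
#'   `"two_part_arabidopsis"` (5'UTR split at 65 nt) or
#'   `"three_part_cerevisiae"` (splits at 20 and 35 nt).
#' @param name dataset label.
#' @param quiet suppress drop messages.
#' @return an object of class `te_dataset`: a list with elements `records`
#'   (data.frame), `scheme`, `name`, `dropped` (data.frame of gene_id/reason).
#' @export
te_dataset <- function(df, scheme = c("one_part", "two_part_arabidopsis",
                                      "three_part_cerevisiae"),
                       name = "dataset", quiet = FALSE) {
  scheme <- match.arg(scheme)
  need <- c("gene_id", "seq", "utr5_len", "cds_len", "tr", "rpkm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df <- df[, need]
  df$gene_id  <- as.character(df$gene_id)
  df$seq      <- toupper(normalize_rna(as.character(df$seq)))
  df$utr5_len <- as.integer(df$utr5_len)
  df$cds_len  <- as.integer(df$cds_len)
  df$tr       <- as.numeric(df$tr)
  df$rpkm     <- as.numeric(df$rpkm)
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_ids")

  reason <- rep(NA_character_, nrow(df))
  bad_alpha <- grepl("[^ACGU]", df$seq)
  reason[bad_alpha] <- "non-ACGU characters"
  too_short <- is.na(reason) & (df$utr5_len + df$cds_len > nchar(df$seq))
  reason[too_short] <- "utr5_len + cds_len exceeds sequence length"
  bad_len <- is.na(reason) &
    (df$utr5_len < 0L | df$cds_len <= 0L | df$cds_len %% 3L != 0L)
  reason[bad_len] <- "invalid utr5_len/cds_len"
  ok <- is.na(reason)
  iaug <- substr(df$seq, df$utr5_len + 1L, df$utr5_len + 3L)
  no_iaug <- ok & iaug != "AUG"
  reason[no_iaug] <- "sequence at CDS start is not AUG"
  bad_tr <- is.na(reason) & (!is.finite(df$tr) | df$tr <= 0)
  reason[bad_tr] <- "non-positive translation rate"

  dropped <- data.frame(gene_id = df$gene_id[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  if (nrow(dropped) && !quiet)
    message("dropped ", nrow(dropped), " record(s): ",
            paste(dropped$gene_id, dropped$reason, sep = ": ", collapse = "; "))
  records <- df[is.na(reason), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records, scheme = scheme, name = name,
                 dropped = dropped),
            class = "te_dataset")
}

#' @export
print.te_dataset <- function(x, ...) {
  cat("te_dataset '", x$name, "': ", nrow(x$records), " genes, scheme ",
      x$scheme, "\n", sep = "")
  invisible(x)
}

n_genes <- function(d) nrow(d$records)

#' Load a dataset from FASTA + annotation table, or a combined table
#'
#' The annotation table is tab-separated with a header and columns
#' `gene_id`, `utr5_len`, `cds_len`, `tr`, `rpkm`; sequences come from a
#' FASTA whose ids are the gene_ids.  Alternatively a single combined
#' tab-separated table with columns `gene_id`, `utr5_seq`, `cds_seq`, `tr`,
#' `rpkm` is accepted (`annotation = NULL`).
#'
#' @param seq_source path to a FASTA file, or to the combined table.
#' @param annotation path to the annotation TSV, or NULL for combined input.
#' @inheritParams te_dataset
#' @return a [te_dataset].
#' @export
load_dataset <- function(seq_source, annotation = NULL,
                         scheme = "one_part", name = NULL, quiet = FALSE) {
  if (!file.exists(seq_source)) stop("no such file: ", seq_source)
  if (is.null(name)) name <- basename(seq_source)
  if (is.null(annotation)) {
    tab <- read.delim(seq_source, stringsAsFactors = FALSE)
    need <- c("gene_id", "utr5_seq", "cds_seq", "tr", "rpkm")
    miss <- setdiff(need, names(tab))
    if (length(miss)) stop("combined table lacks columns: ",
                           paste(miss, collapse = ", "))
    utr <- normalize_rna(ifelse(is.na(tab$utr5_seq), "", tab$utr5_seq))
    cds <- normalize_rna(tab$cds_seq)
    df <- data.frame(gene_id = tab$gene_id,
                     seq = paste0(utr, cds),
                     utr5_len = nchar(utr), cds_len = nchar(cds),
                     tr = tab$tr, rpkm = tab$rpkm,
                     stringsAsFactors = FALSE)
  } else {
    if (!file.exists(annotation)) stop("no such file: ", annotation)
    seqs <- Biostrings::readBStringSet(seq_source)
    ids <- sub("\\s.*$", "", names(seqs))
    ann <- read.delim(annotation, stringsAsFactors = FALSE)
    missing_genes <- setdiff(ann$gene_id, ids)
    if (length(missing_genes))
      stop("annotated genes absent from FASTA: ",
           paste(missing_genes, collapse = ", "))
    df <- data.frame(gene_id = ann$gene_id,
                     seq = as.character(seqs)[match(ann$gene_id, ids)],
                     utr5_len = ann$utr5_len, cds_len = ann$cds_len,
                     tr = ann$tr, rpkm = ann$rpkm,
                     stringsAsFactors = FALSE)
  }
  d <- te_dataset(df, scheme = scheme, name = name, quiet = quiet)
  if (n_genes(d) == 0L) stop("no records survived validation")
  d
}

#' Filter a dataset: replica averaging, abundance threshold, allow-list
#'
#' Replica tables (data.frames with `gene_id`, `tr`, `rpkm`) are intersected
#' on gene_id -- genes without data in all replicas are removed -- and TR and
#' abundance are replaced by per-gene means across replicas.  Genes with mRNA
#' abundance below `min_abundance` (default 1 RPKM) are excluded, then the
#' optional allow-list (e.g. single-isoform genes) is intersected.
#'
#' @param d a [te_dataset].
#' @param min_abundance RPKM threshold (default 1).
#' @param allow_list optional character vector of gene_ids to keep.
#' @param replica_tables optional list of data.frames with
#'   `gene_id`, `tr`, `rpkm`.
#' @return filtered [te_dataset].
#' @export
filter_dataset <- function(d, min_abundance = 1.0, allow_list = NULL,
                           replica_tables = NULL) {
  stopifnot(inherits(d, "te_dataset"))
  r <- d$records
  if (!is.null(replica_tables)) {
    common <- r$gene_id
    for (tab in replica_tables) common <- intersect(common, tab$gene_id)
    r <- r[r$gene_id %in% common, , drop = FALSE]
    if (nrow(r)) {
      trs  <- sapply(replica_tables, function(t) t$tr[match(r$gene_id, t$gene_id)])
      rpk  <- sapply(replica_tables, function(t) t$rpkm[match(r$gene_id, t$gene_id)])
      trs  <- matrix(trs, nrow = nrow(r))
      rpk  <- matrix(rpk, nrow = nrow(r))
      r$tr   <- rowMeans(trs)
      r$rpkm <- rowMeans(rpk)
    }
  }
  r <- r[r$rpkm >= min_abundance, , drop = FALSE]
  if (!is.null(allow_list)) r <- r[r$gene_id %in% allow_list, , drop = FALSE]
  if (nrow(r) == 0L) stop("filter_dataset: no genes remain")
  rownames(r) <- NULL
  d$records <- r
  d
}

#' Split a dataset into high-TR and low-TR cohorts
#'
#' The top and bottom `fraction` of genes ranked by TR (default deciles).
#' Ties are broken by gene_id lexicographic order so the split is
#' deterministic and invariant to input order.
#'
#' @param d a [te_dataset].
#' @param fraction cohort fraction in (0, 0.5].
#' @return list with character vectors `high` and `low` of gene_ids.
#' @export
split_cohorts <- function(d, fraction = 0.10) {
  stopifnot(inherits(d, "te_dataset"))
  if (!(fraction > 0 && fraction <= 0.5)) stop("fraction must be in (0, 0.5]")
  r <- d$records
  k <- floor(fraction * nrow(r))
  if (k < 1L) stop("dataset too small for cohort fraction ", fraction)
  ord <- order(r$tr, r$gene_id)  # ascending TR, id tie-break
  low  <- sort(r$gene_id[ord[seq_len(k)]])
  ordh <- order(-r$tr, r$gene_id)
  high <- sort(r$gene_id[ordh[seq_len(k)]])
  list(high = high, low = low)
}

#' Extract a named mRNA region
#'
#' Regions are defined relative to the AUG-proximal element (APE) bounds,
#' given as iAUG coordinates `(5', 3')` with the 5' bound negative and the 3'
#' bound positive: `five_prime_of_APE` (cap to just 5' of the APE), `uAPE`
#' (APE part 5' of the iAUG), `dAPE` (+4 to the APE 3' bound), and
#' `CDS_3prime_of_APE`.  `UTR5` and `five_prime_region` (5'UTR plus CDS up to
#' the APE 3' bound) ignore the 5' APE bound.  Regions truncated by a short
#' 5'UTR are clipped at the cap (possibly to the empty string).
#'
#' @param rec one row of `d$records` (data.frame or list).
#' @param region region name.
#' @param ape_bounds integer pair, e.g. `c(-35, 28)`.
#' @return RNA string (possibly "").
#' @export
extract_region <- function(rec, region = c("five_prime_of_APE", "uAPE", "dAPE",
                                           "CDS_3prime_of_APE", "UTR5",
                                           "five_prime_region"),
                           ape_bounds = c(-35L, 28L)) {
  region <- match.arg(region)
  u <- rec$utr5_len; n <- rec$utr5_len + rec$cds_len
  a5 <- as.integer(ape_bounds[1]); a3 <- as.integer(ape_bounds[2])
  stopifnot(a5 < 0, a3 >= 4)  # dAPE starts at +4, 3' of the iAUG codon
  sub <- function(i, j) if (j < i) "" else substr(rec$seq, max(1L, i), min(n, j))
  switch(region,
    five_prime_of_APE = if (u + a5 < 0) "" else sub(1L, u + a5),
    uAPE  = if (u == 0L) "" else sub(max(1L, u + a5 + 1L), u),
    dAPE  = sub(u + 4L, u + a3),
    CDS_3prime_of_APE = sub(u + a3 + 1L, u + rec$cds_len),
    UTR5  = sub(1L, u),
    five_prime_region = sub(1L, u + a3))
}

# Vectorized extract_region over a records data.frame.
.extract_region_vec <- function(recs, region, ape_bounds) {
  u <- recs$utr5_len; n <- u + recs$cds_len
  a5 <- as.integer(ape_bounds[1]); a3 <- as.integer(ape_bounds[2])
  stopifnot(a5 < 0, a3 >= 4)
  bounds <- switch(region,
    five_prime_of_APE = cbind(1L, u + a5),
    uAPE  = cbind(pmax(1L, u + a5 + 1L), ifelse(u == 0L, 0L, u)),
    dAPE  = cbind(u + 4L, u + a3),
    CDS_3prime_of_APE = cbind(u + a3 + 1L, u + recs$cds_len),
    UTR5  = cbind(1L, u),
    five_prime_region = cbind(1L, u + a3))
  i <- pmax(1L, bounds[, 1]); j <- pmin(n, bounds[, 2])
  out <- substr(recs$seq, i, j)
  out[j < i] <- ""
  out
}

#' Assign genes to regression parts by 5'UTR length
#'
#' One-part schemes put every gene in `"part1"`.  The two-part scheme splits
#' at 65 nt (Arabidopsis convention) and the three-part scheme at 20 and 35
#' nt (S. cerevisiae convention); boundaries are closed on the upper group.
#'
#' @param d a [te_dataset].
#' @return named character vector gene_id -> part label.
#' @export
assign_parts <- function(d) {
  stopifnot(inherits(d, "te_dataset"))
  u <- d$records$utr5_len
  lab <- switch(d$scheme,
    one_part = rep("part1", length(u)),
    two_part_arabidopsis = ifelse(u >= 65L, "part2_long", "part1_short"),
    three_part_cerevisiae = ifelse(u >= 35L, "part3_long",
                            ifelse(u >= 20L, "part2_mid", "part1_short")))
  setNames(lab, d$records$gene_id)
}

#' Write a dataset (with optional feature columns) as TSV
#'
#' @param d a [te_dataset].
#' @param path output path.
#' @param features optional feature matrix (rows aligned with records).
#' @export
write_dataset_tsv <- function(d, path, features = NULL) {
  out <- d$records
  if (!is.null(features)) {
    stopifnot(nrow(features) == nrow(out))
    out <- cbind(out, as.data.frame(features))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
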
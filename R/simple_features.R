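#' The standard genetic code over the RNA alphabet
#'
#' @return named character vector codon -> one-letter amino acid, `*` for the
#'   three stop codons.
#' @export
genetic_code <- function() {
  bases <- c("U", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  # codons vary 3rd base fastest in standard tables; rebuild in table order
  codons <- unlist(lapply(bases, function(b1)
    lapply(bases, function(b2) paste0(b1, b2, bases))))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",   # UUU..UGG
    "LLLLPPPPHHQQRRRR",   # CUU..CGG
    "IIIMTTTTNNKKSSRR",   # AUU..AGG
    "VVVVAAAADDEEGGGG"), "")[[1]]
  setNames(aa, codons)
}

#' Sense codons and amino acids
#' @return character vector of the 61 non-stop codons (alphabetical).
#' @export
sense_codons <- function() {
  gc <- genetic_code()
  sort(names(gc)[gc != "*"])
}

#' Count upstream AUGs
#'
#' The number of (possibly overlapping) AUG trinucleotides strictly within
#' the 5'UTR; an AUG straddling the -1/+1 boundary is not counted.
#'
#' @param rec one record.
#' @return non-negative integer.
#' @export
count_uaugs <- function(rec) {
  if (rec$utr5_len < 3L) return(0L)
  utr <- substr(rec$seq, 1L, rec$utr5_len)
  m <- gregexpr("(?=AUG)", utr, perl = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

#' CDS length feature
#'
#' log10 of the number of CDS amino acids, i.e. cds_len/3 codons minus the
#' stop (the initiator Met is counted; the stop codon is not an amino acid).
#'
#' @param rec one record (`cds_len >= 6`).
#' @return numeric.
#' @export
cds_length_feature <- function(rec) {
  stopifnot(rec$cds_len >= 6L, rec$cds_len %% 3L == 0L)
  log10(rec$cds_len / 3 - 1)
}

#' Codon, amino-acid and synonymous-preference profile of one CDS
#'
#' Codon counts exclude the stop codon.  `codon_freq` are the 61 sense-codon
#' frequencies; `aa_freq` the 20 amino-acid frequencies; `syn_pref` each
#' codon's count divided by the summed counts of its synonymous family (NA
#' for families of amino acids absent from the gene); `n_half_freq` and
#' `c_half_freq` are codon frequencies in the N- and C-terminal halves of the
#' protein (odd counts: the N-half gets the smaller half).  The identity
#' codon_freq = aa_freq[aa(codon)] * syn_pref[codon] holds for genes that
#' contain all 20 amino acids.
#'
#' @param rec one record; an internal stop codon flags the gene
#'   (`internal_stop = TRUE`) and all profile entries are NA.
#' @return list with `codon_freq`, `aa_freq`, `syn_pref`, `n_half_freq`,
#'   `c_half_freq`, `has_all_aa`, `internal_stop`.
#' @export
codon_profile <- function(rec) {
  stopifnot(rec$cds_len %% 3L == 0L)
  gc <- genetic_code()
  sense <- sense_codons()
  aas <- sort(unique(gc[gc != "*"]))
  cds <- substr(rec$seq, rec$utr5_len + 1L, rec$utr5_len + rec$cds_len)
  cod <- substring(cds, seq(1L, nchar(cds) - 2L, 3L),
                   seq(3L, nchar(cds), 3L))
  n <- length(cod)
  has_stop_end <- gc[cod[n]] == "*"
  body <- if (has_stop_end) cod[-n] else cod
  na61 <- setNames(rep(NA_real_, 61L), sense)
  na20 <- setNames(rep(NA_real_, 20L), aas)
  if (any(gc[body] == "*"))
    return(list(codon_freq = na61, aa_freq = na20, syn_pref = na61,
                n_half_freq = na61, c_half_freq = na61,
                has_all_aa = FALSE, internal_stop = TRUE))
  cnt <- table(factor(body, levels = sense))
  codon_freq <- as.numeric(cnt) / length(body)
  names(codon_freq) <- sense
  aa_of <- gc[sense]
  aa_cnt <- as.numeric(tapply(as.numeric(cnt), aa_of, sum)[aas])
  aa_freq <- setNames(aa_cnt / length(body), aas)
  fam_tot <- aa_cnt[match(aa_of, aas)]
  syn_pref <- setNames(
    ifelse(fam_tot > 0, as.numeric(cnt) / fam_tot, NA_real_), sense)
  nh <- floor(length(body) / 2)
  half <- function(x) {
    if (!length(x)) return(rep(0, 61L))
    as.numeric(table(factor(x, levels = sense))) / length(x)
  }
  n_half <- setNames(half(body[seq_len(nh)]), sense)
  c_half <- setNames(half(body[seq(nh + 1L, length(body))]), sense)
  list(codon_freq = codon_freq, aa_freq = aa_freq, syn_pref = syn_pref,
       n_half_freq = n_half, c_half_freq = c_half,
       has_all_aa = all(aa_cnt > 0), internal_stop = FALSE)
}

#' Simple per-gene feature matrices: uAUG, CDS length, codon families
#'
#' Column naming: `uAUG`, `CDSlen`, `codon.XXX` (61), `AA.X` (20),
#' `syn.XXX` (61), `Ncodon.XXX` / `Ccodon.XXX` (61 each).  Genes with an
#' internal stop codon have NA across the codon families; `syn.*` is NA for
#' genes lacking any amino acid's family.
#'
#' @param d a [te_dataset].
#' @return list of matrices `uaug`, `cdslen`, `codon`, `aa`, `syn`,
#'   `ncodon`, `ccodon`, plus `has_all_aa` (logical vector) and
#'   `pct_all_aa` (percent of genes usable for syn.codon analyses).
#' @export
build_simple_features <- function(d) {
  recs <- d$records
  ng <- nrow(recs)
  sense <- sense_codons()
  aas <- sort(unique(genetic_code()[genetic_code() != "*"]))
  uaug <- matrix(NA_real_, ng, 1, dimnames = list(recs$gene_id, "uAUG"))
  cdsl <- matrix(NA_real_, ng, 1, dimnames = list(recs$gene_id, "CDSlen"))
  codon <- matrix(NA_real_, ng, 61,
                  dimnames = list(recs$gene_id, paste0("codon.", sense)))
  aa <- matrix(NA_real_, ng, 20,
               dimnames = list(recs$gene_id, paste0("AA.", aas)))
  syn <- matrix(NA_real_, ng, 61,
                dimnames = list(recs$gene_id, paste0("syn.", sense)))
  ncod <- matrix(NA_real_, ng, 61,
                 dimnames = list(recs$gene_id, paste0("Ncodon.", sense)))
  ccod <- matrix(NA_real_, ng, 61,
                 dimnames = list(recs$gene_id, paste0("Ccodon.", sense)))
  # vectorized codon tallies: count codons in frame (step 3) over the CDS
  # body (stop codon excluded), via Biostrings
  gcode <- genetic_code()
  utr <- recs$utr5_len
  cds <- substr(recs$seq, utr + 1L, utr + recs$cds_len)
  n_cod <- recs$cds_len %/% 3L
  last <- substr(cds, nchar(cds) - 2L, nchar(cds))
  body_len <- ifelse(gcode[last] == "*", n_cod - 1L, n_cod)
  body <- substr(cds, 1L, 3L * body_len)
  codon_counts <- function(strs) {
    cnt <- Biostrings::oligonucleotideFrequency(
      Biostrings::RNAStringSet(strs), width = 3L, step = 3L)
    cnt[, sense, drop = FALSE]
  }
  cnt_all <- Biostrings::oligonucleotideFrequency(
    Biostrings::RNAStringSet(body), width = 3L, step = 3L)
  internal_stop <- rowSums(cnt_all[, names(gcode)[gcode == "*"],
                                   drop = FALSE]) > 0L
  cnt <- cnt_all[, sense, drop = FALSE]
  codon[] <- cnt / body_len
  aa_ind <- outer(gcode[sense], aas, "==") * 1  # 61 x 20 indicator
  aa_cnt <- cnt %*% aa_ind
  colnames(aa_cnt) <- aas
  aa[] <- aa_cnt / body_len
  fam_tot <- aa_cnt[, gcode[sense], drop = FALSE]  # per-gene family totals
  syn[] <- ifelse(fam_tot > 0, cnt / fam_tot, NA_real_)
  nh <- body_len %/% 2L
  cnt_n <- codon_counts(substr(body, 1L, 3L * nh))
  cnt_c <- codon_counts(substr(body, 3L * nh + 1L, nchar(body)))
  ncod[] <- cnt_n / pmax(nh, 1L)   # nh = 0 rows are all-zero counts
  ccod[] <- cnt_c / (body_len - nh)
  has_all <- rowSums(aa_cnt > 0L) == 20L & !internal_stop
  codon[internal_stop, ] <- NA_real_
  aa[internal_stop, ] <- NA_real_
  syn[internal_stop, ] <- NA_real_
  ncod[internal_stop, ] <- NA_real_
  ccod[internal_stop, ] <- NA_real_
  utr_str <- substr(recs$seq, 1L, utr)
  uaug[, 1] <- vapply(gregexpr("(?=AUG)", utr_str, perl = TRUE),
                      function(m) if (m[1] == -1L) 0L else length(m),
                      integer(1))
  cdsl[, 1] <- log10(recs$cds_len / 3 - 1)
  list(uaug = uaug, cdslen = cdsl, codon = codon, aa = aa, syn = syn,
       ncodon = ncod, ccodon = ccod, has_all_aa = has_all,
       pct_all_aa = 100 * mean(has_all))
}
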
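#' Energy parameters of the built-in RNA model
#'
#' Nearest-neighbor Watson-Crick stack free energies (dG37, kcal/mol) with
#' duplex initiation, terminal-AU and self-complementarity terms, plus the
#' loop constants used by the simplified built-in folder.  The stack table is
#' indexed by the outer and inner base pair of a stack, pair types
#' `AU, UA, GC, CG, GU, UG`; stacks involving a wobble pair share one flat
#' constant.  All values are package constants, not fitted quantities.
#'
#' @return a list with elements `stack` (6x6 matrix), `init`, `terminal_au`,
#'   `symmetry`, `hairpin_a/b`, `bulge_a/b`, `interior_a/b`, `ml_close`,
#'   `ml_branch`, `ml_unpaired`, `max_loop`.
#' @export
rna_energy_params <- function() {
  pt <- c("AU", "UA", "GC", "CG", "GU", "UG")
  st <- matrix(NA_real_, 6, 6, dimnames = list(pt, pt))
  # Watson-Crick nearest-neighbor dG37 (kcal/mol)
  st["AU", "AU"] <- -0.93; st["AU", "UA"] <- -1.10
  st["AU", "GC"] <- -2.08; st["AU", "CG"] <- -2.24
  st["UA", "AU"] <- -1.33; st["UA", "UA"] <- -0.93
  st["UA", "GC"] <- -2.11; st["UA", "CG"] <- -2.35
  st["GC", "AU"] <- -2.35; st["GC", "UA"] <- -2.24
  st["GC", "GC"] <- -3.26; st["GC", "CG"] <- -3.42
  st["CG", "AU"] <- -2.11; st["CG", "UA"] <- -2.08
  st["CG", "GC"] <- -2.36; st["CG", "CG"] <- -3.26
  st[is.na(st)] <- -1.20   # any stack involving a G.U wobble pair
  list(stack = st,
       init = 4.09, terminal_au = 0.45, symmetry = 0.43,
       hairpin_a = 5.0, hairpin_b = 0.3,
       bulge_a = 3.6, bulge_b = 0.3,
       interior_a = 4.0, interior_b = 0.3,
       ml_close = 3.4, ml_branch = 0.4, ml_unpaired = 0.1,
       max_loop = 10L)
}

.pair_name <- function(a, b) {
  p <- paste0(a, b)
  if (p %in% c("AU", "UA", "GC", "CG", "GU", "UG")) p else NA_character_
}

.wc_partner <- c(A = "U", U = "A", G = "C", C = "G")

#' Nearest-neighbor free energy of a fully complementary RNA duplex
#'
#' Implements the standard nearest-neighbor model for a Watson-Crick duplex:
#' dG37 = initiation + sum of stack terms + 0.45 kcal/mol per terminal A-U
#' pair + 0.43 kcal/mol if the duplex is self-complementary.
#'
#' @param strand5to3 top strand, 5'->3'.
#' @param strand3to5 bottom strand, written 3'->5' so position i pairs with
#'   position i of the top strand.
#' @return dG37 in kcal/mol.
#' @examples
#' duplex_energy("GC", "CG")  # init + one GC/GC stack
#' @export
duplex_energy <- function(strand5to3, strand3to5) {
  a <- strsplit(normalize_rna(strand5to3), "")[[1]]
  b <- strsplit(normalize_rna(strand3to5), "")[[1]]
  if (length(a) != length(b)) stop("strands must have equal length")
  n <- length(a)
  if (n < 2) stop("duplex must be at least 2 bp")
  bad <- which(.wc_partner[a] != b)
  if (length(bad))
    stop("non-Watson-Crick pair at position ", bad[1], ": ",
         a[bad[1]], "-", b[bad[1]])
  p <- rna_energy_params()
  pairs <- paste0(a, b)
  e <- p$init
  for (i in seq_len(n - 1)) e <- e + p$stack[pairs[i], pairs[i + 1]]
  if (pairs[1] %in% c("AU", "UA")) e <- e + p$terminal_au
  if (pairs[n] %in% c("AU", "UA")) e <- e + p$terminal_au
  # self-complementary: top strand read 5'->3' equals bottom strand 3'->5'
  # reversed, i.e. the two strands have identical sequence
  if (identical(a, rev(b))) e <- e + p$symmetry
  e
}

.check_backend <- function(backend) {
  if (is.function(backend)) return(backend)
  backend <- match.arg(backend, c("builtin_simplified", "external_mfe"))
  if (backend == "external_mfe")
    stop("external MFE backend (e.g. ViennaRNA RNAfold) is not available in ",
         "this installation; pass a function(seq) -> list(delta_g, structure) ",
         "as `backend`, or use 'builtin_simplified'")
  backend
}

#' Fold one RNA sequence to its minimum-free-energy structure
#'
#' The built-in backend is a Zuker-style dynamic program over the embedded
#' stack table with affine loop penalties (see [rna_energy_params()]); it is
#' deterministic and intended for tests and synthetic data.  A user function
#' `function(seq) list(delta_g=, structure=)` may be supplied as an external
#' backend.
#'
#' @param seq RNA string (T accepted, mapped to U).
#' @param backend `"builtin_simplified"`, `"external_mfe"`, or a function.
#' @return list with `delta_g` (kcal/mol, <= 0) and `structure`
#'   (dot-bracket).
#' @examples
#' fold_window("GGGGAAAACCCC")
#' @export
fold_window <- function(seq, backend = "builtin_simplified") {
  seq <- normalize_rna(seq)
  bk <- .check_backend(backend)
  if (is.function(bk)) {
    out <- bk(seq)
    stopifnot(is.list(out), !is.null(out$delta_g), !is.null(out$structure))
    return(out[c("delta_g", "structure")])
  }
  .fold_one_cpp(seq, rna_energy_params())
}

#' Enumerate and fold the tiling windows of one gene's 5' region
#'
#' Length-`L` windows start at every 5'UTR position, from the 5' cap
#' (position `-utr5_len`) to -1, at one-nucleotide offsets; the last window
#' extends into the CDS to position `+(L-1)`.  Windows that would run past
#' the transcript 3' end are dropped (flagged in the `dropped` attribute).
#'
#' @param rec one record (row of `d$records`).
#' @param L window length (>= 2).
#' @param backend folding backend, see [fold_window()].
#' @param structures compute dot-bracket strings (slower); energies always.
#' @return data.frame with columns `gene_id`, `start` (iAUG coordinate of the
#'   5'-most nucleotide), `length`, `delta_g`, `structure`; zero rows when
#'   `utr5_len` is 0.
#' @export
enumerate_windows <- function(rec, L, backend = "builtin_simplified",
                              structures = TRUE) {
  stopifnot(L >= 2)
  u <- rec$utr5_len
  empty <- data.frame(gene_id = character(), start = integer(),
                      length = integer(), delta_g = numeric(),
                      structure = character(), stringsAsFactors = FALSE)
  if (u == 0L) return(empty)
  n <- u + rec$cds_len
  region_len <- min(n, u + L - 1L)
  region <- substr(rec$seq, 1L, region_len)
  bk <- .check_backend(backend)
  if (is.function(bk)) {
    dg <- rep(NA_real_, u); db <- rep(NA_character_, u)
    for (s in seq_len(u)) {
      if (s + L - 1L > region_len) next
      out <- bk(substr(region, s, s + L - 1L))
      dg[s] <- out$delta_g; db[s] <- out$structure
    }
  } else {
    out <- .fold_windows_cpp(region, as.integer(L), u, rna_energy_params(),
                             structures)
    dg <- out$delta_g; db <- as.character(out$structure)
  }
  keep <- !is.na(dg)
  res <- data.frame(gene_id = rec$gene_id,
                    start = index_to_iaug(which(keep), u),
                    length = as.integer(L),
                    delta_g = dg[keep],
                    structure = if (structures) db[keep] else NA_character_,
                    stringsAsFactors = FALSE)
  attr(res, "dropped") <- sum(!keep)
  res
}

#' Parse a dot-bracket structure into base pairs
#'
#' @param structure dot-bracket string (no pseudoknots).
#' @return two-column integer matrix of paired positions (i < j), 1-based.
#' @export
dotbracket_pairs <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  if (!all(ch %in% c(".", "(", ")")))
    stop("structure contains characters other than '.', '(', ')'")
  open <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  out <- vector("list", sum(ch == ")"))
  k <- 0L
  for (i in seq_along(ch)) {
    if (ch[i] == "(") open <- c(open, i)
    else if (ch[i] == ")") {
      if (!length(open)) stop("unbalanced structure: unmatched ')' at ", i)
      k <- k + 1L
      out[[k]] <- c(open[length(open)], i)
      open <- open[-length(open)]
    }
  }
  if (length(open)) stop("unbalanced structure: unmatched '('")
  if (k == 0L) return(matrix(integer(0), ncol = 2,
                             dimnames = list(NULL, c("i", "j"))))
  m <- do.call(rbind, out[seq_len(k)])
  m <- m[order(m[, 1]), , drop = FALSE]
  dimnames(m) <- list(NULL, c("i", "j"))
  m
}

#' Stem statistics of a dot-bracket structure
#'
#' Base pairs are decomposed into helices (maximal runs of stacked pairs).
#' `n_pairs_contig_stem` is the longest such run; `n_pairs_max_stem` is the
#' largest total over chains of helices merged across junctions with at most
#' one unpaired nucleotide on either side (mismatches and single-nucleotide
#' bulges); `n_pairs_all` counts every pair in the window.
#'
#' @param structure dot-bracket string.
#' @return list with `n_pairs_all`, `n_pairs_max_stem`,
#'   `n_pairs_contig_stem`.
#' @examples
#' stem_statistics("(((.((...)).)))")  # all 5, max 5, contig 3
#' @export
stem_statistics <- function(structure) {
  pr <- dotbracket_pairs(structure)
  if (nrow(pr) == 0L)
    return(list(n_pairs_all = 0L, n_pairs_max_stem = 0L,
                n_pairs_contig_stem = 0L))
  # helices: runs of (i,j),(i+1,j-1),...
  pr <- pr[order(pr[, 1]), , drop = FALSE]
  key <- paste(pr[, 1], pr[, 2])
  has <- function(i, j) paste(i, j) %in% key
  helix_id <- integer(nrow(pr))
  hid <- 0L
  for (r in seq_len(nrow(pr))) {
    i <- pr[r, 1]; j <- pr[r, 2]
    if (has(i - 1L, j + 1L)) {
      helix_id[r] <- helix_id[which(pr[, 1] == i - 1L & pr[, 2] == j + 1L)]
    } else {
      hid <- hid + 1L
      helix_id[r] <- hid
    }
  }
  sizes <- tabulate(helix_id, nbins = hid)
  # helix outer/inner pairs
  outer_i <- tapply(pr[, 1], helix_id, min)
  inner_i <- tapply(pr[, 1], helix_id, max)
  inner_j <- tapply(pr[, 2], helix_id, min)
  # chain helices: helix B directly nested in helix A's inner pair with
  # <= 1 unpaired nt on each side
  best_chain <- sizes
  ord <- order(inner_i, decreasing = TRUE)  # innermost first
  for (h in ord) {
    ii <- inner_i[h]; ij <- inner_j[h]
    # find helix whose outer pair (oi, oj) satisfies the junction rule
    for (g in seq_len(hid)) {
      if (g == h) next
      oi <- outer_i[g]; oj <- pr[which(helix_id == g & pr[, 1] == oi), 2]
      if (oi > ii && oj < ij &&
          (oi - ii - 1L) <= 1L && (ij - oj - 1L) <= 1L) {
        cand <- sizes[h] + best_chain[g]
        if (cand > best_chain[h]) best_chain[h] <- cand
      }
    }
  }
  list(n_pairs_all = nrow(pr),
       n_pairs_max_stem = as.integer(max(best_chain)),
       n_pairs_contig_stem = as.integer(max(sizes)))
}
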
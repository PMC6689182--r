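# Independent oracles used by the folding tests.
#
# The enumeration oracle lists every legal secondary structure of a short
# sequence (legal pairs AU/UA/GC/CG/GU/UG, hairpin loops >= 3 nt) by
# recursion, scores each complete structure by a loop-decomposition walk
# that shares only the parameter table with the package, and minimizes.
# It never calls the dynamic program it checks.

.ok_pair <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

# all structures of chars[i..j] as lists of rbind(i, j) pair matrices
enum_structures <- function(chars, i, j) {
  if (j - i < 4L) return(list(matrix(integer(0), ncol = 2)))
  # j unpaired
  out <- enum_structures(chars, i, j - 1L)
  # j paired with k (hairpin >= 3 enforced by k <= j - 4)
  for (k in seq(i, j - 4L)) {
    if (!.ok_pair(chars[k], chars[j])) next
    left <- if (k > i) enum_structures(chars, i, k - 1L)
            else list(matrix(integer(0), ncol = 2))
    inner <- enum_structures(chars, k + 1L, j - 1L)
    for (l in left) for (m in inner)
      out <- c(out, list(rbind(l, m, c(k, j))))
  }
  out
}

# score one complete structure by loop decomposition (independent of the DP)
score_structure <- function(chars, pairs, par = teseq::rna_energy_params()) {
  if (nrow(pairs) == 0L) return(0)
  partner <- integer(length(chars))
  for (r in seq_len(nrow(pairs))) {
    partner[pairs[r, 1]] <- pairs[r, 2]
    partner[pairs[r, 2]] <- pairs[r, 1]
  }
  ptype <- function(i, j) paste0(chars[i], chars[j])
  score_branch <- function(i, j) {
    # children: maximal pairs directly inside (i, j)
    kids <- matrix(integer(0), ncol = 2)
    k <- i + 1L
    while (k < j) {
      if (partner[k] > k && partner[k] < j) {
        kids <- rbind(kids, c(k, partner[k]))
        k <- partner[k] + 1L
      } else k <- k + 1L
    }
    if (nrow(kids) == 0L) {                      # hairpin
      loop <- j - i - 1L
      return(par$hairpin_a + par$hairpin_b * (loop - 3L))
    }
    if (nrow(kids) == 1L) {                      # stack / bulge / interior
      k <- kids[1, 1]; l <- kids[1, 2]
      d1 <- k - i - 1L; d2 <- j - l - 1L
      e <- if (d1 == 0L && d2 == 0L) par$stack[ptype(i, j), ptype(k, l)]
           else if (d1 > par$max_loop || d2 > par$max_loop) Inf
           else if (d1 == 0L || d2 == 0L)
             par$bulge_a + par$bulge_b * (d1 + d2 - 1L)
           else par$interior_a + par$interior_b * (d1 + d2 - 2L)
      return(e + score_branch(k, l))
    }
    # multiloop
    unpaired <- (j - i - 1L) - sum(kids[, 2] - kids[, 1] + 1L)
    e <- par$ml_close + par$ml_branch * (nrow(kids) + 1L) +
      par$ml_unpaired * unpaired
    for (r in seq_len(nrow(kids))) e <- e + score_branch(kids[r, 1], kids[r, 2])
    e
  }
  # exterior loop: no cost, sum over outermost branches
  total <- 0
  k <- 1L
  while (k <= length(chars)) {
    if (partner[k] > k) {
      total <- total + score_branch(k, partner[k])
      k <- partner[k] + 1L
    } else k <- k + 1L
  }
  total
}

# oracle MFE: round to the DP's 0.01 kcal/mol resolution
oracle_mfe <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n < 5L) return(0)
  structs <- enum_structures(chars, 1L, n)
  e <- vapply(structs, function(p)
    round(score_structure(chars, p) * 100) / 100, numeric(1))
  min(0, min(e))
}

random_rna <- function(n, prob = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE, prob = prob),
        collapse = "")
}
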
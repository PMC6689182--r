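test_that("dataset validation drops invalid records with reasons", {
  good <- make_record(gene_id = "g1")
  bad_iaug <- make_record(cds = "GUGGCUGCUUAA", gene_id = "g2")
  dna <- make_record(utr = "ACGTACGTAC", gene_id = "g3")  # T input
  d <- te_dataset(rbind(good, bad_iaug, dna), quiet = TRUE)
  expect_equal(nrow(d$records), 2L)
  expect_equal(d$dropped$gene_id, "g2")
  expect_match(d$dropped$reason, "not AUG")
  # DNA alphabet normalized to RNA
  expect_false(grepl("T", d$records$seq[d$records$gene_id == "g3"]))
  expect_match(d$records$seq[d$records$gene_id == "g3"], "^ACGUACGUAC")
})

test_that("FASTA+TSV and combined-table loaders agree", {
  d0 <- make_dataset(n = 5, seed = 3)
  fa <- tempfile(fileext = ".fa"); tsv <- tempfile(fileext = ".tsv")
  writeLines(paste0(">", d0$records$gene_id, "\n", d0$records$seq), fa)
  write.table(d0$records[, c("gene_id", "utr5_len", "cds_len", "tr", "rpkm")],
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  d1 <- load_dataset(fa, tsv)
  expect_equal(d1$records$seq, d0$records$seq)
  comb <- tempfile(fileext = ".tsv")
  write.table(data.frame(
    gene_id = d0$records$gene_id,
    utr5_seq = substr(d0$records$seq, 1, d0$records$utr5_len),
    cds_seq = substr(d0$records$seq, d0$records$utr5_len + 1,
                     d0$records$utr5_len + d0$records$cds_len),
    tr = d0$records$tr, rpkm = d0$records$rpkm),
    comb, sep = "\t", quote = FALSE, row.names = FALSE)
  d2 <- load_dataset(comb)
  expect_equal(d2$records$utr5_len, d0$records$utr5_len)
  expect_equal(d2$records$seq,
               substr(d0$records$seq, 1,
                      d0$records$utr5_len + d0$records$cds_len))
  expect_error(load_dataset(tempfile()), "no such file")
})

test_that("filter_dataset averages replicas and applies thresholds", {
  d <- make_dataset(n = 4, seed = 5)
  ids <- d$records$gene_id
  rep1 <- data.frame(gene_id = ids, tr = c(2, 1, 1, 1), rpkm = c(5, 5, 0.4, 5))
  rep2 <- data.frame(gene_id = ids[-2], tr = c(4, 1, 1), rpkm = c(5, 0.4, 5))
  f <- filter_dataset(d, replica_tables = list(rep1, rep2))
  # g2 absent from one replica -> removed; g3 mean RPKM < 1 -> removed
  expect_setequal(f$records$gene_id, ids[c(1, 4)])
  expect_equal(f$records$tr[f$records$gene_id == ids[1]], 3)  # mean(2, 4)
  f2 <- filter_dataset(d, allow_list = ids[1:2])
  expect_setequal(f2$records$gene_id, ids[1:2])
  expect_error(filter_dataset(d, min_abundance = 1e9), "no genes remain")
})

test_that("split_cohorts is deterministic, disjoint, and order-invariant", {
  d <- make_dataset(n = 100, seed = 7)
  co <- split_cohorts(d)
  expect_length(co$high, 10)
  expect_length(co$low, 10)
  expect_length(intersect(co$high, co$low), 0)
  # invariance to record order
  d2 <- d; d2$records <- d2$records[rev(seq_len(100)), ]
  co2 <- split_cohorts(d2)
  expect_identical(co, co2)
  # all-ties: ids in lexicographic order
  d3 <- make_dataset(n = 30, seed = 7, tr = rep(1, 30))
  co3 <- split_cohorts(d3)
  expect_length(co3$high, 3)
  expect_identical(co3$low, sort(d3$records$gene_id)[1:3])
  expect_error(split_cohorts(d, fraction = 0.6), "fraction")
})

test_that("coordinate mapping is a bijection and round-trips", {
  u <- 17L
  pos <- c(seq(-u, -1L), seq(1L, 30L))
  idx <- iaug_to_index(pos, u)
  expect_equal(sort(idx), seq_len(u + 30L))
  expect_equal(index_to_iaug(idx, u), pos)
  expect_error(iaug_to_index(0L, u), "position 0")
})

test_that("extract_region truncates and partitions the mRNA", {
  rec <- make_dataset(n = 1, utr_len = 100, n_codons = 40, seed = 9)$records[1, ]
  ape <- c(-35L, 28L)
  expect_equal(nchar(extract_region(rec, "five_prime_of_APE", ape)), 65L)
  # short UTR: uAPE truncated at cap, 5'ofAPE empty
  rec10 <- make_dataset(n = 1, utr_len = 10, n_codons = 40, seed = 9)$records[1, ]
  expect_identical(extract_region(rec10, "five_prime_of_APE", ape), "")
  expect_equal(extract_region(rec10, "uAPE", ape), substr(rec10$seq, 1, 10))
  # CDS 3' of APE starts at +29
  cds3 <- extract_region(rec, "CDS_3prime_of_APE", ape)
  expect_equal(cds3, substr(rec$seq, rec$utr5_len + 29, rec$utr5_len + rec$cds_len))
  # partition property over random records
  d <- make_dataset(n = 20, utr_len = 50, n_codons = 30, seed = 11)
  for (g in seq_len(20)) {
    r <- d$records[g, ]
    iaug <- substr(r$seq, r$utr5_len + 1, r$utr5_len + 3)
    whole <- paste0(extract_region(r, "five_prime_of_APE", ape),
                    extract_region(r, "uAPE", ape), iaug,
                    extract_region(r, "dAPE", ape),
                    extract_region(r, "CDS_3prime_of_APE", ape))
    expect_identical(whole, substr(r$seq, 1, r$utr5_len + r$cds_len))
  }
})

test_that("assign_parts follows the species thresholds", {
  mk <- function(u, scheme) {
    d <- make_dataset(n = 1, utr_len = u, seed = 1, scheme = scheme)
    unname(assign_parts(d))
  }
  expect_equal(mk(34, "three_part_cerevisiae"), "part2_mid")
  expect_equal(mk(35, "three_part_cerevisiae"), "part3_long")
  expect_equal(mk(19, "three_part_cerevisiae"), "part1_short")
  expect_equal(mk(65, "two_part_arabidopsis"), "part2_long")
  expect_equal(mk(64, "two_part_arabidopsis"), "part1_short")
  expect_equal(mk(200, "one_part"), "part1")
})
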
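# Small fixture builders (in code; no data files).

# one record as a single-row data.frame, defaulting to a clean gene
make_record <- function(utr = "ACGUACGUAC", cds = "AUGGCUGCUUAA",
                        gene_id = "g1", tr = 1, rpkm = 10) {
  data.frame(gene_id = gene_id, seq = paste0(utr, cds),
             utr5_len = nchar(utr), cds_len = nchar(cds),
             tr = tr, rpkm = rpkm, stringsAsFactors = FALSE)
}

# dataset of n genes with random UTR/CDS and lognormal TR
make_dataset <- function(n = 30, utr_len = 20, n_codons = 10, seed = 1,
                         scheme = "one_part", tr = NULL) {
  set.seed(seed)
  sense <- teseq::sense_codons()
  rows <- lapply(seq_len(n), function(i) {
    utr <- paste(sample(c("A", "C", "G", "U"), utr_len, replace = TRUE),
                 collapse = "")
    cds <- paste0("AUG", paste(sample(sense, n_codons - 2L, replace = TRUE),
                               collapse = ""), "UAA")
    make_record(utr, cds, gene_id = sprintf("g%03d", i),
                tr = if (is.null(tr)) rlnorm(1, 0, 1) else tr[i])
  })
  teseq::te_dataset(do.call(rbind, rows), scheme = scheme, quiet = TRUE)
}
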
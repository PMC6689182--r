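# teseq — modeling cis-translational control from general mRNA sequence features

Ribosome profiling shows that steady-state translation rates (TR, footprint
density per mRNA) differ ~100-fold between genes.  Much of that difference
is written into the mRNA itself, in five *general* sequence features: RNA
secondary structure in the 5' region, upstream AUGs (uORFs), the nucleotide
context flanking the initiating AUG, CDS length, and codon usage.  `teseq`
is an R package for quantifying how much of the variance in log10 TR these
features control, singly and together, and how strongly their control
overlaps:

* **Fold features** — sliding-window minimum-free-energy features over the
  5' region (location-, rank- and threshold-based families at many window
  lengths), computed with a built-in simplified Zuker-style folder (Rcpp)
  or any plugged-in external backend; dot-bracket stem statistics; a
  nearest-neighbor duplex-energy model.
* **Motif features** — iAUG-anchored position weight matrices built from
  the most highly translated decile, APE boundary scanning, di/tri-
  nucleotide frequencies, high/low-TR tri-nucleotide ratio tables.
* **Simple features** — uAUG counts, log10 CDS amino-acid count, 61 codon
  frequencies, 20 amino-acid frequencies, 61 synonymous-codon preferences,
  N-/C-half codon usage.
* **Models** — single- or multipart OLS of log10 TR (parts split by 5'UTR
  length, per-part coefficients), BIC forward selection, bootstrap CIs,
  and the collinearity-overlap statistic
  `100 · max((R²A+R²B−R²AB)/R²A, (R²A+R²B−R²AB)/R²B)`.
* **Synthetic data** — a generator with planted, ground-truthed effects
  (hairpins, uAUGs, start context, CDS length, codon bias) driven by a
  single latent score (collinear regime) or independent latents, with a
  calibrated explainable-variance fraction.

## Worked example

```r
library(teseq)

set.seed(1)
gen <- generate_dataset(generator_config(n_genes = 400, seed = 42,
                                         target_r2 = 0.6))
run <- run_pipeline(gen$dataset,
                    run_config(lengths = c(20L, 35L),
                               ape_bounds = c(-35L, 28L),
                               bootstrap = 200, seed = 42))

run$combined$r2                      # 0.649
unlist(run$combined$ci)              # 0.675 0.764 (bootstrap 95% CI)
sapply(run$fits, `[[`, "r2")
#    RNAfold fivemotifs       uAUG     CDSlen      codon
#      0.226      0.393      0.173      0.229      0.538
run$overlaps[c(1, 4, 9), c("set_a", "set_b", "overlap_pct")]
#        set_a set_b overlap_pct
#   fivemotifs  uAUG        78.3
#      RNAfold  uAUG        61.9
#       CDSlen codon        94.7
```

Reading the output: the five feature sets jointly explain 64.9% of the
variance in log10 TR — close to the 60% planted by the generator (the small
excess is finite-sample overfit at n = 400).  The overlap column shows the
collinear regime the generator plants: e.g. 94.7% of the variance explained
by CDS length is shared with the codon-frequency model, because a single
latent gene score drives both planted effects.  On the same run, the
second-most-folded non-overlapping window shares 91.2% of its control with
the most folded one, and the AUG tri-nucleotide's high-TR/low-TR frequency
ratio in 5'UTRs is 0.37 (< 1: uAUGs mark poorly translated mRNAs).

Real datasets load from FASTA + annotation TSV (`gene_id`, `utr5_len`,
`cds_len`, `tr`, `rpkm`) or from a combined table with explicit
`utr5_seq`/`cds_seq` columns:

```r
d <- load_dataset("genes.fa", "annotation.tsv",
                  scheme = "three_part_cerevisiae")
d <- filter_dataset(d, min_abundance = 1)
run <- run_pipeline(d, run_config())   # full 21-length window grid
```

A command-line wrapper with `generate` and `run` verbs is installed as
`exec/teseq`.

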
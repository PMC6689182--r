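---
title: "Modeling cis-translational control from mRNA sequence: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cis-translational control from mRNA sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Steady-state translation rates (TR; ribosome footprint density per mRNA
molecule, from ribosome profiling) vary over roughly two orders of magnitude
between the genes of a genome.  A substantial part of that variation is
encoded in *general* mRNA sequence features — elements present in all or
most mRNAs that act on the preinitiation complex or the ribosome:

1. **RNA secondary structure** in the 5' region (5'UTR plus the 5'-most
   ~30 nt of the CDS), which impedes scanning;
2. **upstream AUGs** (uAUGs), whose uORFs divert initiation;
3. **nucleotides flanking the initiating AUG** (the AUG-proximal element,
   APE, including the Kozak context), which modulate start-codon
   recognition;
4. **CDS length**, which sets the efficiency of ribosome-subunit recycling
   from stop codon back to the 5' end; and
5. **codon usage**, whose match to the aminoacylated-tRNA pool sets
   elongation efficiency.

`teseq` turns each of these into quantitative per-gene features, fits
BIC-selected (possibly multipart) ordinary-least-squares models of log10 TR,
and quantifies how much explained variance two feature sets *share*
("collinearity of control") with the variance-partitioning statistic

  overlap % = 100 · max( (R²A + R²B − R²AB)/R²A , (R²A + R²B − R²AB)/R²B ).

All model R² values are the square of the Pearson correlation between
observed and pooled predicted responses, which for per-part OLS with
intercepts coincides with 1 − RSS/TSS.

## Coordinates and data model

Positions are anchored at the initiating AUG: its A is +1, the nucleotide
5' of it is −1; there is no position 0.  A dataset is a validated table of
records (sequence, 5'UTR and CDS lengths, TR, mRNA abundance).  Records are
dropped — with a logged reason — when the annotated CDS does not start with
AUG, the CDS length is not a positive multiple of 3, or lengths exceed the
sequence.  Replicate tables are averaged per gene after removing genes
absent from any replicate; genes under 1 RPKM are excluded by default.

Species with long, variable 5'UTRs are fitted *multipart*: genes are
grouped by 5'UTR length (two parts split at 65 nt, Arabidopsis-style; three
parts split at 20 and 35 nt, budding-yeast-style) and each part receives
its own intercept and coefficients, with one shared feature list.  The BIC
penalty counts all estimable parameters across parts.

## RNA folding features

Free energies come from a pluggable backend.  The shipped backend is a
deliberately **simplified Zuker-style dynamic program** over Watson–Crick
and G·U pairs:

* Watson–Crick stack energies are the published nearest-neighbor ΔG°37
  values (the same table drives `duplex_energy()`, which adds duplex
  initiation (+4.09), terminal-AU (+0.45 each) and self-complementarity
  (+0.43) terms, all kcal/mol);
* any stack involving a wobble pair uses one flat constant (−1.2 kcal/mol);
* hairpin (≥3 nt), bulge, and interior loops carry affine penalties
  (5.0 + 0.3/nt, 3.6 + 0.3/nt, 4.0 + 0.3/nt); multibranch loops cost
  3.4 + 0.4/branch + 0.1/unpaired nt;
* no dangling ends, no coaxial stacking, no terminal-AU penalty inside
  folds; bulge/interior sides are capped at 10 unpaired nt (under affine
  penalties larger loops essentially never reach the MFE, and the cap keeps
  genome-scale window tiling fast).

This folder is exact for its own model: the test suite verifies it against
exhaustive enumeration of all legal structures for sequences up to 14 nt.
It is a stand-in for a full Turner-parameter folder (ViennaRNA), which can
be plugged in as a function backend; published energies should not be
expected from the built-in model.  Ties among co-optimal structures are
broken deterministically: the exterior loop prefers leaving a base unpaired
(this guarantees ΔG = 0 exactly when the returned structure has no pairs),
and within a helix the traceback prefers the 5'-most continuation over
bifurcation.

Windows of length L tile the 5' region with 1-nt offsets, starting at every
5'UTR position from the cap to −1 (the last window reaches CDS position
+(L−1)); one banded dynamic program per gene folds all of its windows.
Per (dataset, length) the feature families are: six location features
(window starting at the cap, −65, −35, −30, −6, −1), six rank features
(min, 10%, 25%, 75%, 90%, max of the gene's window energies, nearest-rank),
the mean, three percent-beyond-pooled-threshold features and five
sum-beyond-threshold features (thresholds are nearest-rank percentiles of
all windows of all genes; genes with no qualifying window score 0), plus a
single "whole" feature (cap..+35 fold).  The default grid of 21 lengths
spans 6–100 nt, densest over the 25–60 nt range where the most-folded
window is most informative.  Note the family enumeration yields
21 × n_lengths + 1 columns; the "RNAfold" feature set is the BIC-forward
selection over all of them.  An optional constraint (used for fission
yeast) removes every window extending 3' of +30 before selection.

## 5' motif features

PWMs are built from the top-decile (high-TR) cohort, aligned at the iAUG;
a gene contributes counts only at positions it covers, and 0.5 pseudocounts
per nucleotide keep unseen bases finite.  A gene's score is the summed
log10 frequency of its bases, defined only when the gene fully contains the
PWM.  APE bounds are chosen by scanning PWM extents (5' from −5 to −100 in
5-nt steps; 3' at none, +8..+33 in 5-nt steps) and maximizing the R² of a
single-part regression of log10 TR on the score.  Each region (uAPE, dAPE,
5'-of-APE with its 5-nt cap PWM) contributes its PWM score plus 16
dinucleotide and 64 trinucleotide frequencies; BIC forward selection per
region defines the region sets, whose union is the "5'motifs" set.  In
multipart schemes, short-UTR parts are scored with correspondingly shorter
uAPE PWMs (−20..−1, −5..−1).

High/low-TR tri-nucleotide ratio tables (means of per-gene frequencies in
a region, high over low) and their cross-region Pearson correlations
implement the conservation analyses; ratios are undefined where the low-TR
mean is zero.

## Simple features and the combined model

`uAUG` is the count of (possibly overlapping) AUGs strictly within the
5'UTR.  `CDSlen` is log10 of the number of encoded amino acids — cds_len/3
minus the stop codon, initiator Met included.  The codon families are the
61 sense-codon frequencies ("codon"), 20 amino-acid frequencies ("AA"), 61
synonymous preferences (codon count over its family total; undefined for
amino acids absent from a gene, so syn.codon analyses are restricted to
genes containing all 20 amino acids, with the retained fraction reported),
and N-/C-half codon frequencies (odd counts give the N-half the smaller
half).  The identity codon = AA × syn.codon holds exactly and is tested.

The combined model concatenates the five pre-selected sets (a flag re-runs
BIC over the union instead: with pre-selection the combined R² is the
descriptive quantity; re-selection is the parsimonious variant used for
null-data checks).  Confidence intervals come from a 1000× bootstrap that
resamples genes with replacement within parts and refits coefficients with
the feature list frozen — re-selecting per resample would estimate a
different, wider quantity.

Missing feature values (a gene lacking a window or not containing a PWM)
are imputed with the feature's dataset mean inside model matrices only —
never in the response — and the missingness mask is retained.

## The synthetic-data generator

The generator states a budding-yeast-like world: lognormal 5'UTR lengths
(median 45 nt, clipped to 5–500), lognormal CDS lengths (median 400 codons,
clipped to 50–2000), AU-rich background (GC = 0.40), one-part scheme.  A
single latent gene score t ~ N(0,1) drives all five effects by default (the
collinear regime real genomes show); a switch draws independent latents per
effect.  Per gene: hairpins with stem length increasing in −t are planted
into the UTR (stems drawn from the background composition so the marginal
GC stays at the configured value); a Poisson number of AUGs with rate
decreasing in t is inserted; the −6..−1 context is drawn from a
strong/weak PWM mixture weighted by t; CDS codon count is log-correlated
with −t; synonymous codons are drawn with preference weight e^(1.2t) for
one preferred codon per family.  log10 TR is the weighted sum of the
standardized realized effect scores plus Gaussian noise; when a target
explainable-variance fraction f is requested, the noise SD is set to
sd(signal)·sqrt((1−f)/f), which calibrates the realized fraction to within
±0.02 at n ≥ 2000.

What a green test establishes: the pipeline recovers planted effects,
selection is specific under a null, and the overlap statistic separates
collinear from independent regimes.  What it does not establish: agreement
with any real genome's feature distributions (no phylogenetic structure, no
real codon-usage tables, uniform amino-acid composition, iid UTR background
beyond the planted elements), nor the absolute R² values of the paper-scale
datasets, which require the real ribosome-profiling tables and a
full-parameter folder.

## Numerical and design choices

* Cohort ties at the decile boundary, window-energy ties, and BIC ties are
  broken deterministically (gene-id order, 5'-most window, first column).
* Nearest-rank quantiles everywhere a percentile is named.
* BIC = n·ln(RSS/n) + k·ln(n), pooled residuals, k = all estimable
  parameters; forward selection stops at the first non-improving step.
* Aliased columns are dropped by the QR with a warning and do not count
  toward k, so duplicated features never change a selected model.
* Genes with 5'UTR length 0 are retained; their fold and 5'-motif features
  are missing (imputed) rather than the genes dropped.
* The acceptance-scale simulations run the pipeline at a single window
  length (35 nt, the optimum for short-UTR genomes) to stay inside time
  budgets; the window grid is an explicit run parameter, not a constant.

## Known limitations

* The built-in folder's energies are model-internal; only orderings and
  window locations, not kcal/mol values, transfer to Turner-parameter
  folders.
* Forward selection is greedy; it provably matches exhaustive-subset BIC
  only on benign (near-orthogonal) designs, which the tests use.
* The boundary scan's R² can drift upward into signal-free flanks on small
  cohorts because cohort genes score their own bases; at genome scale the
  effect is negligible, and the scan is validated on data where score
  attenuation dominates.
* PWM scores are trained on the high-TR decile and then scored on all
  genes, including that decile.  Even on data where TR is independent of
  sequence this leaks a small amount of rank information (R² of order
  0.005–0.03 at n = 2000), so PWM-based models never have an exactly-zero
  null.  Null-behavior checks therefore use the plain per-gene feature
  candidates; held-out cohort scoring would remove the leak but would
  depart from the method being implemented.
* Single-isoform and poly-A filters are generic allow-lists; no isoform
  resolution is attempted.
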
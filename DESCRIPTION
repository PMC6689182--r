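Package: teseq
Title: Modeling Cis-Translational Control from General mRNA Sequence Features
Version: 0.1.0
Authors@R:
    person("teseq", "maintainers", email = "teseq@example.org", role = c("aut", "cre"))
Description: Computes five families of general mRNA sequence features that
    control translation rates (5'-region RNA folding energies over sliding
    windows, 5' sequence motifs and AUG-proximal position weight matrices,
    upstream AUG counts, CDS length, and codon usage), fits BIC-selected
    multipart linear models of log10 translation rate, and quantifies the
    collinearity of control between features and between mRNA segments.
    Includes a nearest-neighbor RNA duplex energy model, a simplified
    built-in minimum-free-energy folder, and a synthetic-data generator
    with planted effects and known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
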
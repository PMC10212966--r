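Package: meltshift
Title: Differential Thermal Proteome Stability Analysis for Pooled-Temperature Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of thermal proteome stability experiments
    in which the soluble fractions across a temperature gradient are pooled
    into a single sample (proteome integral solubility alteration, PISA), as
    used to read out protein-methylation function. Provides a logistic
    melting-curve model with bounded multi-start least-squares fitting and a
    nested-model F-test for two-condition curve comparison (NPARC-style);
    locally weighted normalization of log2 reporter-intensity matrices;
    empirical-Bayes moderated two-group testing with Benjamini-Hochberg
    adjustment and joint stability/abundance classification to separate
    genuine stability shifts from expression changes; hypergeometric overlap
    statistics with representation factors, rank-based subset shift tests,
    and pre-ranked running-sum enrichment with permutation normalization;
    plus arginine RG-motif classification of methyl sites and fractional
    occupancy estimation from counterpart-peptide depletion. A ground-truth
    labelled synthetic-data generator makes every stage testable without
    access to raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    limma,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
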
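Package: strandmeth
Title: Strand-Resolved Bisulfite Clone-Sequencing Methylation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for clone-level bisulfite amplicon methylation analysis with
    explicit strand handling. Models bisulfite chemistry on reference amplicons
    (CpG discovery, in-silico conversion, strand-specific primer validation),
    simulates clone libraries with known per-CpG per-strand methylation
    probabilities, aligns clone sequences to references with a
    conversion-aware asymmetric scoring scheme, calls per-CpG methylation
    states with conversion-efficiency QC, and provides the statistical layer
    used for paired population comparisons: crossed mixed-effects tests of
    paired methylation differences, donor-level sign-flip permutation tests,
    Bonferroni-corrected significance thresholds, strand-bias
    (hemimethylation) analysis, and complete-linkage hierarchical clustering
    of cell-subtype methylation profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    lme4,
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
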
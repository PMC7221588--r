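Package: bdmshift
Title: Branch-Specific Functional-Shift Tests for Protein Families Using
    BLOSUM62-Derived Replacement Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects signatures of functional change on individual branches of
    a protein phylogeny. Implements Felsenstein-pruning likelihood computation
    under empirical amino-acid substitution models (WAG, JTT) with
    discrete-Gamma rate heterogeneity, branch-length optimization on a fixed
    topology, neighbor-joining tree construction with bootstrap support,
    marginal maximum-likelihood ancestral sequence reconstruction, and a
    branch contrast statistic that scores high-confidence amino-acid
    replacements with a BLOSUM62-derived difference measure (BDM) and compares
    a focal branch against its pooled neighboring branches by a one-tail
    Fisher exact test. Includes a sequence-evolution simulator with an
    optional branch-specific radical-replacement shift for calibration and
    power analysis, and motif scanning utilities for delineating subfamilies
    by short conserved motifs such as PDPCK.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    Biostrings,
    jsonlite,
    withr
Config/testthat/edition: 3
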
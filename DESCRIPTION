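Package: bhlhKingdom
Title: Kingdom Classification of bHLH Protein Domains
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identification and Kingdom-level classification of basic
    Helix-Loop-Helix (bHLH) protein domains. Provides Kingdom-specific
    two-helix profile hidden Markov models for domain identification,
    Atchley factor-score transformation of enumerated alignments,
    canonical variate analysis (CVA) and stepwise discriminant analysis
    (SWDA) classifiers with Mahalanobis-distance posteriors, a chi-square
    decision tree over categorical amino-acid sites, per-site conservation
    analytics (normalized group entropy, sequence-logo bit scores, 50-10
    consensus motifs), a Kingdom-structured synthetic alignment generator,
    and one-versus-all evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
biocViews: Classification, SequenceMatching, HiddenMarkovModel, Proteomics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
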
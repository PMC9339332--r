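Package: mppscan
Title: Mixed-Model QTL Mapping for Eight-Founder Multiparental Mouse Populations
Version: 0.1.0
Authors@R: person("MPP", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: A statistical engine for quantitative trait locus (QTL) analysis
    in eight-founder multiparental mouse populations such as the Collaborative
    Cross and Diversity Outbred (DO). Provides linear mixed model genome scans
    with leave-one-chromosome-out (LOCO) kinship, founder allele effect
    estimation as fixed coefficients or best linear unbiased predictors
    (BLUPs), strain-distribution-pattern (SDP) variant association mapping,
    LOD-drop mediation analysis against -omic candidate mediators, peak
    calling and transcriptome-map summaries, plus a DO-style synthetic data
    generator and a command-line interface so every pipeline stage is testable
    at desk scale without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
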
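Package: rnairescue
Title: Design and Quantification for Mutation-Agnostic RNAi with Engineered
    Gene Replacement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational core of mutation-agnostic RNA
    interference (RNAi) with knockdown-resistant gene replacement: design of
    synonymously recoded, RNAi-resistant target sites with frame and synonymy
    verification; allele-resolved quantification of endogenous versus
    exogenous transcripts from single-cell RNA-seq reads by exact site
    matching; single-cell quality-control filters, delta-delta-Ct qPCR
    knockdown analysis, and the associated parametric and nonparametric
    statistical battery (Welch's t, ANOVA/Tukey with a Bartlett gate,
    Welch ANOVA with Dunnett-T3-style post hoc, Kruskal-Wallis with Dunn's
    test and Benjamini-Hochberg adjustment); plus seeded synthetic-data
    generators (site-spanning reads, negative-binomial expression tables,
    qPCR plates) so every stage is verifiable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
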
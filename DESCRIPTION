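Package: methinstab
Title: Unstable Methylation Genes from Paired Tumor/Normal Dual-Mark
    Nanopore Methylomes
Version: 0.1.0
Authors@R:
    person("Methinstab", "Developers", email = "devel@methinstab.org",
           role = c("aut", "cre"))
Description: Turns paired tumor/normal per-site 5mC and 6mA methylation
    score tables (as emitted by signal-level nanopore callers) into
    differential methylation sites, per-gene instability profiles and
    "unstable methylation gene" calls, quantifies the association of each
    mark with differential expression via chi-square contingency tests,
    and screens top unstable genes for survival-associated tumor
    suppressor candidates with Kaplan-Meier / log-rank statistics. A
    fully parameterised synthetic cohort generator with planted effect
    structure (up/down site-count correlation, methylation-DE coupling,
    survival hazards) provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table (>= 1.14.0),
    jsonlite,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    edgeR
Config/testthat/edition: 3
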
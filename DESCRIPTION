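Package: anclxome
Title: Mendelian Exome Filtering, Segregation Analysis and CSPalpha
    Physicochemistry for Dominant Adult Neuronal Ceroid Lipofuscinosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for prioritizing causal variants in small autosomal
    dominant pedigrees by whole-exome filtering: a multi-stage frequency,
    quality and functional-class filtering cascade with per-stage attrition
    accounting, pedigree-aware perfect-segregation testing with
    population-control screening, and a seeded synthetic cohort simulator
    (Mendelian gene-dropping with shared flow-cell artifacts and an
    implanted causal allele) so the whole pipeline is testable with known
    truth. Also provides in-silico physicochemical characterization of
    CSPalpha (DNAJC5) mutations: Kyte-Doolittle hydropathy profiles,
    Wimley-White interfacial and octanol transfer free energies, HGVS
    codon and splice-site arithmetic, and nonparametric group comparison
    (Kruskal-Wallis with Dunn post-hoc tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
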
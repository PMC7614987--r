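Package: dcanno
Title: Domain-Centric Ontology Annotation and Enrichment for Protein Structural Domains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Statistically infers mappings from protein structural domains
    (SCOP, Pfam, InterPro) to ontology terms from a corpus of annotated
    proteins. Builds a term-by-domain correspondence matrix, tests each
    pair with a one-sided Fisher's exact test, controls the false
    discovery rate by Benjamini-Hochberg, attaches a hypergeometric
    z-score based annotation score rescaled into the 1-100 range, and
    propagates annotations to all ancestor terms over the ontology
    directed acyclic graph (the True Path Rule). Also provides
    domain-based ontology enrichment analysis for user domain lists
    against a reference annotation table, a synthetic-corpus generator
    with planted domain-term associations for validation, and
    command-line entry points for build, enrich and simulate workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
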
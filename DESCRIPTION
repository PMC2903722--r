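Package: rbmed
Title: Rule-Based Semantic Mediation for SBML Model Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semantic integration of heterogeneous molecular-biology data
    sources (UniProtKB XML, PSI-MI 1.0 interaction XML, BioPAX level-2 style
    RDF) into a compact core domain ontology via forward-chaining
    antecedent/consequent mapping rules, followed by export of the integrated
    knowledge onto an SBML Level 2 model as MIRIAM cross-reference
    annotations, SBO terms, names, new species and skeleton reactions.
    Includes a non-materializing select query facility, defined-class
    instance classification over existential restrictions, key-based
    equivalence reconciliation with organism restriction, a deterministic
    synthetic corpus generator replaying the RAD9 checkpoint use cases, and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
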
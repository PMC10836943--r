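Package: gemmerge
Title: Merge, Compare and Translate Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Merges two or more genome-scale metabolic models (GEMs) that may
    use incompatible identifier namespaces. Metabolite identifiers from
    MetaNetX, ModelSEED, BiGG, KEGG and ChEBI are reconciled into a universal
    identifier mapper with explicit precedence and conflict rules; reactions
    are matched across models by keys built from their translated participant
    sets (optionally stoichiometry-aware); pairwise model similarity is
    quantified with Jaccard distance matrices; and models can be translated
    into any supported database namespace with MIRIAM-style annotation
    extension. Models are read and written in SBML Level 3 (FBC v2), COBRA
    JSON and COBRA MATLAB formats.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
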
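Package: taxmerge
Title: Assembly of a Synthetic Reference Taxonomy from Prioritized Sources
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assembling a single synthetic taxonomy from two or
    more source taxonomies supplied in priority order. Source nodes are
    aligned to a growing workspace by name-string matching with an ordered
    set of disambiguation heuristics (separation taxa, disparate ranks,
    shared lineage, subtree overlap, proximity, same name-string), and
    unaligned nodes are merged structurally as grafts or insertions, with
    absorption and conflict handling and incertae sedis placement.
    Includes readers and writers for labels-only Newick and a tabular
    taxonomy interchange format, curator patch directives, stable
    identifier assignment across taxonomy versions, and deterministic
    synthetic-taxonomy generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringi,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
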
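Package: metaprot
Title: Protein Search Database Construction and Consensus Annotation for
    Metaproteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds curated protein search databases for metaproteomics
    (merging FASTA sources, exact-identity deduplication, MD5 header
    hashing, and taxonomy- or function-scoped subsetting from a pluggable
    local protein source) and computes post-identification consensus
    annotations for protein groups: a lowest-common-ancestor taxonomic
    consensus over NCBI-style taxonomies and a most-frequent-name
    functional consensus over filtered tabular alignment hits. Includes a
    synthetic-data generator that plants ground truth for end-to-end
    validation and a command-line interface exposing the workflow as
    composable subcommands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
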
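Package: kgmlnet
Title: Topology-Preserving KEGG Pathway Networks from KGML
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Parses KEGG Markup Language (KGML) pathway files into mixed
    gene/compound/pathway networks and gene-only networks as tab-separated
    edge lists.  Duplicated accessions that occur in separate neighborhoods
    of a pathway map are kept apart by attaching the numeric KGML entry id
    as a terminal modifier, and non-gene nodes are removed by shortest-path
    compound propagation so gene-only networks stay connected exactly where
    the original map was.  Includes a KEGG REST client with on-disk caching,
    export of the original x-y node layout, conversion of identifiers to
    NCBI Entrez or UniProt, synthetic KGML generators for offline testing,
    and evaluation metrics (per-pathway edge difference and partition
    modularity) for comparing parse variants.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    tools,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
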
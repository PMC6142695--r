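Package: cidkat
Title: Document-Level Chemical-Induced Disease Relation Extraction with
    Knowledge Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts chemical-induced disease (CID) relations from annotated
    biomedical abstracts at the document level. Reads PubTator-format corpora,
    chemical-disease knowledge tables and MeSH tree numbers; builds entity-level
    candidate pairs with a sentence-span filter; encodes each article with a
    hierarchical bidirectional-LSTM/CNN network; weighs knowledge-base relation
    embeddings by an attention mechanism conditioned on the learned document
    representation; classifies each candidate pair with a softmax layer trained
    by RMSprop; post-filters predictions by MeSH-tree disease hypernymy; and
    evaluates at the entity level with inter-/intra-sentential stratification.
    Includes a synthetic corpus generator with controllable knowledge and
    lexical label signal so the full pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
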
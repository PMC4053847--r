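Package: transannot
Title: Homology-Guided ORF Detection, Frameshift Flagging and Functional
    Annotation of De Novo Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Processes assembled transcript sequences against a reference
    proteome organised into gene families. Transcripts are matched to
    reference proteins with a built-in six-frame translated Smith-Waterman
    search (or imported tabular search results), assigned to gene families
    by best hit or top-k majority voting, and scanned for open reading
    frames using alignment frame statistics; best hits aligning in more
    than one reading frame flag putative frameshifts, which a naive
    single-indel corrector can attempt to repair. Transcript completeness
    is meta-annotated against trimmed family CDS-length statistics,
    GO and protein-domain annotations are transferred by family consensus
    or best hit, labelled transcript subsets are tested for functional
    enrichment with the hypergeometric distribution and Bonferroni
    correction, and multiple sequence alignments can be edited with
    stringent or relaxed gap-column removal before tree building.
    A seeded synthetic-data generator emulates reference proteomes,
    families, annotations and transcript sets (clean, truncated and
    single-indel) so the entire pipeline can be exercised and benchmarked
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
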
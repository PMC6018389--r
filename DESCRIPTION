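Package: bon
Title: Biological Object Notation: a Block-Structured JSON Container for
    Biological Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Read, write, stream and convert Biological Object Notation
    (BON): a block-structured container format in JSON syntax for
    biological records. Each block is a JSON header object (record count
    plus per-attribute compression flags) followed immediately by a JSON
    payload array; blocks concatenate into streams delimited by the
    "}[" and "]{" signals. Selected attribute values (typically
    sequences, quality strings or whole phylogenetic trees) are
    compressed with zlib at level 6 and wrapped in base64 so metadata
    stays readable mid-stream. Includes a JSON-aware streaming block
    scanner, bidirectional converters for TinySeq-style XML, FASTQ
    (with length-guarded parsing of the ambiguous "@" quality lines),
    FASTA, Newick and NeXML trees encoded as vertex/edge graphs,
    deterministic synthetic fixture generators, file-size and
    compression accounting, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    xml2
Suggests:
    withr,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
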
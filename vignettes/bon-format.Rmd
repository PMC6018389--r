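---
title: "The BON container: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The BON container: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bon)
```

## The format in one paragraph

Biological Object Notation (BON) is a block-structured container in
JSON syntax. A **block** is a JSON *header* object followed
immediately — with no separator, whitespace or newline — by a JSON
*payload* array of biological objects (records). The two-byte sequence
`}[` at the junction is deliberately not valid JSON, which makes it a
boundary signal; concatenated blocks meet at the analogous `]{`
signal, so a stream of blocks is itself not valid JSON while each part
is. The header carries two mandatory attributes: `size`, the number of
top-level payload objects (objects nested *inside* a record, such as a
tree, are not counted), and `data`, a map from attribute name to a
compression flag (1 = compressed, 0 = plain). Any value flagged 1 is a
zlib stream (RFC 1950, level 6 by default) wrapped in standard base64
(RFC 3548), so large values — sequences, quality strings, whole
phylogenetic trees — travel compressed while the attribute names and
any metadata stay readable mid-stream. BON stores no newline bytes
anywhere.

```{r}
b <- bon_encode_block(
  list(list(defline = "example", sequence = "ACGTACGTACGT")),
  compress = "sequence")
cat(bon_serialize(b))
```

## Why a JSON-aware scanner, not `sed`

Because `}[` is invalid JSON, header and payload *can* be separated
with a stream editor on well-behaved data, and `bon` verifies that
equivalence in its tests. But the signal bytes are only guaranteed
unique outside JSON strings: a defline containing the literal text
`}[` would defeat a substring split. The reference scanner in this
package therefore tracks string/escape state and brace depth byte by
byte (in C, with state carried across read chunks, default 64 KiB), so
boundaries are found structurally and a value containing the signals
cannot cause a mis-split. This is a deliberate deviation-for-
correctness from the one-line `sed` recipe. Blocks and whole documents
are treated uniformly: every `]{` junction simply starts the next
block.

Streaming functions (`bon_objects()` with a callback,
`bon_peek_headers()`, `bon_validate()`) hold at most one header or one
record plus one read chunk in memory, so a stream can be screened and
filtered while it is still arriving, without temporary files. Strict
mode rejects any bytes between blocks; a single trailing newline (as
added by text editors) is tolerated by default and can be refused with
`tolerate_trailing_newline = FALSE`.

## Codec choices

* **Encoding.** Text values are UTF-8 encoded before compression.
  Nested structures (e.g. the `tree` attribute) are serialized as
  compact JSON first, so decoding can re-parse them. On decode, a
  decompressed value whose text is parseable JSON structure (starting
  `{` or `[`) is re-parsed; anything else stays a string. The corner
  case is a *plain string* value that happens to be valid JSON — it
  would be re-parsed. None of the converters in this package produce
  such values, but it is a real ambiguity of a container that does not
  record value types; it is documented rather than hidden.
* **Level.** The zlib level is fixed at 6 by default and exposed as a
  knob (`level`, 1–9) on every encoder.
* **Header self-description.** `data` enumerates *every* attribute
  occurring in the payload, flag 0 or 1, not only the compressed ones,
  so a header alone describes what a payload holds. Payload objects
  may have heterogeneous key sets; the header takes the union, in
  order of first appearance.
* **Double compression** of an already-flagged attribute is refused
  rather than silently re-wrapped. Detection is structural (encoded
  records carry a flags attribute) because content sniffing cannot
  work: a plain nucleotide sequence is itself valid base64 alphabet.
* **Determinism.** Serialization is compact (no whitespace), header
  keys are emitted in fixed order (`size`, `data`, extras in insertion
  order), doubles are printed with 15 significant digits, and the
  base64 writer never line-wraps. Byte sizes of serialized output are
  therefore reproducible, which the size-accounting module relies on.
* The base64 wrapper costs `4·⌈n/3⌉` characters for an n-byte stream,
  i.e. about 33% — the price of keeping binary zlib streams inside
  printable JSON. This is why whole-file gzip always beats compressed
  BON in raw size; BON's return is that headers and uncompressed
  attributes remain readable mid-stream.

## Sequence records

TinySeq-style XML maps to BON with the same naming scheme, dropping
the `TSeq_` prefix and flattening the one XML irregularity — the
sequence type carried as a *tag attribute* — into an ordinary key.
`taxid` and `length` are JSON numbers; line breaks inside XML sequence
text are removed. The default compresses only `sequence`.

FASTQ parsing is length-guarded. The `@` that starts a record header
is also a legal quality character (ASCII 64, inside the 33–126 quality
range), so a quality line starting with `@` is ambiguous for naive
parsers. Here, sequence lines are accumulated until the `+` separator
and quality characters are then counted until they equal the sequence
length, so the ambiguity cannot arise; mismatched lengths or quality
bytes outside 33–126 are record-level format errors naming the read.
The record identifier split is a convention of this package (the field
names both ids but not the split): the token after `@` up to the first
whitespace is `readid`; a `spot=<token>` in the remaining description
becomes `spotid`, otherwise the whole remainder does. The default
compresses `sequence` and `quality`.

## Phylogenetic trees

Each BON object holds one tree under the mandatory `tree` attribute,
encoded as two sets: `vertices` (unique `id`, optional taxon `name`,
optional `branch_length`) and `edges` (mandatory `id`, `source`,
`target`, plus free metadata such as a rate estimate with its
confidence interval). Branch lengths sit on the *child vertex* of each
branch, following the convention that nodes carry the branch-length
attribute; since graph formats such as NeXML put lengths on edges
instead, `branch_on_edges = TRUE` emits that layout and the reader
accepts either (the `branch length` spelling with a space is also
accepted on read). Ids are assigned by preorder traversal (`v0`,
`e0`, …) so serialization is byte-stable. Per-tree metadata is hoisted
beside `tree`, which keeps it readable while the whole tree value is
compressed — the default for tree blocks.

The same representation relaxes to a connected DAG in ARG mode
(`arg = TRUE`), admitting reticulations such as recombination nodes
with two parents and extra edge attributes like breakpoint locations.
Only the representation is supported; no ARG inference is performed.
Validation in tree mode checks unique ids, resolvable endpoints, a
single root, at most one incoming edge per vertex, `|E| = |V| − 1` and
connectivity; violations name the offending vertices.

Newick I/O is delegated to `ape`, with two repairs in the wrapper:
single-quoted labels are unquoted on read (and re-quoted on write when
they contain syntax characters), and a single-leaf tree — which `ape`
cannot represent — round-trips through the graph functions directly.
NeXML handling is a minimal trees-only reader/writer on `xml2`,
matching elements by local name so namespace prefixes do not matter;
characters/matrix blocks are out of scope, as is Nexus.

## Size accounting

`bon_measure()` reports byte-exact file sizes, the bytes attributable
to biological data values (`data_bytes`), and their ratio — the
data-to-file ratio; the complement is *clutter* (syntax, tags, keys).
Conventions, chosen once and used consistently: for XML, only element
text counts as data (never tag-attribute values), stripped of line
breaks; for compressed BON, the base64 text as stored on disk counts,
which is why the ratio *declines* as compression shrinks the values.
`bon_gzip_size()` measures the whole-file gzip size at level 6. Its
default method runs the `gzip` program, because the measurement is
defined as the pipeline `gzip -c -6 file | wc -c` and GNU gzip's
deflate output differs slightly in length from zlib's at the same
level; a pure-zlib gzip-container fallback exists for systems without
the binary and is accurate to the deflate-length difference (a
fraction of a percent).

On repeat-rich fixtures the expected ordering
`gzip(source) < compressed BON < uncompressed BON` holds with wide
margins; the package asserts the ordering, not absolute sizes, since
absolute numbers depend on the corpus.

## Synthetic fixtures

All tests run on generated data; nothing is downloaded. The
generators emulate, at desk scale, the shapes that matter to the
format: TinySeq-style XML entries (150–300 nt by default), FASTQ reads
(100–200 nt, qualities uniform over the full 33–126 range) with
adversarial records mixed in at stated rates — 10% of quality strings
starting with `@` and 10% of records line-wrapped, by default — and
random trees over a configurable leaf range. A repeat-rich mode
(tandem motif repeats) produces the low-complexity sequences on which
per-value compression is clearly visible. Everything is reproducible
from the seed alone, and the generators restore the caller's RNG
state.

What the fixtures do *not* emulate: realistic base composition, error
models, realistic quality-score distributions, or the multi-gigabyte
scale of public archives. Passing tests therefore demonstrate the
format's structural guarantees (round-trips, boundary safety, size
orderings) but not absolute compression percentages on real corpora,
which depend on sequence entropy and metadata density.

## Problem sizes and numerical notes

The verification suite exercises, among others: 1,000 random byte
strings through the codec, 200 random blocks (with signal bytes
injected into values) through serialize/scan, a 10,000-read
adversarial FASTQ round-trip, 100 random trees of 10–500 leaves
(topology compared by Robinson–Foulds distance, required to be 0;
total branch length conserved to 1e−9 — in practice it is conserved to
double-precision rounding, ~1e−14), and a 50,000-record repeat-rich
nucleotide fixture for the size ordering. Branch lengths are printed
with 15 significant digits, enough to round-trip doubles to well below
the 1e−9 tolerance. Ties and degenerate inputs: empty payloads, empty
byte strings, single-leaf trees and empty streams are all legal and
tested; non-finite numbers are refused at serialization.
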
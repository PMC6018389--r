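# Converters between BON and sequence-record formats.
#
# TinySeq-style XML <-> BON uses the same naming scheme as the XML
# (the "TSeq_" prefix dropped, and the sequence type -- which the XML
# carries as a tag *attribute* -- becoming an ordinary key). FASTQ
# parsing is length-guarded: quality characters are accumulated until
# their count equals the sequence length, so a quality line that
# happens to start with "@" can never be mistaken for a new record.

TINYSEQ_KEYS <- c("seqtype", "accver", "taxid", "orgname", "defline",
                  "length", "sequence")

chunk_blocks <- function(objects, compress, extras, level, block_size) {
  if (!is.finite(block_size) || block_size >= length(objects) ||
      length(objects) == 0L) {
    return(bon_encode_block(objects, compress = compress, extras = extras,
                            level = level))
  }
  if (block_size < 1L) abort_validate("block_size must be >= 1")
  splits <- unname(split(objects, ceiling(seq_along(objects) / block_size)))
  structure(lapply(splits, bon_encode_block, compress = compress,
                   extras = extras, level = level),
            class = "bon_stream")
}

read_input_text <- function(x, marker) {
  # a path if the file exists; otherwise treat as in-memory text
  if (is.character(x) && length(x) == 1L && !grepl("\n", x, fixed = TRUE) &&
      file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  if (is.character(x) && length(x) == 1L) {
    return(strsplit(x, "\n", fixed = TRUE)[[1L]])
  }
  if (is.character(x)) return(x)
  abort_validate(sprintf("expected %s text or a file path", marker))
}

# ---- TinySeq ---------------------------------------------------------------

#' Convert TinySeq-style XML to BON
#'
#' Maps every `<TSeq>` entry of an NCBI TinySeq XML document to one BON
#' object with keys `seqtype`, `accver`, `taxid`, `orgname`, `defline`,
#' `length` and `sequence` (`taxid` and `length` as JSON numbers). The
#' sequence type, carried in the XML as the `value` attribute of the
#' `TSeq_seqtype` tag, becomes a plain key. Line breaks inside the
#' sequence text are removed -- BON stores no newlines. By default only
#' the sequence value is compressed.
#'
#' @param x XML text or a file path.
#' @param compress Attribute names to compress (default `"sequence"`).
#' @param extras Named list of extra header metadata.
#' @param level zlib compression level.
#' @param block_size Records per block; `Inf` (default) emits a single
#'   block, finite values chunk the payload for streaming, recomputing
#'   each header.
#' @return A [bon_block()], or a `bon_stream` list of blocks when
#'   `block_size` chunks the input.
#' @seealso [bon_to_tinyseq()]
#' @export
tinyseq_to_bon <- function(x, compress = "sequence", extras = list(),
                           level = 6L, block_size = Inf) {
  doc <- tryCatch(
    xml2::read_xml(x),
    error = function(e) abort_parse(
      sprintf("malformed XML: %s", conditionMessage(e))))
  entries <- xml2::xml_find_all(doc, "//TSeq")
  field <- function(tag) {
    xml2::xml_text(xml2::xml_find_first(entries, paste0("./TSeq_", tag)))
  }
  seqtype <- xml2::xml_attr(
    xml2::xml_find_first(entries, "./TSeq_seqtype"), "value")
  accver <- field("accver")
  taxid <- suppressWarnings(as.integer(field("taxid")))
  orgname <- field("orgname")
  defline <- field("defline")
  len <- suppressWarnings(as.integer(field("length")))
  sequence <- gsub("[\r\n ]", "", field("sequence"))

  missing_seq <- which(is.na(sequence) | !nzchar(sequence))
  if (length(missing_seq)) {
    who <- accver[missing_seq]
    who[is.na(who)] <- sprintf("entry %d", missing_seq[is.na(who)])
    abort_format(sprintf("TinySeq entries without a sequence element: %s",
                         paste(who, collapse = ", ")))
  }
  len[is.na(len)] <- nchar(sequence)[is.na(len)]

  objects <- lapply(seq_along(entries), function(i) {
    obj <- list(seqtype = seqtype[i], accver = accver[i], taxid = taxid[i],
                orgname = orgname[i], defline = defline[i],
                length = len[i], sequence = sequence[i])
    obj[!vapply(obj, function(v) is.null(v) || (length(v) == 1L && is.na(v)),
                logical(1))]
  })
  chunk_blocks(objects, compress, extras, level, block_size)
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

#' Convert BON back to TinySeq-style XML
#'
#' Inverse of [tinyseq_to_bon()]: compressed attributes are decoded
#' transparently and each object becomes one `<TSeq>` entry, with the
#' sequence type emitted as the `value` attribute of `TSeq_seqtype`.
#'
#' @param x A [bon_block()], `bon_stream`, or BON text/path.
#' @return XML text.
#' @export
bon_to_tinyseq <- function(x) {
  objects <- as_decoded_objects(x)
  entries <- vapply(objects, function(o) {
    parts <- c("  <TSeq>")
    if (!is.null(o$seqtype)) {
      parts <- c(parts, sprintf("    <TSeq_seqtype value=\"%s\"/>",
                                xml_escape(o$seqtype)))
    }
    for (nm in c("accver", "taxid", "orgname", "defline", "length",
                 "sequence")) {
      if (!is.null(o[[nm]])) {
        v <- o[[nm]]
        v <- if (is.numeric(v)) json_num(as.double(v)) else xml_escape(v)
        parts <- c(parts, sprintf("    <TSeq_%s>%s</TSeq_%s>", nm, v, nm))
      }
    }
    paste(c(parts, "  </TSeq>"), collapse = "\n")
  }, character(1))
  paste0("<?xml version=\"1.0\"?>\n<TSeqSet>\n",
         paste(entries, collapse = "\n"), "\n</TSeqSet>\n")
}

# Accept a block, stream, or raw BON input and return decoded objects.
as_decoded_objects <- function(x) {
  if (inherits(x, "bon_block")) x <- list(x)
  if (is.list(x) && all(vapply(x, inherits, logical(1), "bon_block"))) {
    return(unlist(lapply(x, function(b) bon_decode_block(b)$payload),
                  recursive = FALSE))
  }
  out <- bon_objects(x, decode = TRUE)
  attributes(out) <- NULL
  out
}

# ---- FASTQ -----------------------------------------------------------------

split_fastq_header <- function(line) {
  hdr <- substring(line, 2L)
  sp <- regexpr("[ \t]", hdr)
  if (sp < 0L) {
    c(readid = hdr, desc = "")
  } else {
    c(readid = substr(hdr, 1L, sp - 1L),
      desc = sub("^[ \t]+", "", substring(hdr, sp + 1L)))
  }
}

spotid_from_desc <- function(desc) {
  m <- regmatches(desc, regexec("(?:^|[ \t])spot[=:]([^ \t]+)", desc))[[1L]]
  if (length(m) == 2L) m[2L] else desc
}

#' Parse FASTQ records
#'
#' Length-guarded FASTQ parsing of 4-part records whose sequence and
#' quality may be line-wrapped. Sequence lines are accumulated until
#' the `+` separator line; quality characters are then accumulated
#' until their count equals the sequence length. Because the guard is
#' the length, a quality line starting with `@` (a legal quality
#' character, ASCII 64) is never misread as the start of a new record.
#'
#' @param x FASTQ text or a file path.
#' @return A list of records, each a named list with `readid`,
#'   `spotid`, `sequence`, `quality` and `length`. The read id is the
#'   token after `@` up to the first whitespace; a `spot=<token>` in
#'   the remaining description becomes the spot id, otherwise the whole
#'   remainder does.
#' @seealso [fastq_to_bon()]
#' @export
parse_fastq <- function(x) {
  lines <- read_input_text(x, "FASTQ")
  n <- length(lines)
  while (n > 0L && !nzchar(lines[n])) n <- n - 1L  # trailing blank lines
  records <- vector("list", max(16L, n %/% 4L))
  nrec <- 0L
  i <- 1L
  while (i <= n) {
    line <- lines[i]
    if (!startsWith(line, "@")) {
      abort_format(sprintf(
        "line %d: expected a record header starting with '@', found '%s'",
        i, substr(line, 1L, 30L)))
    }
    hdr <- split_fastq_header(line)
    i <- i + 1L
    seq_parts <- character(0)
    while (i <= n && !startsWith(lines[i], "+")) {
      seq_parts <- c(seq_parts, lines[i])
      i <- i + 1L
    }
    if (i > n) {
      abort_format(sprintf("read '%s': missing '+' separator line",
                           hdr[["readid"]]))
    }
    sequence <- paste(seq_parts, collapse = "")
    slen <- nchar(sequence)
    i <- i + 1L  # past the '+' line
    qual_parts <- character(0)
    qlen <- 0L
    while (qlen < slen) {
      if (i > n) {
        abort_format(sprintf(
          "read '%s': quality truncated (%d of %d characters)",
          hdr[["readid"]], qlen, slen))
      }
      qual_parts <- c(qual_parts, lines[i])
      qlen <- qlen + nchar(lines[i])
      i <- i + 1L
    }
    if (qlen != slen) {
      abort_format(sprintf(
        "read '%s': quality length %d does not match sequence length %d",
        hdr[["readid"]], qlen, slen))
    }
    quality <- paste(qual_parts, collapse = "")
    if (grepl("[^\x21-\x7e]", quality, useBytes = TRUE)) {
      abort_format(sprintf(
        "read '%s': quality contains characters outside ASCII 33-126",
        hdr[["readid"]]))
    }
    nrec <- nrec + 1L
    records[[nrec]] <- list(readid = hdr[["readid"]],
                            spotid = spotid_from_desc(hdr[["desc"]]),
                            sequence = sequence,
                            quality = quality,
                            length = slen)
  }
  records[seq_len(nrec)]
}

#' Convert FASTQ to BON
#'
#' One BON object per read, with the keys `readid`, `spotid`,
#' `sequence`, `quality` and `length`. By default both the sequence and
#' the quality string are compressed, leaving the identifiers readable
#' mid-stream.
#'
#' @inheritParams tinyseq_to_bon
#' @param x FASTQ text or a file path.
#' @param compress Attribute names to compress (default sequence and
#'   quality).
#' @return A [bon_block()] (or `bon_stream` when chunked).
#' @export
fastq_to_bon <- function(x, compress = c("sequence", "quality"),
                         extras = list(), level = 6L, block_size = Inf) {
  chunk_blocks(parse_fastq(x), compress, extras, level, block_size)
}

#' Convert BON back to FASTQ
#'
#' Emits canonical 4-line records (bare `+` line, unwrapped sequence
#' and quality). Compressed blocks decode transparently. Records whose
#' stored `length` disagrees with the sequence or quality length are
#' refused.
#'
#' @param x A [bon_block()], `bon_stream`, or BON text/path.
#' @return FASTQ text (with trailing newline).
#' @export
bon_to_fastq <- function(x) {
  objects <- as_decoded_objects(x)
  if (!length(objects)) return("")
  lines <- vapply(objects, function(o) {
    slen <- nchar(o$sequence %||% "")
    qlen <- nchar(o$quality %||% "")
    stored <- o$length %||% slen
    if (slen != qlen || slen != stored) {
      abort_format(sprintf(
        "read '%s': length invariant violated (sequence %d, quality %d, stored %d)",
        o$readid %||% "?", slen, qlen, as.integer(stored)))
    }
    hdr <- if (!is.null(o$spotid) && nzchar(o$spotid)) {
      paste0("@", o$readid, " ", o$spotid)
    } else {
      paste0("@", o$readid)
    }
    paste(hdr, o$sequence, "+", o$quality, sep = "\n")
  }, character(1))
  paste0(paste(lines, collapse = "\n"), "\n")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- FASTA -----------------------------------------------------------------

wrap_text <- function(s, width) {
  if (width <= 0L || nchar(s) <= width) return(s)
  starts <- seq(1L, nchar(s), by = width)
  paste(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
        collapse = "\n")
}

#' Export a BON block as FASTA
#'
#' Convenience exporter: each object becomes one FASTA record with
#' header line `>accver defline` (falling back to `readid` or a
#' positional id) and the sequence wrapped at `wrap` columns.
#' Compressed sequences decode transparently. Objects without a
#' sequence are skipped; their count is returned in the `skipped`
#' attribute (with a warning).
#'
#' @param x A [bon_block()], `bon_stream`, or BON text/path.
#' @param wrap Sequence line width; 0 emits unwrapped single lines.
#' @return FASTA text with attribute `skipped`.
#' @export
bon_to_fasta <- function(x, wrap = 70L) {
  objects <- as_decoded_objects(x)
  skipped <- 0L
  recs <- character(0)
  for (i in seq_along(objects)) {
    o <- objects[[i]]
    if (is.null(o$sequence)) {
      skipped <- skipped + 1L
      next
    }
    id <- o$accver %||% o$readid %||% sprintf("record_%d", i)
    hdr <- if (!is.null(o$defline) && nzchar(o$defline)) {
      paste0(">", id, " ", o$defline)
    } else paste0(">", id)
    recs <- c(recs, paste0(hdr, "\n", wrap_text(o$sequence, wrap)))
  }
  if (skipped) {
    warning(sprintf("%d object(s) without a sequence were skipped", skipped))
  }
  out <- if (length(recs)) paste0(paste(recs, collapse = "\n"), "\n") else ""
  attr(out, "skipped") <- skipped
  out
}
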
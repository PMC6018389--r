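#' @useDynLib bon, .registration = TRUE
#' @importFrom jsonlite parse_json base64_enc base64_dec
#' @importFrom xml2 read_xml xml_find_all xml_find_first xml_text xml_attr
#' @importFrom ape read.tree write.tree rtree
#' @importFrom stats setNames runif reorder
#' @keywords internal
"_PACKAGE"

B64_RE <- "^[A-Za-z0-9+/]*={0,2}$"

#' Base64 encode/decode without line wrapping
#'
#' Standard-alphabet base64 (RFC 3548, `=` padding) as used to wrap
#' compressed BON values: a single string with no newlines. Encoding n
#' bytes yields `4 * ceiling(n/3)` characters, i.e. about 33% overhead
#' -- the price BON pays for keeping binary zlib streams inside plain
#' JSON text.
#'
#' @param raw A raw vector.
#' @return `bon_base64_encode`: a single base64 string.
#' @export
bon_base64_encode <- function(raw) {
  # jsonlite line-wraps at 76 columns; BON stores no newlines
  gsub("\n", "", jsonlite::base64_enc(raw), fixed = TRUE)
}

#' @rdname bon_base64_encode
#' @param txt A single base64 string (strict: standard alphabet,
#'   padded, no newlines).
#' @param attribute Optional attribute name carried into error
#'   conditions.
#' @return `bon_base64_decode`: the decoded raw vector.
#' @export
bon_base64_decode <- function(txt, attribute = NULL) {
  if (!is.character(txt) || length(txt) != 1L || is.na(txt)) {
    abort_base64("base64 input must be a single string",
                 attribute = attribute)
  }
  if (!grepl(B64_RE, txt) || nchar(txt) %% 4L != 0L) {
    abort_base64(
      sprintf("invalid base64 text%s",
              if (is.null(attribute)) "" else
                sprintf(" in attribute '%s'", attribute)),
      attribute = attribute)
  }
  jsonlite::base64_dec(txt)
}

#' Compress a value into a base64-wrapped zlib string
#'
#' The BON codec for selectively compressed attribute values: the input
#' bytes are compressed as a zlib (RFC 1950) stream, by default at
#' compression level 6, and the stream is encoded as standard base64
#' (RFC 3548 alphabet with `=` padding, no line wrapping). Character
#' input is encoded as UTF-8 first. The result is plain text that can
#' sit inside a JSON string: base64 costs about 33% over the raw stream
#' but keeps the container printable.
#'
#' @param x A raw vector, or a length-1 character vector (taken as
#'   UTF-8 text).
#' @param level zlib compression level, 1-9. Default 6.
#' @return A single base64 string with no newlines.
#' @seealso [bon_decompress_value()]
#' @examples
#' bon_compress_value("ACGTACGTACGT")
#' bon_decompress_value(bon_compress_value("ACGT"), as = "text")
#' @export
bon_compress_value <- function(x, level = 6L) {
  if (is.character(x)) {
    if (length(x) != 1L || is.na(x)) {
      abort_validate("text input to the codec must be a single string")
    }
    x <- charToRaw(enc2utf8(x))
  }
  if (!is.raw(x)) abort_validate("input must be raw bytes or a string")
  bon_base64_encode(.Call(C_zlib_compress, x, as.integer(level)))
}

#' Decompress a base64-wrapped zlib string
#'
#' Inverse of [bon_compress_value()]. The two failure stages are
#' distinguishable by condition class: text that is not valid base64
#' signals `bon_base64_error`; valid base64 that does not wrap a valid
#' zlib stream signals `bon_zlib_error`.
#'
#' @param x A single base64 string.
#' @param as `"raw"` (default) returns the decompressed bytes,
#'   `"text"` converts them to a UTF-8 string.
#' @param attribute Optional attribute name carried into error
#'   conditions, used by block decoding to report which attribute
#'   failed.
#' @return Raw vector or character scalar.
#' @export
bon_decompress_value <- function(x, as = c("raw", "text"), attribute = NULL) {
  as <- match.arg(as)
  z <- bon_base64_decode(x, attribute = attribute)
  out <- tryCatch(
    .Call(C_zlib_decompress, z),
    error = function(e) {
      abort_zlib(
        sprintf("invalid zlib stream%s: %s",
                if (is.null(attribute)) "" else
                  sprintf(" in attribute '%s'", attribute),
                conditionMessage(e)),
        attribute = attribute)
    }
  )
  if (as == "text") {
    out <- rawToChar(out)
    Encoding(out) <- "UTF-8"
  }
  out
}

# ---- header ----------------------------------------------------------------

#' Construct a BON header
#'
#' A header is the JSON object that precedes every payload. It has two
#' mandatory attributes: `size`, the number of top-level objects in the
#' payload (nested objects are not counted), and `data`, a map from
#' attribute name to a compression flag -- 1 for zlib+base64 compressed
#' values, 0 for plain values. Any further entries (`extras`) are free
#' metadata that stays readable while streaming.
#'
#' @param size Non-negative integer object count.
#' @param data Named list or vector of 0/1 compression flags.
#' @param extras Named list of additional header metadata.
#' @return An object of class `bon_header`.
#' @examples
#' bon_header(2, data = c(defline = 0, sequence = 1))
#' @export
bon_header <- function(size, data = list(), extras = list()) {
  size <- as.integer(size)
  if (length(size) != 1L || is.na(size) || size < 0L) {
    abort_validate("header size must be a single non-negative integer")
  }
  data <- as.list(data)
  if (length(data)) {
    nm <- names(data)
    if (is.null(nm) || anyNA(nm) || any(!nzchar(nm))) {
      abort_validate("every entry in header 'data' must have a non-empty name")
    }
    if (anyDuplicated(nm)) {
      abort_validate("attribute names in header 'data' must be unique")
    }
    flags <- vapply(data, function(f) as.integer(f)[1L], integer(1))
    if (anyNA(flags) || !all(flags %in% c(0L, 1L))) {
      abort_validate("compression flags must be exactly 0 or 1")
    }
    data <- as.list(flags)
    names(data) <- nm
  }
  extras <- as.list(extras)
  if (length(extras) &&
      (is.null(names(extras)) || any(!nzchar(names(extras))))) {
    abort_validate("header extras must be named")
  }
  structure(list(size = size, data = data, extras = extras),
            class = "bon_header")
}

# Reconstruct a header from a parsed JSON object (list).
as_bon_header <- function(x, block = NULL) {
  if (!is.list(x) || is.null(x$size) || is.null(x[["data"]])) {
    abort_validate(
      sprintf("header%s must carry the mandatory 'size' and 'data' attributes",
              if (is.null(block)) "" else sprintf(" of block %d", block)),
      block = block)
  }
  extras <- x[setdiff(names(x), c("size", "data"))]
  tryCatch(
    bon_header(x$size, x[["data"]], extras),
    bon_error = function(e) {
      bon_abort(sprintf("%s%s", conditionMessage(e),
                        if (is.null(block)) "" else
                          sprintf(" (block %d)", block)),
                class(e)[1L], block = block)
    })
}

#' @export
print.bon_header <- function(x, ...) {
  cat(sprintf("<bon_header> size=%d\n", x$size))
  if (length(x$data)) {
    flags <- unlist(x$data)
    cat("  data:", paste0(names(flags), "=", flags, collapse = " "), "\n")
  } else {
    cat("  data: (empty)\n")
  }
  if (length(x$extras)) {
    cat("  extras:", paste(names(x$extras), collapse = ", "), "\n")
  }
  invisible(x)
}

# ---- objects ---------------------------------------------------------------

flags_of <- function(record) {
  f <- attr(record, "bon_flags", exact = TRUE)
  if (is.null(f)) character(0) else f
}

#' Compress selected attributes of a record
#'
#' Replaces the values of the attributes named in `compress` with their
#' zlib+base64 encoding. Attribute names are never compressed, only
#' values. String values are compressed as UTF-8 text; nested
#' structures (e.g. a phylogenetic tree graph) are first serialized as
#' compact JSON so decoding can re-parse them. Names in `compress` that
#' the record does not carry are ignored (absence is legal).
#' Re-compressing an attribute that is already compressed is refused.
#'
#' @param record Named list: one biological object.
#' @param compress Character vector of attribute names to compress.
#' @param level zlib compression level.
#' @return The record with compressed values; the set of keys is
#'   unchanged.
#' @seealso [bon_decode_object()], [bon_block()]
#' @export
bon_encode_object <- function(record, compress = character(), level = 6L) {
  if (!is.list(record)) abort_validate("a BON object must be a named list")
  compress <- as.character(compress)
  if (any(!nzchar(compress))) {
    abort_validate("compression spec names must be non-empty")
  }
  hit <- intersect(compress, names(record))
  if (!length(hit)) return(record)
  already <- intersect(hit, flags_of(record))
  if (length(already)) {
    abort_validate(sprintf(
      "attribute '%s' is already compressed; refusing double compression",
      already[1L]), attribute = already[1L])
  }
  for (nm in hit) {
    v <- record[[nm]]
    txt <- if (is.character(v) && length(v) == 1L) v else json_value(v)
    record[[nm]] <- bon_compress_value(txt, level = level)
  }
  attr(record, "bon_flags") <- union(flags_of(record), hit)
  record
}

#' Decompress the flagged attributes of a record
#'
#' Inverse of [bon_encode_object()]: every attribute flagged 1 in the
#' governing header is base64-decoded and zlib-decompressed. Values
#' whose decompressed text starts with `{` or `[` are re-parsed as JSON
#' (they were nested structures); anything else is kept as a plain
#' string.
#'
#' @param record Named list, typically as parsed from a payload.
#' @param header A [bon_header()] whose `data` flags govern the record.
#' @param object Optional object index carried into error conditions.
#' @return The decoded record.
#' @export
bon_decode_object <- function(record, header, object = NULL) {
  stopifnot(inherits(header, "bon_header"))
  flags <- header$data
  for (nm in names(flags)) {
    if (flags[[nm]] != 1L || is.null(record[[nm]])) next
    txt <- withCallingHandlers(
      bon_decompress_value(record[[nm]], as = "text", attribute = nm),
      bon_error = function(e) {
        if (!is.null(object) && is.null(e$object)) {
          bon_abort(sprintf("%s (object %d)", conditionMessage(e), object),
                    class(e)[1L], attribute = nm, object = object)
        }
      })
    # values that were nested structures were compressed as compact
    # JSON; re-parse when the text is valid JSON structure, otherwise
    # keep it as a plain string (a quality string may start with '{')
    record[[nm]] <- if (substr(txt, 1L, 1L) %in% c("{", "[")) {
      tryCatch(jsonlite::parse_json(txt, simplifyVector = FALSE),
               error = function(e) txt)
    } else txt
  }
  attr(record, "bon_flags") <- NULL
  record
}

# ---- blocks ----------------------------------------------------------------

#' Build the header describing a payload
#'
#' `size` is the number of top-level payload objects (nested objects
#' are excluded); `data` enumerates every attribute name occurring in
#' any payload object, in order of first appearance, flagged 1 when
#' named in `compress` and 0 otherwise, so the header is a full
#' self-description of the payload. `extras` are appended verbatim.
#'
#' @param payload List of records (named lists).
#' @param compress Character vector of attribute names to flag.
#' @param extras Named list of extra header metadata.
#' @return A [bon_header()].
#' @examples
#' recs <- list(list(defline = "d1", sequence = "ACGT"),
#'              list(defline = "d2", sequence = "GGCC"))
#' bon_build_header(recs, compress = "sequence")
#' @export
bon_build_header <- function(payload, compress = character(), extras = list()) {
  keys <- unique(unlist(lapply(payload, names), use.names = FALSE))
  flags <- as.list(as.integer(keys %in% compress))
  names(flags) <- keys
  bon_header(length(payload), flags, extras)
}

#' Construct a BON block
#'
#' A block is one header plus its payload: the unit of concatenation in
#' a BON stream. `bon_block()` wraps already-consistent parts;
#' [bon_encode_block()] is the convenience constructor that compresses
#' and builds the header in one step.
#'
#' @param header A [bon_header()].
#' @param payload List of records (named lists).
#' @param validate Check the header/payload invariants (default TRUE).
#' @return An object of class `bon_block`.
#' @export
bon_block <- function(header, payload = list(), validate = TRUE) {
  if (!inherits(header, "bon_header")) header <- as_bon_header(header)
  if (!is.list(payload)) abort_validate("payload must be a list of objects")
  block <- structure(list(header = header, payload = payload),
                     class = "bon_block")
  if (validate) validate_block(block)
  block
}

validate_block <- function(block, index = NULL) {
  h <- block$header
  at <- if (is.null(index)) "" else sprintf(" (block %d)", index)
  if (h$size != length(block$payload)) {
    abort_validate(sprintf(
      "header size %d does not match payload length %d%s",
      h$size, length(block$payload), at), block = index)
  }
  compressed <- names(h$data)[unlist(h$data) == 1L]
  for (i in seq_along(block$payload)) {
    obj <- block$payload[[i]]
    if (!is.list(obj)) {
      abort_validate(sprintf("payload element %d is not an object%s", i, at),
                     block = index, object = i)
    }
    for (nm in intersect(compressed, names(obj))) {
      v <- obj[[nm]]
      if (!(is.character(v) && length(v) == 1L && grepl(B64_RE, v))) {
        abort_validate(sprintf(
          "attribute '%s' of object %d is flagged compressed but is not base64 text%s",
          nm, i, at), block = index, object = i, attribute = nm)
      }
    }
  }
  invisible(block)
}

#' Encode records into a complete BON block
#'
#' @param payload List of records (named lists).
#' @param compress Attribute names whose values are compressed
#'   (zlib level `level`, base64-wrapped).
#' @param extras Named list of extra header metadata.
#' @param level zlib compression level, default 6.
#' @return A [bon_block()].
#' @examples
#' b <- bon_encode_block(
#'   list(list(defline = "d", sequence = "ACGTACGT")),
#'   compress = "sequence")
#' cat(bon_serialize(b))
#' @export
bon_encode_block <- function(payload, compress = character(),
                             extras = list(), level = 6L) {
  encoded <- lapply(payload, bon_encode_object, compress = compress,
                    level = level)
  header <- bon_build_header(payload, compress = compress, extras = extras)
  bon_block(header, encoded, validate = FALSE)
}

#' Decode every object of a block
#'
#' @param block A [bon_block()].
#' @return The block with all flagged attributes decompressed and the
#'   header flags reset to 0.
#' @export
bon_decode_block <- function(block) {
  stopifnot(inherits(block, "bon_block"))
  h <- block$header
  payload <- lapply(seq_along(block$payload), function(i) {
    bon_decode_object(block$payload[[i]], h, object = i)
  })
  data <- h$data
  data[] <- list(0L)
  bon_block(bon_header(h$size, data, h$extras), payload, validate = FALSE)
}

#' @export
print.bon_block <- function(x, ...) {
  cat(sprintf("<bon_block> %d object(s)\n", length(x$payload)))
  print(x$header)
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

serialize_header <- function(h) {
  data <- if (length(h$data)) {
    paste0("\"", json_escape(names(h$data)), "\":",
           vapply(h$data, function(f) as.character(f), character(1)),
           collapse = ",")
  } else ""
  extras <- if (length(h$extras)) {
    paste0(",", paste0("\"", json_escape(names(h$extras)), "\":",
                       vapply(h$extras, json_value, character(1)),
                       collapse = ","))
  } else ""
  paste0("{\"size\":", h$size, ",\"data\":{", data, "}", extras, "}")
}

#' Serialize a block to BON text
#'
#' Emits the compact JSON of the header immediately followed by the
#' compact JSON of the payload array: no separator, no whitespace, no
#' newlines. The header/payload junction is the two-byte signal `}[`,
#' which is not valid JSON and therefore marks the boundary; each of
#' the two parts is independently valid JSON. Header keys are emitted
#' in the fixed order `size`, `data`, then extras in insertion order,
#' so output is byte-deterministic.
#'
#' @param block A [bon_block()], or a list of blocks (a stream), in
#'   which case blocks are concatenated and consecutive blocks meet at
#'   the `]{` signal.
#' @return A single string of BON text.
#' @seealso [bon_scan()], [bon_write()]
#' @examples
#' bon_serialize(bon_block(bon_header(0)))
#' @export
bon_serialize <- function(block) {
  if (inherits(block, "bon_block")) {
    validate_block(block)
    payload <- if (length(block$payload)) {
      paste0("[", paste0(vapply(block$payload, json_value, character(1)),
                         collapse = ","), "]")
    } else "[]"
    return(paste0(serialize_header(block$header), payload))
  }
  if (is.list(block)) {
    return(paste0(vapply(block, bon_serialize, character(1)), collapse = ""))
  }
  abort_validate("expected a bon_block or a list of bon_blocks")
}

#' Write BON text to a file or connection
#'
#' Writes the serialized stream byte-for-byte (no trailing newline is
#' added: BON stores no newlines).
#'
#' @param block A [bon_block()], list of blocks, or already-serialized
#'   BON text.
#' @param path File path or writable connection; `"-"` writes to
#'   standard output.
#' @return Invisibly, the number of bytes written.
#' @export
bon_write <- function(block, path) {
  txt <- if (is.character(block) && length(block) == 1L) block
         else bon_serialize(block)
  bytes <- charToRaw(txt)
  if (identical(path, "-")) {
    con <- stdout()
    writeLines(txt, con, sep = "")
  } else if (inherits(path, "connection")) {
    writeBin(bytes, path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(bytes, con)
  }
  invisible(length(bytes))
}
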
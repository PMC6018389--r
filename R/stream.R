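# Streaming reader.
#
# Boundary detection is a JSON-aware byte scanner (string/escape/
# brace-depth state carried across chunk edges, implemented in C), not
# a substring split on "}[": the signal bytes inside a string value can
# never cause a mis-split. Memory use is bounded by one unit (header or
# payload object) plus one read chunk.

# Resolve scanner input to either in-memory bytes or a connection.
open_stream_input <- function(x) {
  if (is.raw(x)) return(list(bytes = x))
  if (inherits(x, "connection")) {
    if (!isOpen(x)) {
      open(x, "rb")
      return(list(con = x, close = TRUE))
    }
    return(list(con = x, close = FALSE))
  }
  if (is.character(x) && length(x) == 1L) {
    if (startsWith(x, "{") || x == "") return(list(bytes = charToRaw(x)))
    if (identical(x, "-")) return(list(con = file("stdin", "rb"), close = TRUE))
    if (!file.exists(x)) {
      abort_parse(sprintf(
        "input '%s' is neither BON text (expected leading '{') nor an existing file",
        substr(x, 1, 40)))
    }
    return(list(con = file(x, "rb"), close = TRUE))
  }
  abort_validate("stream input must be text, raw bytes, a path or a connection")
}

scan_err_msg <- function(err, char, pos, block) {
  what <- if (char >= 32L && char < 127L) sprintf("'%s'", intToUtf8(char))
          else sprintf("byte 0x%02x", char)
  msg <- switch(as.character(err),
    "1" = sprintf("expected '{' starting a header but found %s", what),
    "2" = sprintf("header must be followed immediately by '[' but found %s (the '}[' junction admits no separator)", what),
    "3" = sprintf("payload elements must be JSON objects; found %s", what),
    sprintf("scanner error %d", err))
  sprintf("%s at byte %d (after %d complete block%s)", msg, pos, block,
          if (block == 1L) "" else "s")
}

# Core chunked driver. Callbacks receive raw text spans:
#   on_header(txt, block_index)
#   on_object(txt, block_index, object_index)   (NULL skips extraction)
#   on_block_end(block_index, n_objects)
# Indices are 1-based. Returns c(blocks =, objects =).
scan_driver <- function(x, on_header = NULL, on_object = NULL,
                        on_block_end = NULL, chunk_size = 65536L,
                        tolerate_trailing_newline = TRUE) {
  input <- open_stream_input(x)
  if (!is.null(input$con) && isTRUE(input$close)) on.exit(close(input$con))

  state <- c(0L, 0L, 0L, 0L, -1L, 0L)
  held <- raw(0)       # unconsumed bytes
  held_base <- 0L      # stream offset of held[1]
  blocks_done <- 0L
  objs_in_block <- 0L
  total_objects <- 0L
  pending_nl <- FALSE  # saw trailing newline; nothing else may follow

  feed <- function(chunk) {
    if (pending_nl) {
      extra <- chunk[!chunk %in% as.raw(c(10L, 13L))]
      if (length(extra) || !tolerate_trailing_newline) {
        abort_parse(scan_err_msg(1L, as.integer(chunk[1L]), state[6L],
                                 blocks_done))
      }
      return(invisible())
    }
    res <- .Call(C_bon_scan_chunk, chunk, state)
    held <<- c(held, chunk)
    ev <- res$events
    if (length(ev)) {
      k <- length(ev) / 3L
      for (j in seq_len(k)) {
        type <- ev[3L * j - 2L]
        a <- ev[3L * j - 1L]
        b <- ev[3L * j]
        if (type == 1L) {
          if (!is.null(on_header)) {
            on_header(rawToChar(held[(a - held_base + 1L):(b - held_base)]),
                      blocks_done + 1L)
          }
          objs_in_block <<- 0L
        } else if (type == 2L) {
          objs_in_block <<- objs_in_block + 1L
          total_objects <<- total_objects + 1L
          if (!is.null(on_object)) {
            on_object(rawToChar(held[(a - held_base + 1L):(b - held_base)]),
                      blocks_done + 1L, objs_in_block)
          }
        } else {
          blocks_done <<- blocks_done + 1L
          if (!is.null(on_block_end)) on_block_end(blocks_done, objs_in_block)
        }
      }
    }
    state <<- res$state
    if (res$err != 0L) {
      if (res$err == 1L && res$err_char %in% c(10L, 13L) &&
          tolerate_trailing_newline) {
        # allowed only if nothing but newline bytes remain
        rest <- held[(state[6L] - held_base + 1L):length(held)]
        if (all(rest %in% as.raw(c(10L, 13L)))) {
          pending_nl <<- TRUE
          held <<- raw(0)
          return(invisible())
        }
      }
      abort_parse(scan_err_msg(res$err, res$err_char, state[6L], blocks_done),
                  offset = state[6L], block = blocks_done)
    }
    # drop consumed bytes: keep from the open unit (if any), else frontier
    keep_from <- if (state[5L] >= 0L) state[5L] else state[6L]
    drop <- keep_from - held_base
    if (drop > 0L) {
      held <<- held[-seq_len(drop)]
      held_base <<- keep_from
    }
    invisible()
  }

  if (!is.null(input$bytes)) {
    if (length(input$bytes)) feed(input$bytes)
  } else {
    repeat {
      chunk <- readBin(input$con, what = "raw", n = chunk_size)
      if (!length(chunk)) break
      feed(chunk)
    }
  }

  if (!pending_nl && (state[1L] != 0L || state[2L] != 0L || state[3L] != 0L)) {
    abort_parse(sprintf(
      "truncated BON stream: ended mid-block after %d complete block%s at byte %d",
      blocks_done, if (blocks_done == 1L) "" else "s", state[6L]),
      offset = state[6L], block = blocks_done)
  }
  c(blocks = blocks_done, objects = total_objects)
}

#' Scan a BON stream into blocks
#'
#' Splits concatenated BON text at the `}[` and `]{` signals using a
#' JSON-aware scanner (so the signal characters inside string values
#' cannot cause mis-splits), parses each header and payload object as
#' strict standalone JSON, and validates that every header's `size`
#' equals its payload's object count.
#'
#' @param x BON text, raw bytes, a file path, a connection, or `"-"`
#'   for standard input.
#' @param decode Decompress flagged attributes (default FALSE: objects
#'   keep their base64 values verbatim).
#' @param chunk_size Read buffer in bytes (default 64 KiB); boundaries
#'   may straddle chunks.
#' @param tolerate_trailing_newline Accept newline bytes at end of
#'   stream (as added by text editors); anything else between or after
#'   blocks is rejected.
#' @return A list of [bon_block()] objects, classed `bon_stream`.
#' @seealso [bon_objects()], [bon_peek_headers()]
#' @examples
#' s <- bon_serialize(bon_encode_block(
#'   list(list(id = "a", sequence = "ACGT")), compress = "sequence"))
#' bon_scan(s, decode = TRUE)[[1]]$payload[[1]]$sequence
#' @export
bon_scan <- function(x, decode = FALSE, chunk_size = 65536L,
                     tolerate_trailing_newline = TRUE) {
  blocks <- list()
  cur_header <- NULL
  cur_payload <- list()
  scan_driver(
    x,
    on_header = function(txt, bi) {
      cur_header <<- as_bon_header(json_parse(txt, "BON header"), block = bi)
      cur_payload <<- list()
    },
    on_object = function(txt, bi, oi) {
      cur_payload[[oi]] <<- json_parse(txt, sprintf("payload object %d", oi))
    },
    on_block_end = function(bi, nobj) {
      if (cur_header$size != nobj) {
        abort_validate(sprintf(
          "block %d: header announces size %d but payload has %d object(s)",
          bi, cur_header$size, nobj), block = bi)
      }
      b <- bon_block(cur_header, cur_payload, validate = FALSE)
      if (decode) b <- bon_decode_block(b)
      blocks[[bi]] <<- b
    },
    chunk_size = chunk_size,
    tolerate_trailing_newline = tolerate_trailing_newline)
  structure(blocks, class = "bon_stream")
}

#' @export
print.bon_stream <- function(x, ...) {
  cat(sprintf("<bon_stream> %d block(s), %d object(s)\n", length(x),
              sum(vapply(x, function(b) length(b$payload), integer(1)))))
  invisible(x)
}

#' Iterate over the objects of a BON stream
#'
#' Yields payload objects one at a time in stream order; memory use is
#' bounded by one object plus scanner state, never the whole stream.
#' With `decode = TRUE` flagged attributes are decompressed through the
#' governing block header; codec failures carry the block and object
#' index.
#'
#' @inheritParams bon_scan
#' @param callback Optional `function(object, block, index)` invoked
#'   per object (streaming mode, nothing accumulated). When `NULL` the
#'   objects are returned as a list with an integer attribute `block`
#'   giving each object's 1-based block index.
#' @return The list of objects (invisibly, when `callback` is given).
#' @export
bon_objects <- function(x, decode = TRUE, callback = NULL,
                        chunk_size = 65536L) {
  out <- list()
  idx <- integer(0)
  cur_header <- NULL
  accumulate <- is.null(callback)
  scan_driver(
    x,
    on_header = function(txt, bi) {
      cur_header <<- as_bon_header(json_parse(txt, "BON header"), block = bi)
    },
    on_object = function(txt, bi, oi) {
      obj <- json_parse(txt, sprintf("payload object %d", oi))
      if (decode) {
        obj <- withCallingHandlers(
          bon_decode_object(obj, cur_header, object = oi),
          bon_error = function(e) {
            if (is.null(e$block)) {
              bon_abort(sprintf("%s (block %d)", conditionMessage(e), bi),
                        class(e)[1L], block = bi, object = oi,
                        attribute = e$attribute)
            }
          })
      }
      if (accumulate) {
        out[[length(out) + 1L]] <<- obj
        idx[[length(idx) + 1L]] <<- bi
      } else {
        callback(obj, bi, oi)
      }
    },
    chunk_size = chunk_size)
  if (accumulate) {
    attr(out, "block") <- idx
    out
  } else {
    invisible(out)
  }
}

#' Read only the headers of a BON stream
#'
#' Skips payload content entirely (nothing is decompressed or parsed
#' beyond locating boundaries), so metadata can be screened while the
#' data part of a stream is still arriving.
#'
#' @inheritParams bon_scan
#' @return List of [bon_header()] objects.
#' @export
bon_peek_headers <- function(x, chunk_size = 65536L) {
  headers <- list()
  scan_driver(
    x,
    on_header = function(txt, bi) {
      headers[[bi]] <<- as_bon_header(json_parse(txt, "BON header"),
                                      block = bi)
    },
    chunk_size = chunk_size)
  headers
}

#' Validate a BON stream
#'
#' Runs the scanner with full validation: strict JSON parsing of every
#' header and object, header/payload size agreement, flag values, and
#' base64 well-formedness of compressed attributes. With
#' `decode = TRUE` compressed values are additionally decompressed.
#'
#' @inheritParams bon_scan
#' @return Invisibly, a named integer vector `c(blocks=, objects=)`.
#' @export
bon_validate <- function(x, decode = FALSE, chunk_size = 65536L) {
  cur_header <- NULL
  counts <- scan_driver(
    x,
    on_header = function(txt, bi) {
      cur_header <<- as_bon_header(json_parse(txt, "BON header"), block = bi)
    },
    on_object = function(txt, bi, oi) {
      obj <- json_parse(txt, sprintf("payload object %d", oi))
      compressed <- names(cur_header$data)[unlist(cur_header$data) == 1L]
      for (nm in intersect(compressed, names(obj))) {
        v <- obj[[nm]]
        if (!(is.character(v) && length(v) == 1L && grepl(B64_RE, v))) {
          abort_validate(sprintf(
            "block %d object %d: attribute '%s' flagged compressed but not base64",
            bi, oi, nm), block = bi, object = oi, attribute = nm)
        }
        if (decode) bon_decompress_value(v, attribute = nm)
      }
      if (is.null(names(obj)) && length(obj)) {
        abort_validate(sprintf("block %d object %d is not a JSON object",
                               bi, oi), block = bi, object = oi)
      }
    },
    on_block_end = function(bi, nobj) {
      if (cur_header$size != nobj) {
        abort_validate(sprintf(
          "block %d: header announces size %d but payload has %d object(s)",
          bi, cur_header$size, nobj), block = bi)
      }
    },
    chunk_size = chunk_size)
  invisible(counts)
}
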
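# File-size and compression accounting.
#
# "Clutter" is every byte of a file not attributable to biological
# data or metadata: syntax, tags, keys. The data-to-file ratio
# (data_bytes / file_bytes) quantifies it; higher means more data,
# less clutter. data_bytes counts the on-disk value bytes of the
# configured data attributes -- for XML, element text only (stripped of
# line breaks), never tag-attribute values; for compressed BON, the
# base64 text as stored, which is why the ratio declines as compressed
# values shrink.

default_data_keys <- function(format) {
  switch(format,
         bon = c("sequence", "quality", "tree"),
         fastq = c("sequence", "quality"),
         tinyseq = "sequence",
         fasta = "sequence")
}

data_bytes_bon <- function(file, data_keys) {
  total <- 0
  bon_objects(file, decode = FALSE, callback = function(obj, bi, oi) {
    for (nm in intersect(data_keys, names(obj))) {
      v <- obj[[nm]]
      total <<- total + if (is.character(v)) {
        sum(nchar(v, type = "bytes"))
      } else {
        nchar(json_value(v), type = "bytes")
      }
    }
  })
  total
}

data_bytes_fastq <- function(file, data_keys) {
  recs <- parse_fastq(file)
  sum(vapply(recs, function(r) {
    sum(vapply(intersect(data_keys, names(r)), function(nm) {
      v <- r[[nm]]
      if (is.character(v)) nchar(v, type = "bytes") else 0L
    }, integer(1)))
  }, numeric(1)))
}

data_bytes_tinyseq <- function(file, data_keys) {
  doc <- xml2::read_xml(file)
  sum(vapply(data_keys, function(key) {
    txt <- xml2::xml_text(
      xml2::xml_find_all(doc, sprintf("//TSeq_%s", key)))
    sum(nchar(gsub("[\r\n ]", "", txt), type = "bytes"))
  }, numeric(1)))
}

data_bytes_fasta <- function(file, data_keys) {
  lines <- read_input_text(file, "FASTA")
  sum(nchar(lines[!startsWith(lines, ">")], type = "bytes"))
}

#' Measure file size and data-to-file ratio
#'
#' Byte-exact accounting for one file: total size, the bytes
#' attributable to biological data values (the configured `data_keys`,
#' in their on-disk representation), and their ratio. For the
#' `gzip_whole` variant the file is compressed whole at level 6 (the
#' shell pipeline `gzip -c -6 file | wc -c`) and the data ratio is
#' undefined.
#'
#' @param file Path to the file to measure.
#' @param variant One of `"source"`, `"bon_uncompressed"`,
#'   `"bon_compressed"`, `"gzip_whole"` -- a label recording which
#'   representation the file holds.
#' @param format How to locate data values: `"bon"`, `"fastq"`,
#'   `"tinyseq"` or `"fasta"`. BON variants imply `"bon"`.
#' @param data_keys Attribute names counted as biological data;
#'   defaults depend on `format` (sequence/quality/tree).
#' @param gzip_level Compression level for `gzip_whole`.
#' @return A `bon_size_report`: list with `file`, `variant`,
#'   `file_bytes`, `data_bytes`, `ratio`.
#' @seealso [bon_gzip_size()], [bon_compare_sizes()]
#' @export
bon_measure <- function(file,
                        variant = c("source", "bon_uncompressed",
                                    "bon_compressed", "gzip_whole"),
                        format = c("bon", "fastq", "tinyseq", "fasta"),
                        data_keys = NULL, gzip_level = 6L) {
  variant <- match.arg(variant)
  format <- match.arg(format)
  if (!file.exists(file)) abort_validate(sprintf("no such file: %s", file))
  if (startsWith(variant, "bon_")) format <- "bon"
  data_keys <- data_keys %||% default_data_keys(format)

  if (variant == "gzip_whole") {
    fb <- bon_gzip_size(file, level = gzip_level)
    report <- list(file = file, variant = variant, file_bytes = fb,
                   data_bytes = NA_real_, ratio = NA_real_)
  } else {
    fb <- as.numeric(file.size(file))
    db <- switch(format,
                 bon = data_bytes_bon(file, data_keys),
                 fastq = data_bytes_fastq(file, data_keys),
                 tinyseq = data_bytes_tinyseq(file, data_keys),
                 fasta = data_bytes_fasta(file, data_keys))
    report <- list(file = file, variant = variant, file_bytes = fb,
                   data_bytes = as.numeric(db),
                   ratio = if (fb > 0) db / fb else NA_real_)
  }
  structure(report, class = "bon_size_report")
}

#' @export
print.bon_size_report <- function(x, ...) {
  cat(sprintf("<bon_size_report> %s (%s)\n", basename(x$file), x$variant))
  cat(sprintf("  file_bytes: %.0f  data_bytes: %s  ratio: %s\n",
              x$file_bytes,
              if (is.na(x$data_bytes)) "NA" else sprintf("%.0f", x$data_bytes),
              if (is.na(x$ratio)) "NA" else sprintf("%.4f", x$ratio)))
  invisible(x)
}

#' Whole-file gzip size
#'
#' Size in bytes of the file compressed whole with gzip at the given
#' level. The default method runs the gzip program itself (the
#' measurement is defined as the pipeline `gzip -c -6 file | wc -c`,
#' and GNU gzip's deflate output differs slightly in length from
#' zlib's at the same level). When no gzip binary is on the PATH a
#' zlib-based gzip container is sized instead (identical framing;
#' deflate length may differ by a fraction of a percent).
#'
#' @param file Path to the file.
#' @param level Compression level 1-9, default 6.
#' @param method `"auto"` (gzip binary if available), `"gzip"`, or
#'   `"zlib"`.
#' @return Number of bytes (numeric scalar).
#' @export
bon_gzip_size <- function(file, level = 6L, method = c("auto", "gzip", "zlib")) {
  method <- match.arg(method)
  if (!file.exists(file)) abort_validate(sprintf("no such file: %s", file))
  if (method == "auto") {
    method <- if (nzchar(Sys.which("gzip"))) "gzip" else "zlib"
  }
  if (method == "gzip") {
    out <- tempfile()
    on.exit(unlink(out))
    status <- system2("gzip", c("-c", paste0("-", as.integer(level)), file),
                      stdout = out)
    if (status != 0L) abort_validate("gzip invocation failed")
    return(as.numeric(file.size(out)))
  }
  bytes <- readBin(file, "raw", file.size(file))
  z <- .Call(C_zlib_compress, bytes, as.integer(level))
  deflate_len <- length(z) - 2L - 4L  # strip zlib header and adler32
  # gzip member: 10-byte header + FNAME (gzip -c FILE stores the name) +
  # deflate + crc32 + isize
  10 + nchar(basename(file), type = "bytes") + 1 + deflate_len + 8
}

#' Compare file sizes across format variants
#'
#' Tabulates [bon_measure()] reports for a set of variant files of the
#' same data set and the percent size change of each against the
#' source.
#'
#' @param files Named character vector mapping variant name (e.g.
#'   `source`, `bon_uncompressed`, `bon_compressed`) to a file path. A
#'   `gzip_whole` entry may name the *source* file; it is compressed
#'   whole for measurement.
#' @param formats Named character vector (same names) giving each
#'   file's format for data-byte counting; unnamed entries default to
#'   `"bon"` for BON variants and `source_format` otherwise.
#' @param source_format Format of the source file.
#' @param data_keys Attribute names counted as data.
#' @param source Name of the baseline variant (default `"source"`).
#' @return A `data.frame` with one row per variant: `variant`,
#'   `file_bytes`, `data_bytes`, `ratio`, `pct_vs_source`.
#' @export
bon_compare_sizes <- function(files, formats = NULL,
                              source_format = "fastq", data_keys = NULL,
                              source = "source") {
  stopifnot(is.character(files), !is.null(names(files)))
  rows <- lapply(names(files), function(v) {
    fmt <- formats[[v]] %||%
      if (startsWith(v, "bon")) "bon" else source_format
    variant <- if (v %in% c("source", "bon_uncompressed", "bon_compressed",
                            "gzip_whole")) v else "source"
    rep <- bon_measure(files[[v]], variant = variant, format = fmt,
                       data_keys = data_keys)
    data.frame(variant = v, file_bytes = rep$file_bytes,
               data_bytes = rep$data_bytes, ratio = rep$ratio,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (source %in% out$variant) {
    base <- out$file_bytes[out$variant == source][1L]
    out$pct_vs_source <- 100 * (out$file_bytes - base) / base
  } else {
    out$pct_vs_source <- NA_real_
  }
  out
}
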
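# Deterministic compact JSON emission.
#
# Serialized BON must be byte-stable (no whitespace, fixed header key
# order, full numeric precision, no newlines) so that file-size
# accounting is reproducible; jsonlite::toJSON boxes scalars, wraps
# lines and rounds doubles, so the writer lives here. Parsing stays on
# jsonlite's strict parser.

json_escape <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE, useBytes = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE, useBytes = TRUE)
  if (any(grepl("[\x01-\x1f]", s, useBytes = TRUE))) {
    s <- gsub("\n", "\\n", s, fixed = TRUE, useBytes = TRUE)
    s <- gsub("\r", "\\r", s, fixed = TRUE, useBytes = TRUE)
    s <- gsub("\t", "\\t", s, fixed = TRUE, useBytes = TRUE)
    s <- gsub("\b", "\\b", s, fixed = TRUE, useBytes = TRUE)
    s <- gsub("\f", "\\f", s, fixed = TRUE, useBytes = TRUE)
    # any remaining control characters
    s <- vapply(s, function(x) {
      if (!grepl("[\x01-\x1f]", x, useBytes = TRUE)) return(x)
      chars <- strsplit(x, "", fixed = TRUE)[[1L]]
      codes <- utf8ToInt(x)
      ctrl <- which(codes < 32L)
      chars[ctrl] <- sprintf("\\u%04x", codes[ctrl])
      paste(chars, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  s
}

json_num <- function(x) {
  if (!is.finite(x)) abort_validate("non-finite number cannot be serialized as JSON")
  if (x == floor(x) && abs(x) < 2^53) sprintf("%.0f", x)
  else formatC(x, digits = 15, format = "g", width = 1)
}

json_value <- function(x) {
  if (is.null(x)) return("null")
  if (is.list(x)) {
    nm <- names(x)
    if (length(x) == 0L) {
      return(if (is.null(nm)) "[]" else "{}")
    }
    if (!is.null(nm)) {
      if (anyNA(nm) || any(!nzchar(nm))) {
        abort_validate("object attribute names must be non-empty")
      }
      inner <- vapply(x, json_value, character(1), USE.NAMES = FALSE)
      return(paste0("{", paste0("\"", json_escape(nm), "\":", inner,
                                collapse = ","), "}"))
    }
    inner <- vapply(x, json_value, character(1), USE.NAMES = FALSE)
    return(paste0("[", paste0(inner, collapse = ","), "]"))
  }
  if (length(x) != 1L) {
    inner <- vapply(seq_along(x), function(i) json_value(x[[i]]),
                    character(1))
    return(paste0("[", paste0(inner, collapse = ","), "]"))
  }
  if (is.character(x)) {
    if (is.na(x)) abort_validate("NA string cannot be serialized as JSON")
    return(paste0("\"", json_escape(x), "\""))
  }
  if (is.logical(x)) {
    if (is.na(x)) abort_validate("NA cannot be serialized as JSON")
    return(if (x) "true" else "false")
  }
  if (is.numeric(x)) return(json_num(as.double(x)))
  abort_validate(sprintf("cannot serialize value of class '%s' as JSON",
                         class(x)[1L]))
}

json_parse <- function(txt, what = "JSON") {
  tryCatch(
    jsonlite::parse_json(txt, simplifyVector = FALSE),
    error = function(e) {
      abort_parse(sprintf("invalid %s: %s", what, conditionMessage(e)))
    }
  )
}
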
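# Classed conditions so callers can distinguish failure stages:
# base64 vs zlib codec failures, scanner/JSON parse errors, structural
# validation, and record-level format errors.

bon_abort <- function(msg, class, ..., call = NULL) {
  stop(errorCondition(msg, ..., class = c(class, "bon_error"), call = call))
}

abort_base64 <- function(msg, ...) bon_abort(msg, "bon_base64_error", ...)
abort_zlib <- function(msg, ...) bon_abort(msg, "bon_zlib_error", ...)
abort_parse <- function(msg, ...) bon_abort(msg, "bon_parse_error", ...)
abort_validate <- function(msg, ...) bon_abort(msg, "bon_validate_error", ...)
abort_format <- function(msg, ...) bon_abort(msg, "bon_format_error", ...)
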
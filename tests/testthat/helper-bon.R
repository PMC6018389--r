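# Shared fixtures for the suite: random records/blocks built in code,
# plus a structural normalizer so round-trip comparisons ignore the
# integer/double distinction JSON does not make.

`%||%` <- function(a, b) if (is.null(a)) b else a

random_string <- function(max_len = 20L, adversarial = FALSE) {
  pool <- c(LETTERS, letters, 0:9, " ", ".", "-", "_")
  s <- paste(sample(pool, sample.int(max_len, 1L), replace = TRUE),
             collapse = "")
  if (adversarial) {
    # inject the block signals, JSON syntax and escapes into values
    s <- paste0(sample(c("}[", "]{", "\"", "\\", "{", "[", "],"), 1L), s)
  }
  s
}

random_record <- function(adversarial = FALSE) {
  keys <- sample(c("defline", "sequence", "quality", "name", "score",
                   "note"), sample(2:5, 1L))
  rec <- lapply(keys, function(k) {
    switch(sample.int(3L, 1L),
           random_string(adversarial = adversarial),
           sample.int(1000L, 1L),
           stats::runif(1L))
  })
  names(rec) <- keys
  if (stats::runif(1) < 0.2) {
    rec$meta <- list(a = random_string(), b = sample.int(10L, 1L))
  }
  rec
}

random_block <- function(max_objects = 5L, adversarial = FALSE) {
  payload <- lapply(seq_len(sample.int(max_objects + 1L, 1L) - 1L),
                    function(i) random_record(adversarial = adversarial))
  keys <- unique(unlist(lapply(payload, names)))
  compressible <- Filter(function(k) {
    all(vapply(payload, function(o) {
      is.null(o[[k]]) || (is.character(o[[k]]) && length(o[[k]]) == 1L)
    }, logical(1)))
  }, setdiff(keys, "meta"))
  spec <- if (length(compressible)) {
    sample(compressible, sample.int(length(compressible) + 1L, 1L) - 1L)
  } else character(0)
  bon_encode_block(payload, compress = spec)
}

# recursively coerce numerics to double and drop attributes
# (an empty JSON object and an empty list compare equal)
normalize_tree <- function(x) {
  if (is.list(x)) {
    out <- lapply(x, normalize_tree)
    nm <- names(x)
    attributes(out) <- if (length(nm)) list(names = nm) else NULL
    return(out)
  }
  if (is.numeric(x)) return(as.double(x))
  x
}

expect_same_structure <- function(a, b) {
  expect_equal(normalize_tree(a), normalize_tree(b), tolerance = 1e-12)
}

block_payloads_equal <- function(a, b) {
  isTRUE(all.equal(normalize_tree(lapply(a, function(bl) bl$payload)),
                   normalize_tree(lapply(b, function(bl) bl$payload)),
                   tolerance = 1e-12))
}
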
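# Headers, object encoding, block serialization.

test_that("header invariants are enforced", {
  h <- bon_header(2, data = c(defline = 0, sequence = 1))
  expect_s3_class(h, "bon_header")
  expect_identical(h$size, 2L)
  expect_error(bon_header(-1), class = "bon_validate_error")
  expect_error(bon_header(1, data = c(sequence = 2)),
               class = "bon_validate_error")
  expect_error(bon_header(1, data = stats::setNames(list(1), "")),
               class = "bon_validate_error")
  expect_error(bon_header(1, data = c(a = 1, a = 0)),
               class = "bon_validate_error")
})

test_that("encode_object compresses named attributes and nothing else", {
  rec <- list(defline = "d", sequence = "ACGT")
  enc <- bon_encode_object(rec, compress = "sequence")
  expect_identical(enc$defline, "d")
  expect_identical(enc$sequence, bon_compress_value("ACGT"))
  expect_identical(names(enc), names(rec))
  # empty spec is the identity
  expect_identical(bon_encode_object(rec, character(0)), rec)
  # absent attributes in the compression spec are legal and ignored
  expect_identical(names(bon_encode_object(rec, c("sequence", "ghost"))),
                   names(rec))
})

test_that("double compression is refused", {
  rec <- bon_encode_object(list(sequence = "ACGT"), "sequence")
  expect_error(bon_encode_object(rec, "sequence"),
               class = "bon_validate_error")
})

test_that("decode_object inverts encode_object, including nested values", {
  tree <- list(vertices = list(list(id = "v0", name = "A")),
               edges = list())
  rec <- list(name = "t1", tree = tree, note = "plain")
  enc <- bon_encode_object(rec, compress = "tree")
  expect_type(enc$tree, "character")
  expect_match(enc$tree, "^[A-Za-z0-9+/=]+$")
  h <- bon_build_header(list(rec), compress = "tree")
  dec <- bon_decode_object(enc, h)
  expect_same_structure(dec, rec)
})

test_that("decode leaves records untouched when flags are 0", {
  rec <- list(sequence = "ACGT")
  h <- bon_header(1, data = c(sequence = 0))
  expect_identical(bon_decode_object(rec, h), rec)
})

test_that("decode failures carry the attribute and object index", {
  h <- bon_header(1, data = c(sequence = 1))
  err <- tryCatch(
    bon_decode_object(list(sequence = "AAAA"), h, object = 3L),
    error = identity)
  expect_s3_class(err, "bon_zlib_error")
  expect_identical(err$attribute, "sequence")
  expect_identical(err$object, 3L)
})

test_that("build_header counts top-level objects and enumerates all keys", {
  recs <- list(list(defline = "a", sequence = "ACGT"),
               list(defline = "b", sequence = "GG"))
  h <- bon_build_header(recs, compress = "sequence")
  expect_identical(h$size, 2L)
  expect_identical(h$data, list(defline = 0L, sequence = 1L))

  expect_identical(bon_build_header(list())$size, 0L)
  expect_length(bon_build_header(list())$data, 0L)

  # nested objects are not counted, and key sets may be heterogeneous
  recs2 <- list(list(tree = list(vertices = list(), edges = list())),
                list(tree = list(), label = "x"))
  h2 <- bon_build_header(recs2)
  expect_identical(h2$size, 2L)
  expect_identical(names(h2$data), c("tree", "label"))
})

test_that("serialization is compact, deterministic and newline-free", {
  expect_identical(bon_serialize(bon_block(bon_header(0))),
                   "{\"size\":0,\"data\":{}}[]")
  b <- bon_encode_block(
    list(list(defline = "has \"quotes\" and \\slashes\\",
              sequence = "ACGT", n = 3L),
         list(defline = "line\nbreak", sequence = "GG", x = 0.5)),
    compress = "sequence",
    extras = list(source = "unit test", version = 1L))
  s <- bon_serialize(b)
  expect_false(grepl("\n", s, fixed = TRUE))
  expect_identical(s, bon_serialize(b))  # byte-stable
  # header key order: size, data, extras in insertion order
  expect_match(s, "^\\{\"size\":2,\"data\":\\{.*\\},\"source\":\"unit test\",\"version\":1\\}\\[")
})

test_that("serialized blocks split at '}[' into two valid JSON parts", {
  b <- bon_encode_block(list(list(defline = "plain", sequence = "ACGT")),
                        compress = "sequence")
  s <- bon_serialize(b)
  at <- regexpr("}[", s, fixed = TRUE)
  header_txt <- substr(s, 1L, at)
  payload_txt <- substring(s, at + 1L)
  expect_silent(jsonlite::parse_json(header_txt))
  expect_silent(jsonlite::parse_json(payload_txt))
})

test_that("header/payload count mismatch refuses to serialize", {
  bad <- bon_block(bon_header(3), list(list(a = 1)), validate = FALSE)
  expect_error(bon_serialize(bad), class = "bon_validate_error")
})

test_that("streams concatenate blocks with the ']{' junction", {
  empty <- bon_block(bon_header(0))
  expect_identical(bon_serialize(list(empty, empty)),
                   "{\"size\":0,\"data\":{}}[]{\"size\":0,\"data\":{}}[]")
  one <- bon_encode_block(list(list(a = "x")))
  expect_identical(bon_serialize(list(one)), bon_serialize(one))
})

test_that("block round-trip preserves structure for random blocks", {
  set.seed(99)
  for (i in 1:25) {
    b <- random_block(adversarial = TRUE)
    s <- bon_serialize(b)
    expect_false(grepl("\n", s, fixed = TRUE))
    back <- bon_scan(s)
    expect_length(back, 1L)
    expect_identical(back[[1L]]$header$size, b$header$size)
    expect_same_structure(back[[1L]]$header$data, b$header$data)
    expect_same_structure(back[[1L]]$payload, b$payload)
  }
})
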
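# TinySeq XML, FASTQ and FASTA conversion.

test_that("a TinySeq entry maps to a BON object with the same naming scheme", {
  xml <- paste0(
    "<?xml version=\"1.0\"?>\n<TSeqSet>\n  <TSeq>\n",
    "    <TSeq_seqtype value=\"nucleotide\"/>\n",
    "    <TSeq_accver>NC_000001.1</TSeq_accver>\n",
    "    <TSeq_taxid>9606</TSeq_taxid>\n",
    "    <TSeq_orgname>Homo sapiens</TSeq_orgname>\n",
    "    <TSeq_defline>test entry</TSeq_defline>\n",
    "    <TSeq_length>4</TSeq_length>\n",
    "    <TSeq_sequence>ACGT</TSeq_sequence>\n",
    "  </TSeq>\n</TSeqSet>\n")
  b <- tinyseq_to_bon(xml)
  expect_identical(b$header$size, 1L)
  expect_identical(b$header$data$sequence, 1L)
  expect_true(all(unlist(b$header$data[names(b$header$data) != "sequence"]) == 0L))
  o <- bon_decode_block(b)$payload[[1L]]
  expect_identical(o$seqtype, "nucleotide")
  expect_identical(o$accver, "NC_000001.1")
  expect_identical(o$taxid, 9606L)
  expect_identical(o$length, 4L)
  expect_identical(o$sequence, "ACGT")
})

test_that("line breaks inside XML sequence text are removed", {
  xml <- gen_tinyseq_xml(2, seed = 3, wrap = 10)
  expect_match(xml, "[ACGT]{10}\n[ACGT]")  # wrapped on disk
  b <- tinyseq_to_bon(xml, compress = character(0))
  for (o in b$payload) {
    expect_false(grepl("\n", o$sequence, fixed = TRUE))
    expect_identical(nchar(o$sequence), o$length)
  }
})

test_that("TinySeq round-trips through BON and back", {
  xml <- gen_tinyseq_xml(5, seed = 11)
  b1 <- tinyseq_to_bon(xml)
  b2 <- tinyseq_to_bon(bon_to_tinyseq(b1))
  expect_same_structure(bon_decode_block(b1)$payload,
                        bon_decode_block(b2)$payload)
})

test_that("TinySeq error paths: missing sequence, malformed XML", {
  bad <- paste0("<TSeqSet><TSeq><TSeq_accver>X1.1</TSeq_accver>",
                "</TSeq></TSeqSet>")
  err <- tryCatch(tinyseq_to_bon(bad), error = identity)
  expect_s3_class(err, "bon_format_error")
  expect_match(conditionMessage(err), "X1.1")
  expect_error(tinyseq_to_bon("<TSeqSet><TSeq></TSeqSet>"),
               class = "bon_parse_error")
})

test_that("FASTQ quality lines starting with '@' are parsed unambiguously", {
  fq <- "@r1 spot=1\nACGT\n+\n@AAA\n"
  rec <- parse_fastq(fq)[[1L]]
  expect_identical(rec, list(readid = "r1", spotid = "1", sequence = "ACGT",
                             quality = "@AAA", length = 4L))
})

test_that("line wrapping does not change the parsed record", {
  flat <- "@r1 desc here\nACGTACGT\n+\nIIIIHHHH\n"
  wrapped <- "@r1 desc here\nACGT\nACGT\n+\nIIII\nHHHH\n"
  expect_identical(parse_fastq(flat), parse_fastq(wrapped))
  # the wrapped quality itself starts lines with '@'
  tricky <- "@r1\nACGTACGT\n+\n@@@@\n@@@@\n"
  expect_identical(parse_fastq(tricky)[[1L]]$quality, "@@@@@@@@")
})

test_that("FASTQ length and character-range violations are format errors", {
  err <- tryCatch(parse_fastq("@r9\nACGT\n+\nIIIII\n"), error = identity)
  expect_s3_class(err, "bon_format_error")
  expect_match(conditionMessage(err), "r9")
  expect_error(parse_fastq("@r1\nACGT\n+\nII\tI\n"),
               class = "bon_format_error")
  expect_error(parse_fastq("@r1\nACGT\n"), class = "bon_format_error")
})

test_that("FASTQ round-trips through BON with compressed sequence+quality", {
  fq <- gen_fastq(50, seed = 21)
  b <- fastq_to_bon(fq)
  expect_identical(b$header$data$sequence, 1L)
  expect_identical(b$header$data$quality, 1L)
  back <- bon_to_fastq(b)
  expect_same_structure(parse_fastq(back), parse_fastq(fq))
  expect_identical(bon_to_fastq(bon_block(bon_header(0))), "")
})

test_that("records failing the length invariant are refused on write", {
  b <- bon_encode_block(list(list(readid = "r1", spotid = "",
                                  sequence = "ACGT", quality = "II",
                                  length = 4L)))
  expect_error(bon_to_fastq(b), class = "bon_format_error")
})

test_that("the uncompressed BON excess over FASTQ is the per-record key overhead", {
  # all records identical in field widths and no JSON-escapable bytes
  # in the quality range, so the JSON overhead per record is a constant
  # determined by the key names and punctuation
  fq <- gen_fastq(20, seed = 8, length_range = c(100L, 100L),
                  quality_range = c(35L, 91L),
                  at_quality_rate = 0, wrap_rate = 0)
  recs <- parse_fastq(fq)
  b <- fastq_to_bon(fq, compress = character(0))
  per_obj <- vapply(b$payload, function(o) {
    nchar(bon:::json_value(o), type = "bytes")
  }, integer(1))
  value_bytes <- vapply(recs, function(r) {
    nchar(r$readid) + nchar(r$spotid) + nchar(r$sequence) +
      nchar(r$quality) + nchar(as.character(r$length))
  }, numeric(1))
  overhead <- per_obj - value_bytes
  expect_identical(length(unique(overhead)), 1L)
  # the constant is the serialized empty-valued template
  template <- nchar(bon:::json_value(list(readid = "", spotid = "",
                                          sequence = "", quality = "",
                                          length = 0L))) - 1L
  expect_identical(unique(overhead), as.numeric(template))
})

test_that("FASTA export wraps, falls back on ids, and skips seqless objects", {
  b <- bon_encode_block(
    list(list(accver = "SYN1.1", defline = "first",
              sequence = strrep("ACGT", 30)),
         list(readid = "r2", sequence = "GGCC"),
         list(defline = "no sequence here")),
    compress = "sequence")
  expect_warning(out <- bon_to_fasta(b, wrap = 50), "skipped")
  expect_identical(attr(out, "skipped"), 1L)
  lines <- strsplit(out, "\n")[[1L]]
  expect_identical(lines[1L], ">SYN1.1 first")
  expect_true(all(nchar(lines[2:4]) == c(50L, 50L, 20L)))
  expect_identical(lines[5L], ">r2")
  unwrapped <- suppressWarnings(bon_to_fasta(b, wrap = 0))
  expect_identical(strsplit(unwrapped, "\n")[[1L]][2L], strrep("ACGT", 30))
})

test_that("chunked conversion emits one header per block", {
  fq <- gen_fastq(10, seed = 2)
  st <- fastq_to_bon(fq, block_size = 4)
  expect_s3_class(st, "bon_stream")
  expect_identical(vapply(st, function(b) b$header$size, integer(1)),
                   c(4L, 4L, 2L))
  expect_identical(length(bon_objects(bon_serialize(st))), 10L)
})
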
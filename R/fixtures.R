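# Deterministic synthetic fixture generators.
#
# Desk-scale stand-ins for downloaded sequence archives and tree
# repositories: everything is reproducible from the seed alone, with
# adversarial records (quality lines starting with "@", line-wrapped
# sequence/quality) mixed in at stated rates, and an optional
# repeat-rich mode (tandem motif repeats) that makes per-value
# compression ratios visible.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

NUC <- c("A", "C", "G", "T")
AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

# vectorized over lens
random_seqs <- function(lens, alphabet = NUC, repeat_rich = FALSE,
                        motif = "ACGTACGGT") {
  if (repeat_rich) {
    tandem <- strrep(motif, ceiling(max(lens, 1L) / nchar(motif)))
    return(substring(tandem, 1L, lens))
  }
  chars <- sample(alphabet, sum(lens), replace = TRUE)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  vapply(seq_along(lens), function(i) {
    paste(chars[starts[i]:ends[i]], collapse = "")
  }, character(1))
}

#' Generate a synthetic FASTQ file
#'
#' Deterministic for a given seed. A stated fraction of records is
#' adversarial: their quality string starts with `@` (a legal quality
#' character that a naive 4-line parser misreads as a record start)
#' and/or their sequence and quality lines are wrapped. Quality
#' characters are drawn uniformly from `quality_range` (ASCII bounds
#' within 33-126).
#'
#' @param n_records Number of reads.
#' @param seed Integer seed; the generator restores the caller's RNG
#'   state.
#' @param length_range Min/max read length in nucleotides.
#' @param quality_range ASCII bounds for quality characters (within
#'   33-126).
#' @param at_quality_rate Fraction of records whose quality starts
#'   with `@`.
#' @param wrap_rate Fraction of records with line-wrapped sequence and
#'   quality.
#' @param wrap_width Column width used for wrapped records.
#' @param repeat_rich Use tandem motif repeats instead of uniform
#'   residues (compresses far better, mirroring low-complexity data).
#' @return FASTQ text (single string, trailing newline).
#' @export
gen_fastq <- function(n_records, seed = 1L, length_range = c(100L, 200L),
                      quality_range = c(33L, 126L), at_quality_rate = 0.1,
                      wrap_rate = 0.1, wrap_width = 40L,
                      repeat_rich = FALSE) {
  stopifnot(length_range[1L] <= length_range[2L],
            quality_range[1L] >= 33L, quality_range[2L] <= 126L,
            quality_range[1L] <= quality_range[2L])
  if (n_records == 0L) return("")
  with_seed(seed, {
    lens <- sample(length_range[1L]:length_range[2L], n_records,
                   replace = TRUE)
    seqs <- random_seqs(lens, NUC, repeat_rich = repeat_rich)
    quals <- vapply(lens, function(len) {
      intToUtf8(sample(quality_range[1L]:quality_range[2L], len,
                       replace = TRUE))
    }, character(1))
    at_q <- stats::runif(n_records) < at_quality_rate
    quals[at_q] <- paste0("@", substring(quals[at_q], 2L))
    desc <- rep("", n_records)
    idx <- seq_len(n_records)
    desc[idx %% 3L == 1L] <- sprintf("spot=%d", idx[idx %% 3L == 1L])
    desc[idx %% 3L == 2L] <- sprintf("length=%d", lens[idx %% 3L == 2L])
    hdr <- sprintf("@r%05d", idx)
    hdr[nzchar(desc)] <- paste(hdr[nzchar(desc)], desc[nzchar(desc)])
    wrap <- stats::runif(n_records) < wrap_rate
    seqs[wrap] <- vapply(seqs[wrap], wrap_text, character(1),
                         width = wrap_width, USE.NAMES = FALSE)
    quals[wrap] <- vapply(quals[wrap], wrap_text, character(1),
                          width = wrap_width, USE.NAMES = FALSE)
    paste0(paste(hdr, seqs, "+", quals, sep = "\n", collapse = "\n"), "\n")
  })
}

#' Generate a synthetic TinySeq-style XML file
#'
#' Mirrors the TinySeq structure, including the sequence type carried
#' as a tag attribute. Deterministic for a given seed.
#'
#' @param n_records Number of entries.
#' @param seed Integer seed.
#' @param length_range Min/max sequence length.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param repeat_rich Tandem motif repeats instead of uniform residues.
#' @param wrap Wrap sequence text at this many columns (0 = single
#'   line, the default; wrapping exercises newline removal on read).
#' @return XML text.
#' @export
gen_tinyseq_xml <- function(n_records, seed = 1L,
                            length_range = c(150L, 300L),
                            alphabet = c("nucleotide", "protein"),
                            repeat_rich = FALSE, wrap = 0L) {
  alphabet <- match.arg(alphabet)
  stopifnot(length_range[1L] <= length_range[2L])
  letters_pool <- if (alphabet == "nucleotide") NUC else AA
  orgs <- c("Synthetica exempli", "Fictus organismus", "Testus generatus")
  with_seed(seed, {
    idx <- seq_len(n_records)
    lens <- sample(length_range[1L]:length_range[2L], n_records,
                   replace = TRUE)
    seqs <- random_seqs(lens, letters_pool, repeat_rich = repeat_rich)
    if (wrap > 0L) {
      seqs <- vapply(seqs, wrap_text, character(1), width = wrap,
                     USE.NAMES = FALSE)
    }
    entries <- sprintf(paste0(
      "  <TSeq>\n",
      "    <TSeq_seqtype value=\"%s\"/>\n",
      "    <TSeq_accver>SYN%06d.1</TSeq_accver>\n",
      "    <TSeq_taxid>%d</TSeq_taxid>\n",
      "    <TSeq_orgname>%s</TSeq_orgname>\n",
      "    <TSeq_defline>synthetic %s record %d</TSeq_defline>\n",
      "    <TSeq_length>%d</TSeq_length>\n",
      "    <TSeq_sequence>%s</TSeq_sequence>\n",
      "  </TSeq>"),
      alphabet, idx, sample(1e5L, n_records, replace = TRUE),
      sample(orgs, n_records, replace = TRUE), alphabet, idx, lens, seqs)
    paste0("<?xml version=\"1.0\"?>\n<TSeqSet>\n",
           paste(entries, collapse = "\n"), "\n</TSeqSet>\n")
  })
}

#' Generate random phylogenetic trees
#'
#' Random topologies with uniform branch lengths via `ape::rtree`,
#' returned as Newick strings. Deterministic for a given seed.
#'
#' @param n_trees Number of trees.
#' @param seed Integer seed.
#' @param leaves_range Min/max number of leaves per tree.
#' @return Character vector of Newick strings.
#' @export
gen_trees <- function(n_trees = 10L, seed = 1L, leaves_range = c(5L, 20L)) {
  stopifnot(leaves_range[1L] >= 2L, leaves_range[1L] <= leaves_range[2L])
  with_seed(seed, {
    vapply(seq_len(n_trees), function(i) {
      n <- sample(leaves_range[1L]:leaves_range[2L], 1L)
      phy <- ape::rtree(n, tip.label = paste0("t", seq_len(n)))
      ape::write.tree(phy, digits = 10L)
    }, character(1))
  })
}
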
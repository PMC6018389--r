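# Minimal NeXML (trees element only) reader and writer, built on xml2.
#
# The reader matches elements by local name, so namespace-prefixed and
# default-namespace documents both work; otu references are resolved to
# taxon labels. Only trees (and, in ARG mode, tree-like networks) are
# handled -- characters/matrix blocks are ignored.

#' Read trees from a NeXML document
#'
#' @param x NeXML text or a file path.
#' @param arg Accept reticulated (network) trees as connected DAGs.
#' @return A list of `bon_phylo_graph` objects; each carries a
#'   `metadata` attribute with the tree's `label` when present.
#' @seealso [nexml_to_bon()]
#' @export
read_nexml <- function(x, arg = FALSE) {
  doc <- tryCatch(
    xml2::read_xml(x),
    error = function(e) abort_parse(
      sprintf("malformed NeXML: %s", conditionMessage(e))))
  otus <- xml2::xml_find_all(doc, "//*[local-name()='otu']")
  otu_label <- stats::setNames(xml2::xml_attr(otus, "label"),
                               xml2::xml_attr(otus, "id"))
  trees <- xml2::xml_find_all(doc, "//*[local-name()='tree']")
  if (!length(trees)) abort_parse("NeXML document contains no tree elements")

  lapply(trees, function(tree) {
    nodes <- xml2::xml_find_all(tree, "./*[local-name()='node']")
    edges <- xml2::xml_find_all(tree, "./*[local-name()='edge']")
    rootedge <- xml2::xml_find_first(tree, "./*[local-name()='rootedge']")
    nid <- xml2::xml_attr(nodes, "id")
    nlabel <- xml2::xml_attr(nodes, "label")
    notu <- xml2::xml_attr(nodes, "otu")
    esrc <- xml2::xml_attr(edges, "source")
    etgt <- xml2::xml_attr(edges, "target")
    eid <- xml2::xml_attr(edges, "id")
    elen <- suppressWarnings(as.double(xml2::xml_attr(edges, "length")))

    blen <- stats::setNames(rep(NA_real_, length(nid)), nid)
    blen[etgt] <- elen
    if (!inherits(rootedge, "xml_missing")) {
      rt <- xml2::xml_attr(rootedge, "target")
      rl <- suppressWarnings(as.double(xml2::xml_attr(rootedge, "length")))
      if (!is.na(rt) && !is.na(rl)) blen[rt] <- rl
    }
    vertices <- lapply(seq_along(nid), function(i) {
      v <- list(id = nid[i])
      nm <- nlabel[i]
      if (is.na(nm) && !is.na(notu[i])) nm <- otu_label[[notu[i]]]
      if (!is.na(nm) && nzchar(nm)) v$name <- nm
      if (!is.na(blen[[nid[i]]])) v$branch_length <- blen[[nid[i]]]
      v
    })
    graph_edges <- lapply(seq_along(eid), function(i) {
      list(id = if (is.na(eid[i])) paste0("e", i - 1L) else eid[i],
           source = esrc[i], target = etgt[i])
    })
    g <- new_phylo_graph(vertices, graph_edges)
    graph_validate(g, arg = arg)
    label <- xml2::xml_attr(tree, "label")
    if (!is.na(label)) attr(g, "metadata") <- list(label = label)
    g
  })
}

#' Convert NeXML trees to BON
#'
#' Each tree of the document becomes one BON object whose mandatory
#' `tree` attribute holds the vertex/edge graph; the tree's label (when
#' present) is hoisted beside `tree` so it remains readable while the
#' tree itself is compressed. The header `size` equals the number of
#' trees (nested objects are not counted). The default compresses the
#' whole tree value.
#'
#' @inheritParams read_nexml
#' @param compress Attribute names to compress (default `"tree"`).
#' @param extras,level,block_size See [tinyseq_to_bon()].
#' @return A [bon_block()] (or `bon_stream` when chunked).
#' @export
nexml_to_bon <- function(x, compress = "tree", extras = list(), level = 6L,
                         block_size = Inf, arg = FALSE) {
  graphs <- read_nexml(x, arg = arg)
  metadata <- lapply(graphs, attr, "metadata")
  trees_to_bon(graphs, metadata = metadata, compress = compress,
               extras = extras, level = level, block_size = block_size)
}

#' Write BON trees as a NeXML document
#'
#' Inverse of [nexml_to_bon()]: emits a minimal NeXML document (otus
#' resolved from vertex names, one `tree` element per object, branch
#' lengths on edges -- the NeXML convention -- plus a `rootedge` when
#' the root vertex carries a length).
#'
#' @param x A [bon_block()], `bon_stream`, or BON text/path of tree
#'   objects.
#' @param arg Accept connected DAGs.
#' @return NeXML text.
#' @export
bon_to_nexml <- function(x, arg = FALSE) {
  graphs <- bon_to_trees(x, arg = arg)
  otu_ids <- character(0)   # label -> otu id
  lines <- character(0)
  tree_chunks <- vector("list", length(graphs))
  for (ti in seq_along(graphs)) {
    g <- graphs[[ti]]
    info <- graph_validate(g, arg = arg)
    bl <- graph_branch_lengths(g, info)
    outdeg <- table(factor(info$src, levels = info$vids))
    md <- attr(g, "metadata")
    label <- if (!is.null(md$label)) {
      sprintf(" label=\"%s\"", xml_escape(as.character(md$label)))
    } else ""
    node_lines <- vapply(seq_along(g$vertices), function(i) {
      v <- g$vertices[[i]]
      id <- as.character(v$id)
      at <- sprintf(" id=\"%s\"", xml_escape(id))
      if (!is.null(v$name)) {
        nm <- as.character(v$name)
        if (!nm %in% names(otu_ids)) {
          otu_ids[[nm]] <<- sprintf("otu%d", length(otu_ids) + 1L)
        }
        at <- paste0(at, sprintf(" label=\"%s\"", xml_escape(nm)))
        if (outdeg[[id]] == 0L) {
          at <- paste0(at, sprintf(" otu=\"%s\"", otu_ids[[nm]]))
        }
      }
      if (id == info$root) at <- paste0(at, " root=\"true\"")
      sprintf("      <node%s/>", at)
    }, character(1))
    edge_lines <- vapply(seq_along(g$edges), function(i) {
      e <- g$edges[[i]]
      len <- bl[[as.character(e$target)]]
      sprintf("      <edge id=\"%s\" source=\"%s\" target=\"%s\"%s/>",
              xml_escape(as.character(e$id)),
              xml_escape(as.character(e$source)),
              xml_escape(as.character(e$target)),
              if (is.na(len)) "" else sprintf(" length=\"%s\"", json_num(len)))
    }, character(1))
    root_line <- if (!is.na(bl[[info$root]])) {
      sprintf("      <rootedge id=\"re%d\" target=\"%s\" length=\"%s\"/>",
              ti, xml_escape(info$root), json_num(bl[[info$root]]))
    } else character(0)
    tree_chunks[[ti]] <- c(
      sprintf("    <tree id=\"tree%d\"%s>", ti, label),
      node_lines, root_line, edge_lines, "    </tree>")
  }
  otu_lines <- if (length(otu_ids)) {
    sprintf("    <otu id=\"%s\" label=\"%s\"/>",
            unname(otu_ids), xml_escape(names(otu_ids)))
  } else character(0)
  paste(c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
          "<nexml xmlns=\"http://www.nexml.org/2009\" version=\"0.9\">",
          "  <otus id=\"otus1\">", otu_lines, "  </otus>",
          "  <trees id=\"trees1\" otus=\"otus1\">",
          unlist(tree_chunks),
          "  </trees>", "</nexml>", ""),
        collapse = "\n")
}
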
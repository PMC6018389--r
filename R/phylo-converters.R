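# Phylogenetic trees as vertex/edge graphs.
#
# A tree is stored as two sets, "vertices" and "edges". Every edge has
# the mandatory attributes id/source/target (plus free metadata such as
# rate estimates); every vertex has a unique id, an optional taxon
# name, and -- following the convention that nodes carry the attribute
# "branch length" -- the length of its incoming branch. A compatibility
# flag emits lengths on edges instead (the NeXML convention). The same
# representation relaxes to a connected DAG in ARG mode, which admits
# reticulations (e.g. ancestral recombination graphs); only the
# representation is supported, no ARG inference.

new_phylo_graph <- function(vertices, edges) {
  structure(list(vertices = vertices, edges = edges),
            class = "bon_phylo_graph")
}

#' @export
print.bon_phylo_graph <- function(x, ...) {
  cat(sprintf("<bon_phylo_graph> %d vertices, %d edges\n",
              length(x$vertices), length(x$edges)))
  invisible(x)
}

#' Encode a phylogenetic tree as a vertex/edge graph
#'
#' Vertices and edges get deterministic ids assigned by preorder
#' traversal (`v0`, `v1`, ... from the root; `e0`, ... in the same
#' visit order), so serialization is byte-stable. Leaf names are
#' preserved verbatim; the branch length of each branch is stored on
#' its child vertex (or on the edge with `branch_on_edges = TRUE`).
#' The root carries a branch length only if the input has a root edge.
#'
#' @param phy An `ape::phylo` tree.
#' @param branch_on_edges Store branch lengths inside edge definitions
#'   instead of on child vertices.
#' @param edge_metadata Optional list (aligned with the tree's edge
#'   matrix rows, cladewise) of named lists merged into the edge
#'   definitions, e.g. rate estimates with confidence intervals.
#' @return A `bon_phylo_graph`: `list(vertices = , edges = )` ready for
#'   JSON encoding.
#' @seealso [graph_to_tree()], [trees_to_bon()]
#' @examples
#' g <- tree_to_graph(ape::read.tree(text = "(A:1,(B:2,C:3):4);"))
#' length(g$vertices); length(g$edges)
#' @export
tree_to_graph <- function(phy, branch_on_edges = FALSE, edge_metadata = NULL) {
  if (!inherits(phy, "phylo")) abort_validate("expected an ape 'phylo' tree")
  if (anyDuplicated(phy$tip.label)) {
    abort_validate(sprintf(
      "duplicate leaf labels: %s (vertex ids stay unique, names may not)",
      paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", ")))
  }
  phy <- stats::reorder(phy, "cladewise")
  edge_metadata <- edge_metadata %||% attr(phy, "edge_metadata")
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  root <- ntip + 1L
  # preorder vertex numbering: root first, then children in edge order
  vid <- character(nnode)
  vid[root] <- "v0"
  children <- phy$edge[, 2L]
  vid[children] <- paste0("v", seq_along(children))

  name_of <- function(node) {
    if (node <= ntip) return(phy$tip.label[node])
    if (!is.null(phy$node.label)) {
      lab <- phy$node.label[node - ntip]
      if (!is.na(lab) && nzchar(lab)) return(lab)
    }
    NULL
  }
  blen_of <- function(k) {
    # incoming edge index of a vertex in preorder numbering; 0 = root
    if (k == 0L) {
      if (!is.null(phy$root.edge)) phy$root.edge else NULL
    } else if (!is.null(phy$edge.length)) {
      phy$edge.length[k]
    } else NULL
  }
  order_nodes <- c(root, children)
  vertices <- lapply(seq_along(order_nodes) - 1L, function(k) {
    node <- order_nodes[k + 1L]
    v <- list(id = paste0("v", k))
    nm <- name_of(node)
    if (!is.null(nm)) v$name <- nm
    if (!branch_on_edges) {
      bl <- blen_of(k)
      if (!is.null(bl)) v$branch_length <- bl
    }
    v
  })
  edges <- lapply(seq_along(children), function(i) {
    e <- list(id = paste0("e", i - 1L),
              source = vid[phy$edge[i, 1L]],
              target = vid[phy$edge[i, 2L]])
    if (branch_on_edges && !is.null(phy$edge.length)) {
      e$branch_length <- phy$edge.length[i]
    }
    md <- edge_metadata[[i]]
    if (!is.null(md)) e <- c(e, md)
    e
  })
  new_phylo_graph(vertices, edges)
}

# Structural checks. Returns list(root = , children = , vertex_index = ).
graph_validate <- function(graph, arg = FALSE) {
  vs <- graph$vertices
  es <- graph$edges
  vids <- vapply(vs, function(v) as.character(v$id %||% NA_character_),
                 character(1))
  if (anyNA(vids) || anyDuplicated(vids)) {
    abort_validate("vertex ids must be present and unique")
  }
  eids <- vapply(es, function(e) as.character(e$id %||% NA_character_),
                 character(1))
  if (anyNA(eids) || anyDuplicated(eids)) {
    abort_validate("edge ids must be present and unique")
  }
  src <- vapply(es, function(e) as.character(e$source), character(1))
  tgt <- vapply(es, function(e) as.character(e$target), character(1))
  bad <- setdiff(c(src, tgt), vids)
  if (length(bad)) {
    abort_validate(sprintf("edges reference unknown vertices: %s",
                           paste(bad, collapse = ", ")))
  }
  incoming <- table(factor(tgt, levels = vids))
  if (!arg) {
    multi <- vids[incoming > 1L]
    if (length(multi)) {
      abort_validate(sprintf(
        "not a tree: vertices with several incoming edges: %s",
        paste(multi, collapse = ", ")))
    }
  }
  roots <- vids[incoming == 0L]
  if (length(roots) != 1L) {
    abort_validate(sprintf(
      "expected exactly one root (vertex without incoming edge), found %d%s",
      length(roots),
      if (length(roots)) paste0(": ", paste(roots, collapse = ", ")) else ""))
  }
  if (!arg && length(es) != length(vs) - 1L) {
    abort_validate(sprintf(
      "not a tree: %d edges for %d vertices (expected |E| == |V| - 1)",
      length(es), length(vs)))
  }
  # connectivity (and, in ARG mode, acyclicity) by traversal from the root
  adj <- split(tgt, factor(src, levels = vids))
  seen <- new.env(parent = emptyenv())
  stack <- roots
  visits <- 0L
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (!is.null(seen[[v]])) next
    seen[[v]] <- TRUE
    visits <- visits + 1L
    stack <- c(stack, adj[[v]])
  }
  if (visits != length(vs)) {
    unreached <- vids[vapply(vids, function(v) is.null(seen[[v]]), logical(1))]
    abort_validate(sprintf("graph not connected; unreachable vertices: %s",
                           paste(unreached, collapse = ", ")))
  }
  if (arg && has_directed_cycle(vids, src, tgt)) {
    abort_validate("ARG mode requires an acyclic graph; directed cycle found")
  }
  list(root = roots, vids = vids, src = src, tgt = tgt)
}

has_directed_cycle <- function(vids, src, tgt) {
  indeg <- table(factor(tgt, levels = vids))
  adj <- split(tgt, factor(src, levels = vids))
  queue <- vids[indeg == 0L]
  removed <- 0L
  indeg <- as.list(as.integer(indeg))
  names(indeg) <- vids
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    removed <- removed + 1L
    for (w in adj[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  removed != length(vids)
}

graph_branch_lengths <- function(graph, info) {
  # named by target vertex id; NA when absent
  bl <- rep(NA_real_, length(info$vids))
  names(bl) <- info$vids
  on_edges <- any(vapply(graph$edges, function(e)
    !is.null(e$branch_length), logical(1)))
  if (on_edges) {
    for (e in graph$edges) {
      if (!is.null(e$branch_length)) {
        bl[[as.character(e$target)]] <- as.double(e$branch_length)
      }
    }
  } else {
    for (v in graph$vertices) {
      if (!is.null(v$branch_length)) {
        bl[[as.character(v$id)]] <- as.double(v$branch_length)
      }
    }
  }
  bl
}

#' Rebuild a phylogenetic tree from a vertex/edge graph
#'
#' Exact inverse of [tree_to_graph()] up to id relabeling. The graph
#' must pass the tree invariants (unique ids, resolvable endpoints,
#' `|E| == |V| - 1`, a single root, one incoming edge per non-root
#' vertex, connectivity); violations signal a structural error naming
#' the offending vertices. Branch lengths are read from child vertices
#' or, if any edge defines one, from edges. Edge metadata (keys other
#' than id/source/target/branch_length) is preserved as the
#' `edge_metadata` attribute, aligned with the edge matrix rows.
#'
#' @param graph A `bon_phylo_graph` (or the equivalent plain list, e.g.
#'   decoded from BON).
#' @return An `ape::phylo` tree.
#' @export
graph_to_tree <- function(graph) {
  info <- graph_validate(graph)
  vids <- info$vids
  if (length(vids) < 2L) {
    abort_validate(paste(
      "a single-vertex graph cannot be represented as an ape tree;",
      "use graph_to_newick()"))
  }
  outdeg <- table(factor(info$src, levels = vids))
  tips <- vids[outdeg == 0L]
  internals <- c(info$root, setdiff(vids[outdeg > 0L], info$root))
  num <- c(seq_along(tips), length(tips) + seq_along(internals))
  names(num) <- c(tips, internals)

  edge <- cbind(num[info$src], num[info$tgt])
  dimnames(edge) <- NULL
  names_of <- vapply(graph$vertices, function(v)
    if (is.null(v$name)) NA_character_ else as.character(v$name), character(1))
  names(names_of) <- vids

  phy <- list(edge = edge, Nnode = length(internals),
              tip.label = unname(names_of[tips]))
  phy$tip.label[is.na(phy$tip.label)] <- tips[is.na(phy$tip.label)]
  nl <- unname(names_of[internals])
  if (any(!is.na(nl))) {
    nl[is.na(nl)] <- ""
    phy$node.label <- nl
  }
  bl <- graph_branch_lengths(graph, info)
  el <- unname(bl[info$tgt])
  if (any(!is.na(el))) {
    el[is.na(el)] <- 0
    phy$edge.length <- el
  }
  if (!is.na(bl[[info$root]])) phy$root.edge <- bl[[info$root]]
  class(phy) <- "phylo"
  phy <- stats::reorder(phy, "cladewise")

  md <- lapply(graph$edges, function(e) {
    keep <- setdiff(names(e), c("id", "source", "target", "branch_length"))
    if (length(keep)) e[keep] else NULL
  })
  if (any(!vapply(md, is.null, logical(1)))) {
    # align metadata with the reordered edge matrix
    tgt_ids <- info$tgt
    ord <- match(names(num)[match(phy$edge[, 2L], num)], tgt_ids)
    attr(phy, "edge_metadata") <- md[ord]
  }
  phy
}

# ---- Newick ----------------------------------------------------------------

strip_quotes <- function(labels) {
  quoted <- grepl("^'.*'$", labels)
  labels[quoted] <- gsub("''", "'",
                         sub("^'(.*)'$", "\\1", labels[quoted]))
  labels
}

quote_label <- function(label) {
  if (grepl("[ \t()\\[\\]:;,'\"]", label, perl = TRUE)) {
    paste0("'", gsub("'", "''", label), "'")
  } else label
}

check_parens <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0L)) {
    abort_parse(sprintf("unbalanced parentheses at offset %d",
                        which(depth < 0L)[1L]), offset = which(depth < 0L)[1L])
  }
  if (depth[length(depth)] != 0L) {
    abort_parse(sprintf("unbalanced parentheses: %d unclosed at end of input",
                        depth[length(depth)]), offset = nchar(text))
  }
}

#' Read a Newick tree
#'
#' Standard Newick grammar (branch lengths after `:`, internal labels
#' allowed) via `ape::read.tree`, with two repairs: single-quoted
#' labels are unquoted (ape keeps the quote characters), and unbalanced
#' parentheses are reported with a byte offset.
#'
#' @param text A single Newick string. A single-leaf tree (`"A;"`) is
#'   not representable as an `ape::phylo`; use [newick_to_graph()] for
#'   that case.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  check_parens(text)
  phy <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) abort_parse(
      sprintf("malformed Newick: %s", conditionMessage(e))))
  if (is.null(phy)) abort_parse("malformed Newick: ape could not parse it")
  phy$tip.label <- strip_quotes(phy$tip.label)
  if (!is.null(phy$node.label)) phy$node.label <- strip_quotes(phy$node.label)
  phy
}

#' Write a Newick tree
#'
#' @param phy An `ape::phylo` tree.
#' @param digits Precision for branch lengths.
#' @return A single Newick string.
#' @export
write_newick <- function(phy, digits = 10L) {
  ape::write.tree(phy, digits = digits)
}

singleton_newick_re <- "^\\s*('(?:[^']|'')*'|[^():;,\\s]+)\\s*(?::([-+0-9.eE]+))?\\s*;?\\s*$"

#' Convert Newick text to a vertex/edge graph
#'
#' Like [read_newick()] followed by [tree_to_graph()], but also
#' accepts the degenerate single-leaf tree (`"A;"` becomes one vertex
#' and no edges).
#'
#' @inheritParams tree_to_graph
#' @param text A single Newick string.
#' @return A `bon_phylo_graph`.
#' @export
newick_to_graph <- function(text, branch_on_edges = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl("[(,]", text)) {
    m <- regmatches(text, regexec(singleton_newick_re, text))[[1L]]
    if (length(m) < 2L || !nzchar(m[2L])) {
      abort_parse("malformed Newick: empty or unlabelled single-leaf tree")
    }
    v <- list(id = "v0", name = strip_quotes(m[2L]))
    if (length(m) >= 3L && nzchar(m[3L])) {
      v$branch_length <- as.double(m[3L])
    }
    return(new_phylo_graph(list(v), list()))
  }
  tree_to_graph(read_newick(text), branch_on_edges = branch_on_edges)
}

#' Write a vertex/edge graph as Newick
#'
#' Direct recursive writer (no intermediate `phylo`), so single-vertex
#' graphs are representable and labels needing quoting are
#' single-quoted with `''` escapes.
#'
#' @param graph A `bon_phylo_graph` or equivalent list.
#' @param digits Precision for branch lengths.
#' @return A single Newick string ending in `;`.
#' @export
graph_to_newick <- function(graph, digits = 10L) {
  info <- graph_validate(graph)
  vs <- graph$vertices
  names(vs) <- info$vids
  bl <- graph_branch_lengths(graph, info)
  kids <- split(info$tgt, factor(info$src, levels = info$vids))
  fmt_len <- function(id) {
    if (is.na(bl[[id]])) "" else
      paste0(":", formatC(bl[[id]], digits = digits, format = "g", width = 1))
  }
  rec <- function(id) {
    label <- if (is.null(vs[[id]]$name)) "" else
      quote_label(as.character(vs[[id]]$name))
    ch <- kids[[id]]
    if (!length(ch)) return(paste0(label, fmt_len(id)))
    paste0("(", paste(vapply(ch, rec, character(1)), collapse = ","), ")",
           label, fmt_len(id))
  }
  paste0(rec(info$root), ";")
}

# ---- BON blocks of trees ---------------------------------------------------

# A graph as a JSON-ready plain list (class stripped).
graph_as_list <- function(graph) {
  list(vertices = lapply(graph$vertices, unclass),
       edges = lapply(graph$edges, unclass))
}

list_as_graph <- function(x, arg = FALSE) {
  if (!is.list(x) || is.null(x$vertices) || is.null(x$edges)) {
    abort_validate("a tree attribute must carry 'vertices' and 'edges' sets")
  }
  g <- new_phylo_graph(x$vertices, x$edges)
  graph_validate(g, arg = arg)
  g
}

#' Encode trees as a BON block
#'
#' Each BON object holds one phylogenetic tree under the mandatory
#' attribute `tree` (the vertex/edge graph as a nested object), with
#' any per-tree metadata hoisted beside it so it stays readable while
#' the tree itself is compressed. The default compresses the whole
#' `tree` value.
#'
#' @param trees A list of `ape::phylo` trees, Newick strings, or
#'   `bon_phylo_graph` objects (mixable).
#' @param metadata Optional list (one named list per tree) of
#'   attributes stored beside `tree`.
#' @param compress Attribute names to compress (default `"tree"`).
#' @param extras,level,block_size See [tinyseq_to_bon()].
#' @return A [bon_block()] whose header size is the number of trees.
#' @seealso [bon_to_trees()], [nexml_to_bon()]
#' @export
trees_to_bon <- function(trees, metadata = NULL, compress = "tree",
                         extras = list(), level = 6L, block_size = Inf) {
  if (inherits(trees, "phylo") || is.character(trees) ||
      inherits(trees, "bon_phylo_graph")) {
    trees <- if (is.character(trees)) as.list(trees) else list(trees)
  }
  objects <- lapply(seq_along(trees), function(i) {
    t <- trees[[i]]
    g <- if (inherits(t, "bon_phylo_graph")) t
         else if (inherits(t, "phylo")) tree_to_graph(t)
         else if (is.character(t)) newick_to_graph(t)
         else abort_validate("trees must be phylo, Newick text, or graphs")
    obj <- list(tree = graph_as_list(g))
    md <- metadata[[i]]
    if (!is.null(md)) obj <- c(obj, md)
    obj
  })
  chunk_blocks(objects, compress, extras, level, block_size)
}

#' Decode a BON block of trees
#'
#' @param x A [bon_block()], `bon_stream`, or BON text/path whose
#'   objects carry a `tree` attribute.
#' @param arg Accept connected DAGs (ancestral recombination graph
#'   mode) instead of requiring strict trees.
#' @return A list of `bon_phylo_graph` objects; per-tree metadata is
#'   attached as the `metadata` attribute of each graph.
#' @export
bon_to_trees <- function(x, arg = FALSE) {
  objects <- as_decoded_objects(x)
  lapply(objects, function(o) {
    if (is.null(o$tree)) abort_validate("object has no 'tree' attribute")
    g <- list_as_graph(o$tree, arg = arg)
    md <- o[setdiff(names(o), "tree")]
    if (length(md)) attr(g, "metadata") <- md
    g
  })
}
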